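#' Transition probability matrix of a relation
#'
#' Row-normalizes the relation's adjacency so each row is the probability
#' distribution of a one-step walk from that node to the target type:
#' `T(i, j) = I(i, j) / sum_k I(i, k)`. Rows of zero-degree nodes stay
#' all-zero (walk mass is simply lost at dead ends) rather than raising a
#' division error. Results are cached per network and type pair.
#'
#' @param network A `hetero_network`.
#' @param source_type,target_type Type labels of the relation.
#' @return Row-stochastic (or zero-row) numeric matrix.
#' @export
#' @examples
#' net <- toy_network()
#' transition_matrix(net, "L", "T")["l1", ]  # 0.5, 0, 0, 0.5
transition_matrix <- function(network, source_type, target_type) {
  key <- paste0("T|", rel_key(source_type, target_type))
  cached <- network$cache[[key]]
  if (!is.null(cached)) return(cached)
  m <- relation_matrix(network, source_type, target_type)
  rs <- rowSums(m)
  tm <- m / ifelse(rs == 0, 1, rs)
  network$cache[[key]] <- tm
  tm
}

#' Reachable probability matrix along a metapath
#'
#' The ordered product of the path's transition matrices,
#' `R = T_{P1 P2} T_{P2 P3} ... T_{Pn Pn+1}`: entry `(i, j)` is the
#' probability that a type-constrained random walk started at node `i`
#' ends at node `j`. A single-node path gives the identity. Row sums are
#' at most 1; mass below 1 reflects dead ends passed en route.
#'
#' @param network A `hetero_network`.
#' @param path A [metapath] whose consecutive relations all exist in the
#'   network.
#' @return Numeric matrix, rows indexed by start-type nodes, columns by
#'   end-type nodes.
#' @export
reachable_matrix <- function(network, path) {
  stopifnot(inherits(path, "metapath"))
  types <- path$types
  if (length(types) == 1L) {
    ids <- names(network$index[[types]])
    if (is.null(ids)) stop("unknown node type: ", types)
    eye <- diag(length(ids))
    dimnames(eye) <- list(ids, ids)
    return(eye)
  }
  R <- transition_matrix(network, types[1L], types[2L])
  for (k in seq_len(length(types) - 2L))
    R <- R %*% transition_matrix(network, types[k + 1L], types[k + 2L])
  R
}

# Cosine between all row pairs of two nonnegative matrices over a shared
# midpoint dimension; rows with zero norm score 0 against everything.
cosine_rows <- function(A, B) {
  num <- A %*% t(B)
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  denom <- outer(na, nb)
  s <- ifelse(denom == 0, 0, num / denom)
  pmin(pmax(s, 0), 1)
}

#' HeteSim scores for all node pairs along a metapath
#'
#' HeteSim measures the relatedness of a start-type node and an end-type
#' node under a metapath as the cosine between the reachable-probability
#' distributions of walks launched from both ends toward the path's
#' midpoint:
#' `HeteSim(l, p | P) = R_PL(l,:) R_PR^-1(p,:)^T / (|R_PL(l,:)| |R_PR^-1(p,:)|)`
#' where `P` splits into a left part `PL` and right part `PR` at the
#' midpoint and `PR^-1` is the reversed right part. An odd-length path is
#' split at both candidate midpoints and the two scores averaged. Scores
#' lie in `[0, 1]`; a node whose walk distribution is identically zero
#' (no route to the midpoint) scores 0 against every partner.
#'
#' @param network A `hetero_network`.
#' @param path A [metapath] valid on the network.
#' @return Numeric matrix of scores, rows = start-type nodes, columns =
#'   end-type nodes.
#' @export
#' @examples
#' round(hetesim_pairwise(toy_network(), parse_metapath("LTP", c("L", "T", "P"))), 4)
hetesim_pairwise <- function(network, path) {
  splits <- split_metapath(path)
  score <- NULL
  for (s in splits) {
    RL <- reachable_matrix(network, s$left)
    RR <- reachable_matrix(network, reverse_metapath(s$right))
    part <- cosine_rows(RL, RR)
    score <- if (is.null(score)) part else score + part
  }
  score / length(splits)
}

#' HeteSim score for a single node pair
#'
#' Equivalent to the corresponding entry of [hetesim_pairwise()], but
#' computed by propagating only the two endpoint rows through the
#' transition matrices, which is much cheaper when one pair is needed on
#' an edited network (as in leave-one-out evaluation).
#'
#' @param network A `hetero_network`.
#' @param path A [metapath].
#' @param source_id,target_id Node identifiers under the path's endpoint
#'   types.
#' @return Score in `[0, 1]`.
#' @export
#' @examples
#' hetesim_pair(toy_network(), parse_metapath("LTP", c("L", "T", "P")), "l3", "p1")
hetesim_pair <- function(network, path, source_id, target_id) {
  stopifnot(inherits(path, "metapath"))
  types <- path$types
  i <- network$index[[types[1L]]][source_id]
  j <- network$index[[types[length(types)]]][target_id]
  if (is.na(i)) stop("unknown ", types[1L], " node id: ", source_id)
  if (is.na(j)) stop("unknown ", types[length(types)], " node id: ", target_id)

  propagate <- function(sub_path, row_index) {
    tys <- sub_path$types
    n <- length(network$index[[tys[1L]]])
    v <- rep(0, n)
    v[row_index] <- 1
    if (length(tys) > 1L)
      for (k in seq_len(length(tys) - 1L))
        v <- as.numeric(v %*% transition_matrix(network, tys[k], tys[k + 1L]))
    v
  }
  total <- 0
  splits <- split_metapath(path)
  for (s in splits) {
    vl <- propagate(s$left, i)
    vr <- propagate(reverse_metapath(s$right), j)
    denom <- sqrt(sum(vl^2)) * sqrt(sum(vr^2))
    total <- total + if (denom == 0) 0 else sum(vl * vr) / denom
  }
  min(max(total / length(splits), 0), 1)
}
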