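rel_key <- function(a, b) paste(a, b, sep = "|")

#' Network construction options
#'
#' Controls how raw weighted edge lists are turned into a heterogeneous
#' network: the sparsification cutoff, whether retained edges are binarized
#' to 0/1 adjacency, and whether nodes left without edges keep their index
#' slot.
#'
#' @param cutoff Minimum edge weight retained, in `[0, 1]`. Applied to every
#'   relation unless overridden in `cutoff_relations`.
#' @param binarize If `TRUE` (default), retained edges get weight 1, so
#'   walks run on 0/1 adjacency; if `FALSE` the original weights are kept.
#' @param keep_isolated_nodes If `TRUE` (default), nodes seen in any edge
#'   list stay indexed even when the cutoff removes all their edges, so
#'   matrix dimensions are stable across cutoffs.
#' @param cutoff_relations Optional named numeric vector of per-relation
#'   cutoffs keyed as `"A|B"` (e.g. `c("L|P" = 0.9)`), overriding `cutoff`
#'   for those relations.
#'
#' @return A `network_config` list.
#' @export
#' @examples
#' network_config(cutoff = 0.9)
network_config <- function(cutoff = 0, binarize = TRUE,
                           keep_isolated_nodes = TRUE,
                           cutoff_relations = NULL) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
  if (is.na(cutoff) || cutoff < 0 || cutoff > 1)
    stop("'cutoff' must be in [0, 1]")
  if (!is.null(cutoff_relations)) {
    if (is.null(names(cutoff_relations)) || any(!nzchar(names(cutoff_relations))))
      stop("'cutoff_relations' must be a named numeric vector")
    if (any(cutoff_relations < 0 | cutoff_relations > 1))
      stop("per-relation cutoffs must be in [0, 1]")
  }
  structure(list(cutoff = cutoff,
                 binarize = isTRUE(binarize),
                 keep_isolated_nodes = isTRUE(keep_isolated_nodes),
                 cutoff_relations = cutoff_relations),
            class = "network_config")
}

new_hetero_network <- function(index, relations, config = network_config()) {
  structure(list(node_types = names(index),
                 index = index,
                 relations = relations,
                 config = config,
                 cache = new.env(parent = emptyenv())),
            class = "hetero_network")
}

#' Build a heterogeneous network from matrices
#'
#' Low-level constructor taking one adjacency/similarity matrix per
#' unordered type pair, keyed `"A|B"`. Within-type matrices must be
#' symmetric; the reciprocal ordered relation is stored as the transpose.
#' Row/column names supply the node identifiers.
#'
#' @param matrices Named list of nonnegative numeric matrices with full
#'   dimnames; names are `"A|B"` relation keys.
#' @param config A [network_config()].
#' @return A `hetero_network` object.
#' @export
hetero_network_from_matrices <- function(matrices, config = network_config()) {
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    stop("'matrices' must be a named list keyed as 'A|B'")
  index <- list()
  note_nodes <- function(type, ids) {
    known <- index[[type]]
    index[[type]] <<- union(known, ids)
  }
  for (key in names(matrices)) {
    m <- matrices[[key]]
    types <- strsplit(key, "|", fixed = TRUE)[[1L]]
    if (length(types) != 2L) stop("bad relation key: ", key)
    if (is.null(rownames(m)) || is.null(colnames(m)))
      stop("matrix for relation ", key, " must have dimnames")
    if (any(!is.finite(m)) || any(m < 0))
      stop("matrix for relation ", key, " must be finite and nonnegative")
    note_nodes(types[1L], rownames(m))
    note_nodes(types[2L], colnames(m))
  }
  index <- lapply(index, function(ids) stats::setNames(seq_along(ids), ids))
  relations <- list()
  for (key in names(matrices)) {
    m <- matrices[[key]]
    types <- strsplit(key, "|", fixed = TRUE)[[1L]]
    a <- types[1L]; b <- types[2L]
    full <- matrix(0, length(index[[a]]), length(index[[b]]),
                   dimnames = list(names(index[[a]]), names(index[[b]])))
    full[rownames(m), colnames(m)] <- m
    if (a == b) {
      if (!isTRUE(all.equal(full, t(full))))
        stop("within-type relation ", key, " must be symmetric")
      diag(full) <- 0
      relations[[rel_key(a, b)]] <- full
    } else {
      if (rel_key(a, b) %in% names(relations) ||
          rel_key(b, a) %in% names(relations))
        stop("relation for type pair (", a, ",", b, ") supplied twice")
      relations[[rel_key(a, b)]] <- full
      relations[[rel_key(b, a)]] <- t(full)
    }
  }
  new_hetero_network(index, relations, config)
}

apply_cutoff <- function(m, cutoff, binarize) {
  m[m < cutoff] <- 0
  if (binarize) m[m > 0] <- 1
  m
}

#' Assemble the cutoff-thresholded heterogeneous lncRNA-protein network
#'
#' Combines the three weighted edge sets — lncRNA-lncRNA similarity (`ll`),
#' lncRNA-protein association (`lp`), protein-protein interaction (`pp`) —
#' into one typed network. Edges with weight at or above the cutoff are
#' retained (others dropped), and retained weights are set to 1 when
#' `config$binarize` is `TRUE`. The node universe is the union of all
#' identifiers seen in the edge sets, so feature matrices keep fixed
#' dimensions across cutoffs.
#'
#' @param ll,lp,pp [edge_set] objects typed `L|L`, `L|P`, `P|P`.
#' @param config A [network_config()].
#' @return A `hetero_network` with relations `L|L`, `L|P`, `P|L`, `P|P`.
#' @export
#' @examples
#' lp <- edge_set(data.frame(source = c("l1", "l2"),
#'                           target = c("p1", "p1"),
#'                           weight = c(0.95, 0.2)), "L", "P")
#' ll <- edge_set(data.frame(source = "l1", target = "l2", weight = 0.8),
#'                "L", "L")
#' pp <- edge_set(data.frame(source = character(), target = character(),
#'                           weight = numeric()), "P", "P")
#' net <- build_hetero_network(ll, lp, pp, network_config(cutoff = 0.9))
#' network_summary(net)
build_hetero_network <- function(ll, lp, pp, config = network_config()) {
  sets <- list(ll = ll, lp = lp, pp = pp)
  expected <- list(ll = c("L", "L"), lp = c("L", "P"), pp = c("P", "P"))
  for (nm in names(sets)) {
    es <- sets[[nm]]
    if (!inherits(es, "edge_set"))
      stop("'", nm, "' must be an edge_set")
    tp <- c(attr(es, "source_type"), attr(es, "target_type"))
    if (!identical(tp, expected[[nm]]))
      stop("'", nm, "' must be typed (", expected[[nm]][1L], ",",
           expected[[nm]][2L], "), got (", tp[1L], ",", tp[2L], ")")
  }
  lnc_ids <- sort(unique(c(ll$source, ll$target, lp$source)))
  prot_ids <- sort(unique(c(pp$source, pp$target, lp$target)))
  index <- list(L = stats::setNames(seq_along(lnc_ids), lnc_ids),
                P = stats::setNames(seq_along(prot_ids), prot_ids))

  cut_for <- function(key) {
    cr <- config$cutoff_relations
    if (!is.null(cr) && key %in% names(cr)) cr[[key]] else config$cutoff
  }
  fill <- function(es, ridx, cidx, symmetric) {
    m <- matrix(0, length(ridx), length(cidx),
                dimnames = list(names(ridx), names(cidx)))
    if (nrow(es) > 0L) {
      i <- ridx[es$source]; j <- cidx[es$target]
      m[cbind(i, j)] <- es$weight
      if (symmetric) {
        m[cbind(j, i)] <- es$weight
        diag(m) <- 0
      }
    }
    m
  }
  mll <- apply_cutoff(fill(ll, index$L, index$L, TRUE),
                      cut_for("L|L"), config$binarize)
  mlp <- apply_cutoff(fill(lp, index$L, index$P, FALSE),
                      cut_for("L|P"), config$binarize)
  mpp <- apply_cutoff(fill(pp, index$P, index$P, TRUE),
                      cut_for("P|P"), config$binarize)

  net <- new_hetero_network(index,
                            list("L|L" = mll,
                                 "L|P" = mlp,
                                 "P|L" = t(mlp),
                                 "P|P" = mpp),
                            config)
  if (!config$keep_isolated_nodes) net <- drop_isolated(net)
  net
}

drop_isolated <- function(net) {
  keep <- lapply(net$node_types, function(ty) {
    deg <- rep(0, length(net$index[[ty]]))
    for (key in names(net$relations)) {
      types <- strsplit(key, "|", fixed = TRUE)[[1L]]
      if (types[1L] == ty) deg <- deg + rowSums(net$relations[[key]])
    }
    deg > 0
  })
  names(keep) <- net$node_types
  relations <- net$relations
  for (key in names(relations)) {
    types <- strsplit(key, "|", fixed = TRUE)[[1L]]
    relations[[key]] <-
      relations[[key]][keep[[types[1L]]], keep[[types[2L]]], drop = FALSE]
  }
  index <- lapply(net$node_types, function(ty) {
    ids <- names(net$index[[ty]])[keep[[ty]]]
    stats::setNames(seq_along(ids), ids)
  })
  names(index) <- net$node_types
  new_hetero_network(index, relations, net$config)
}

#' Network relation lookup
#'
#' @param network A `hetero_network`.
#' @param source_type,target_type Type labels of the ordered relation.
#' @return The relation's adjacency matrix.
#' @export
relation_matrix <- function(network, source_type, target_type) {
  key <- rel_key(source_type, target_type)
  m <- network$relations[[key]]
  if (is.null(m))
    stop("no relation between types (", source_type, ",", target_type,
         ") in this network")
  m
}

#' Summarize a heterogeneous network
#'
#' Node counts per type and edge counts per stored relation (each
#' undirected relation counted once: upper triangle for within-type
#' relations, one orientation for cross-type relations).
#'
#' @param network A `hetero_network`.
#' @param json If `TRUE`, return a JSON string instead of a list.
#' @return A list (or JSON string) with `nodes` and `edges` components.
#' @export
network_summary <- function(network, json = FALSE) {
  nodes <- lapply(network$index, length)
  seen <- character()
  edges <- list()
  for (key in names(network$relations)) {
    types <- strsplit(key, "|", fixed = TRUE)[[1L]]
    canon <- rel_key(min(types), max(types))
    if (canon %in% seen) next
    seen <- c(seen, canon)
    m <- network$relations[[rel_key(min(types), max(types))]]
    n <- if (types[1L] == types[2L]) sum(m[upper.tri(m)] > 0) else sum(m > 0)
    edges[[canon]] <- n
  }
  out <- list(nodes = nodes, edges = edges)
  if (json) jsonlite::toJSON(out, auto_unbox = TRUE) else out
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("<hetero_network>\n")
  s <- network_summary(x)
  cat("  nodes:", paste(sprintf("%s=%d", names(s$nodes), unlist(s$nodes)),
                        collapse = ", "), "\n")
  cat("  edges:", paste(sprintf("%s=%d", names(s$edges), unlist(s$edges)),
                        collapse = ", "), "\n")
  invisible(x)
}

# Return a copy of the network with one L-P association edge removed and a
# fresh transition-matrix cache. Used by the cross-validation leakage
# control.
remove_lp_edge <- function(network, lncRNA_id, protein_id,
                           lnc_type = "L", prot_type = "P") {
  i <- network$index[[lnc_type]][lncRNA_id]
  j <- network$index[[prot_type]][protein_id]
  if (is.na(i) || is.na(j)) stop("unknown node id")
  relations <- network$relations
  relations[[rel_key(lnc_type, prot_type)]][i, j] <- 0
  relations[[rel_key(prot_type, lnc_type)]][j, i] <- 0
  new_hetero_network(network$index, relations, network$config)
}

# Remove every L-P edge incident to either endpoint of a pair (strict
# leakage control).
remove_incident_lp_edges <- function(network, lncRNA_id, protein_id,
                                     lnc_type = "L", prot_type = "P") {
  i <- network$index[[lnc_type]][lncRNA_id]
  j <- network$index[[prot_type]][protein_id]
  if (is.na(i) || is.na(j)) stop("unknown node id")
  relations <- network$relations
  key <- rel_key(lnc_type, prot_type)
  relations[[key]][i, ] <- 0
  relations[[key]][, j] <- 0
  relations[[rel_key(prot_type, lnc_type)]] <- t(relations[[key]])
  new_hetero_network(network$index, relations, network$config)
}
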