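#' Synthetic network specification
#'
#' Parameters of the block-structured generator that stands in for real
#' co-expression / association / interaction networks. lncRNAs and
#' proteins are assigned to functional blocks; an lncRNA-protein
#' association edge appears with probability `within_block_edge_prob`
#' inside a block and `cross_block_edge_prob` across blocks, and
#' within-type similarities are near 1 inside a block and near 0 across
#' blocks, perturbed by half-normal noise of scale `similarity_noise` and
#' truncated to `[0, 1]`. Ground truth for evaluation is block
#' co-membership. Defaults (60 lncRNAs, 40 proteins, 4 blocks, 0.6/0.05
#' edge probabilities, noise 0.1) give a clearly recoverable planted
#' signal at a size where a full 14-path leave-one-out run takes minutes
#' on one CPU.
#'
#' @param n_lnc,n_prot Node counts.
#' @param n_blocks Number of blocks.
#' @param within_block_edge_prob,cross_block_edge_prob Edge probabilities;
#'   the planted signal requires `within > cross`.
#' @param similarity_noise Nonnegative noise scale for the similarity
#'   weights.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_lnc = 60L, n_prot = 40L, n_blocks = 4L,
                           within_block_edge_prob = 0.6,
                           cross_block_edge_prob = 0.05,
                           similarity_noise = 0.1, seed = 7L) {
  if (n_lnc < 1L || n_prot < 1L || n_blocks < 1L)
    stop("node and block counts must be positive")
  if (n_blocks > min(n_lnc, n_prot))
    stop("more blocks than nodes of a type")
  for (p in c(within_block_edge_prob, cross_block_edge_prob))
    if (p < 0 || p > 1) stop("edge probabilities must lie in [0, 1]")
  if (within_block_edge_prob <= cross_block_edge_prob)
    stop("'within_block_edge_prob' must exceed 'cross_block_edge_prob' ",
         "for a planted signal")
  if (similarity_noise < 0) stop("'similarity_noise' must be >= 0")
  structure(list(n_lnc = as.integer(n_lnc), n_prot = as.integer(n_prot),
                 n_blocks = as.integer(n_blocks),
                 within_block_edge_prob = within_block_edge_prob,
                 cross_block_edge_prob = cross_block_edge_prob,
                 similarity_noise = similarity_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

sim_matrix <- function(same_block, noise) {
  n <- nrow(same_block)
  raw <- matrix(0, n, n)
  up <- upper.tri(raw)
  base <- ifelse(same_block[up], 1, 0)
  jitter <- abs(stats::rnorm(sum(up), sd = 1)) * noise
  raw[up] <- clamp01(ifelse(same_block[up], base - jitter, base + jitter))
  raw + t(raw)
}

#' Generate a seeded synthetic heterogeneous network
#'
#' Draws a network under a [synthetic_spec()]: block-structured
#' lncRNA-protein association edges (weight 1), and within-type
#' similarity weights near 1 inside blocks and near 0 across blocks, so
#' that the usual cutoffs separate planted from spurious similarity. The
#' result is deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param config [network_config()] applied when assembling the network
#'   object; the default keeps the planted similarity structure and the
#'   binary association edges.
#' @return List with `network` (a `hetero_network`), `truth` (a
#'   `labeled_pair_set` labeling every lncRNA-protein pair by block
#'   co-membership), and `edge_sets` (the raw `ll`, `lp`, `pp`
#'   [edge_set]s, re-thresholdable via [build_hetero_network()]).
#' @export
#' @examples
#' sim <- generate_network(synthetic_spec(n_lnc = 12, n_prot = 8,
#'                                        n_blocks = 2))
#' network_summary(sim$network)
generate_network <- function(spec = synthetic_spec(),
                             config = network_config(cutoff = 0.3,
                                                     binarize = TRUE)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lnc_ids <- sprintf("l%03d", seq_len(spec$n_lnc))
  prot_ids <- sprintf("p%03d", seq_len(spec$n_prot))
  lnc_block <- rep_len(seq_len(spec$n_blocks), spec$n_lnc)
  prot_block <- rep_len(seq_len(spec$n_blocks), spec$n_prot)

  drawn <- withr::with_seed(spec$seed, {
    same_lp <- outer(lnc_block, prot_block, "==")
    prob <- ifelse(same_lp, spec$within_block_edge_prob,
                   spec$cross_block_edge_prob)
    adj <- matrix(as.numeric(stats::runif(length(prob)) < prob),
                  spec$n_lnc, spec$n_prot)
    ll <- sim_matrix(outer(lnc_block, lnc_block, "=="),
                     spec$similarity_noise)
    pp <- sim_matrix(outer(prot_block, prot_block, "=="),
                     spec$similarity_noise)
    list(adj = adj, ll = ll, pp = pp)
  })
  dimnames(drawn$adj) <- list(lnc_ids, prot_ids)
  dimnames(drawn$ll) <- list(lnc_ids, lnc_ids)
  dimnames(drawn$pp) <- list(prot_ids, prot_ids)

  mat_to_edges <- function(m, symmetric) {
    idx <- if (symmetric) which(upper.tri(m) & m > 0, arr.ind = TRUE)
           else which(m > 0, arr.ind = TRUE)
    data.frame(source = rownames(m)[idx[, 1L]],
               target = colnames(m)[idx[, 2L]],
               weight = m[idx])
  }
  edge_sets <- list(
    ll = edge_set(mat_to_edges(drawn$ll, TRUE), "L", "L"),
    lp = edge_set(mat_to_edges(drawn$adj, FALSE), "L", "P"),
    pp = edge_set(mat_to_edges(drawn$pp, TRUE), "P", "P"))

  cut_for <- function(key) {
    cr <- config$cutoff_relations
    if (!is.null(cr) && key %in% names(cr)) cr[[key]] else config$cutoff
  }
  relations <- list(
    "L|L" = apply_cutoff(drawn$ll, cut_for("L|L"), config$binarize),
    "L|P" = apply_cutoff(drawn$adj, cut_for("L|P"), config$binarize),
    "P|P" = apply_cutoff(drawn$pp, cut_for("P|P"), config$binarize))
  network <- hetero_network_from_matrices(relations, config)

  truth <- expand.grid(lncRNA = lnc_ids, protein = prot_ids,
                       stringsAsFactors = FALSE)
  truth$label <- as.integer(
    lnc_block[match(truth$lncRNA, lnc_ids)] ==
      prot_block[match(truth$protein, prot_ids)])
  truth <- structure(truth,
                     source_networks = c(positive = "synthetic",
                                         negative = "synthetic"),
                     seed = spec$seed,
                     class = c("labeled_pair_set", "data.frame"))
  list(network = network, truth = truth, edge_sets = edge_sets)
}

#' Three-type worked-example network
#'
#' The small heterogeneous network used throughout the documentation to
#' illustrate HeteSim by hand: three lncRNAs (`l1`-`l3`), four
#' intermediate nodes of type `T` (`t1`-`t4`), and two proteins
#' (`p1`-`p2`), with binary incidence
#' `L-T = [[1,0,0,1],[0,1,0,0],[0,1,1,1]]` and
#' `P-T = [[0,1,0,0],[1,1,1,0]]`. Along the path `L-T-P` the HeteSim
#' score matrix is `[[0, 0.4082], [1, 0.5774], [0.5774, 0.6667]]` (4
#' decimals), e.g. `hetesim(l3, p1) = 0.5774`.
#'
#' @return A `hetero_network` with types `L`, `T`, `P`.
#' @export
#' @examples
#' round(hetesim_pairwise(toy_network(),
#'                        parse_metapath("LTP", c("L", "T", "P"))), 4)
toy_network <- function() {
  I_LT <- matrix(c(1, 0, 0, 1,
                   0, 1, 0, 0,
                   0, 1, 1, 1),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("l1", "l2", "l3"),
                                 c("t1", "t2", "t3", "t4")))
  I_PT <- matrix(c(0, 1, 0, 0,
                   1, 1, 1, 0),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"),
                                 c("t1", "t2", "t3", "t4")))
  hetero_network_from_matrices(list("L|T" = I_LT, "P|T" = I_PT),
                               network_config(cutoff = 0, binarize = TRUE))
}
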