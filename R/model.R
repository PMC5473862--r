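pair_key <- function(l, p) paste(l, p, sep = "\r")

#' Classifier configuration
#'
#' Hyperparameters of the per-pair interaction classifier. The damping
#' constant `beta` in `(0, 1)` discounts longer metapaths: a 3-node path's
#' HeteSim score is multiplied by `beta`, a 4-node path's by `beta^2`, a
#' 5-node path's by `beta^3`. The default `beta = 0.2` sits among the
#' best-performing values of the published grid; downstream accuracy is
#' quite insensitive to it. Features are standardized with statistics
#' fitted on the training rows only; the kernel and cost are passed to the
#' support vector machine.
#'
#' @param beta Damping constant in `(0, 1)`.
#' @param kernel SVM kernel: `"radial"` (default) or `"linear"`.
#' @param cost Positive regularization (soft-margin) constant.
#' @param feature_scaling `"standardize"` (default) or `"none"`.
#' @param seed Integer seed controlling any stochastic step of training.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(beta = 0.2, kernel = "radial", cost = 1,
                              feature_scaling = "standardize", seed = 1L) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1)
    stop("'beta' must lie in (0, 1)")
  kernel <- match.arg(kernel, c("radial", "linear"))
  feature_scaling <- match.arg(feature_scaling, c("standardize", "none"))
  if (!is.numeric(cost) || cost <= 0) stop("'cost' must be positive")
  structure(list(beta = beta, kernel = kernel, cost = cost,
                 feature_scaling = feature_scaling,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Build the damped metapath feature table
#'
#' One row per (lncRNA, protein) pair, one column per metapath; the entry
#' is `beta^(node_count - 2)` times the pair's HeteSim score under that
#' path, so a 3-node path contributes at most `beta`, a 4-node path at
#' most `beta^2`, and so on. Column order follows the `paths` argument
#' (default: the canonical manifest order), and the table is deterministic
#' given the network.
#'
#' @param network A `hetero_network` with `L` and `P` layers.
#' @param pairs Data frame with columns `lncRNA`, `protein` (or a
#'   2-column matrix/data frame in that order).
#' @param paths List of [metapath]s from `L` to `P`.
#' @param beta Damping constant; `beta = 1` leaves raw HeteSim scores.
#' @return A `feature_table`: list with `pairs`, `columns`, `values`
#'   (matrix), `beta`.
#' @export
build_feature_table <- function(network, pairs, paths = canonical_metapaths(),
                                beta = 0.2) {
  pairs <- as.data.frame(pairs)
  if (!all(c("lncRNA", "protein") %in% names(pairs)))
    names(pairs)[1:2] <- c("lncRNA", "protein")
  pairs$lncRNA <- as.character(pairs$lncRNA)
  pairs$protein <- as.character(pairs$protein)
  li <- network$index$L[pairs$lncRNA]
  pi_ <- network$index$P[pairs$protein]
  if (any(is.na(li)))
    stop("unknown lncRNA id(s): ",
         paste(unique(pairs$lncRNA[is.na(li)]), collapse = ", "))
  if (any(is.na(pi_)))
    stop("unknown protein id(s): ",
         paste(unique(pairs$protein[is.na(pi_)]), collapse = ", "))
  cols <- vapply(paths, function(p) p$name, character(1L))
  values <- matrix(0, nrow(pairs), length(paths),
                   dimnames = list(NULL, cols))
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    if (p$types[1L] != "L" || p$types[length(p$types)] != "P")
      stop("feature paths must run from L to P; got ", p$name)
    damp <- beta^(length(p$types) - 2L)
    if (nrow(pairs) <= 4L) {
      values[, k] <- damp * mapply(hetesim_pair,
                                   source_id = pairs$lncRNA,
                                   target_id = pairs$protein,
                                   MoreArgs = list(network = network, path = p))
    } else {
      scores <- hetesim_pairwise(network, p)
      values[, k] <- damp * scores[cbind(li, pi_)]
    }
  }
  structure(list(pairs = pairs[c("lncRNA", "protein")],
                 columns = cols, values = values, beta = beta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$values), " pairs x ", ncol(x$values),
      " paths (beta = ", x$beta, ")\n", sep = "")
  invisible(x)
}

#' Sample labeled training pairs from two cutoff networks
#'
#' Positives are drawn uniformly without replacement from the L-P edges of
#' the sparse, high-confidence network (e.g. the 0.9-cutoff network);
#' negatives are drawn uniformly from the (lncRNA x protein) pairs that
#' carry no association edge in the dense network (e.g. the 0.3-cutoff
#' network), the most conservative non-interaction evidence. A list of
#' mandatory positives (e.g. a gold-standard interaction set) is forced
#' into the positive draw. Balanced classes avoid the bias of an
#' imbalanced training set.
#'
#' @param positive_net,negative_net `hetero_network`s sharing the L/P
#'   universes.
#' @param n_pos,n_neg Numbers of positive and negative pairs.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param mandatory_positives Optional data frame of `lncRNA`, `protein`
#'   pairs that must appear among the positives (must be edges of
#'   `positive_net`).
#' @return A `labeled_pair_set`: data frame `lncRNA`, `protein`, `label`
#'   with attributes `source_networks` and `seed`.
#' @export
sample_training_pairs <- function(positive_net, negative_net, n_pos, n_neg,
                                  seed = 1L, mandatory_positives = NULL) {
  adj_pos <- relation_matrix(positive_net, "L", "P")
  edges <- which(adj_pos > 0, arr.ind = TRUE)
  pos_all <- data.frame(lncRNA = rownames(adj_pos)[edges[, 1L]],
                        protein = colnames(adj_pos)[edges[, 2L]],
                        stringsAsFactors = FALSE)
  mand <- if (is.null(mandatory_positives)) pos_all[0, ] else {
    m <- as.data.frame(mandatory_positives)
    if (!all(c("lncRNA", "protein") %in% names(m)))
      names(m)[1:2] <- c("lncRNA", "protein")
    miss <- !(pair_key(m$lncRNA, m$protein) %in%
                pair_key(pos_all$lncRNA, pos_all$protein))
    if (any(miss))
      stop("mandatory positive(s) are not edges of the positive network: ",
           paste(paste(m$lncRNA[miss], m$protein[miss]), collapse = ", "))
    m[c("lncRNA", "protein")]
  }
  if (nrow(mand) > n_pos)
    stop("more mandatory positives (", nrow(mand), ") than n_pos (", n_pos, ")")
  pool <- pos_all[!(pair_key(pos_all$lncRNA, pos_all$protein) %in%
                      pair_key(mand$lncRNA, mand$protein)), ]
  if (n_pos - nrow(mand) > nrow(pool))
    stop("requested ", n_pos, " positives but only ",
         nrow(pool) + nrow(mand), " edges are available")

  adj_neg <- relation_matrix(negative_net, "L", "P")
  non_edges <- which(adj_neg == 0, arr.ind = TRUE)
  neg_all <- data.frame(lncRNA = rownames(adj_neg)[non_edges[, 1L]],
                        protein = colnames(adj_neg)[non_edges[, 2L]],
                        stringsAsFactors = FALSE)
  # a candidate negative must not be a sampled positive either
  neg_all <- neg_all[!(pair_key(neg_all$lncRNA, neg_all$protein) %in%
                         pair_key(pos_all$lncRNA, pos_all$protein)), ]
  if (n_neg > nrow(neg_all))
    stop("requested ", n_neg, " negatives but only ", nrow(neg_all),
         " non-edges are available")

  drawn <- withr::with_seed(seed, {
    pos <- rbind(mand, pool[sample.int(nrow(pool), n_pos - nrow(mand)), ])
    neg <- neg_all[sample.int(nrow(neg_all), n_neg), ]
    list(pos = pos, neg = neg)
  })
  out <- rbind(cbind(drawn$pos, label = 1L), cbind(drawn$neg, label = 0L))
  rownames(out) <- NULL
  structure(out,
            source_networks = c(positive = "positive_net",
                                negative = "negative_net"),
            seed = as.integer(seed),
            class = c("labeled_pair_set", "data.frame"))
}

#' Balanced subsample of a labeled pair set
#'
#' Draws `n_pos` positives and `n_neg` negatives uniformly without
#' replacement from a labeled pair set (for example the ground truth
#' returned by [generate_network()]), reproducibly given the seed.
#'
#' @param labeled A `labeled_pair_set` or data frame with columns
#'   `lncRNA`, `protein`, `label`.
#' @param n_pos,n_neg Class counts to draw.
#' @param seed Integer seed.
#' @return A `labeled_pair_set` with exactly `n_pos + n_neg` rows.
#' @export
subsample_labeled <- function(labeled, n_pos, n_neg, seed = 1L) {
  pos <- labeled[labeled$label == 1L, , drop = FALSE]
  neg <- labeled[labeled$label == 0L, , drop = FALSE]
  if (n_pos > nrow(pos) || n_neg > nrow(neg))
    stop("requested more pairs than available in a class")
  out <- withr::with_seed(seed, rbind(
    pos[sample.int(nrow(pos), n_pos), , drop = FALSE],
    neg[sample.int(nrow(neg), n_neg), , drop = FALSE]))
  rownames(out) <- NULL
  structure(as.data.frame(out)[c("lncRNA", "protein", "label")],
            source_networks = attr(labeled, "source_networks"),
            seed = as.integer(seed),
            class = c("labeled_pair_set", "data.frame"))
}

align_features <- function(features, labeled) {
  idx <- match(pair_key(labeled$lncRNA, labeled$protein),
               pair_key(features$pairs$lncRNA, features$pairs$protein))
  if (any(is.na(idx)))
    stop("labeled pair(s) missing from the feature table")
  idx
}

fit_scaling <- function(x, kind) {
  if (kind == "none")
    return(list(center = rep(0, ncol(x)), scale = rep(1, ncol(x))))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1  # constant columns pass through
  list(center = ctr, scale = scl)
}

apply_scaling <- function(x, scaling) {
  sweep(sweep(x, 2L, scaling$center), 2L, scaling$scale, "/")
}

#' Train the interaction classifier
#'
#' Fits a support vector machine on the damped metapath features of the
#' labeled pairs. The decision value (signed margin distance) is the
#' continuous score used for ranking and ROC analysis; larger means more
#' likely to interact.
#'
#' @param features A [build_feature_table()] result covering all labeled
#'   pairs.
#' @param labels A `labeled_pair_set` (columns `lncRNA`, `protein`,
#'   `label`).
#' @param config A [classifier_config()].
#' @return An `lpi_classifier` carrying the fitted model, the feature
#'   column manifest, the scaling statistics and the config.
#' @export
train_classifier <- function(features, labels, config = classifier_config()) {
  idx <- align_features(features, labels)
  y <- factor(labels$label, levels = c(0L, 1L))
  if (length(unique(labels$label)) < 2L)
    stop("training labels contain a single class")
  x <- features$values[idx, , drop = FALSE]
  scaling <- fit_scaling(x, config$feature_scaling)
  xs <- apply_scaling(x, scaling)
  model <- withr::with_seed(config$seed,
    e1071::svm(x = xs, y = y, kernel = config$kernel, cost = config$cost,
               scale = FALSE))
  structure(list(model = model, columns = features$columns,
                 scaling = scaling, config = config),
            class = "lpi_classifier")
}

#' @export
print.lpi_classifier <- function(x, ...) {
  cat("<lpi_classifier> ", x$config$kernel, " SVM, cost ", x$config$cost,
      ", beta ", x$config$beta, ", ", length(x$columns), " path features\n",
      sep = "")
  invisible(x)
}

#' Decision scores for pairs
#'
#' Applies a fitted classifier to a feature table with the same column
#' manifest (order included) as training; any mismatch is a schema error.
#' Returns one finite decision score per pair, oriented so that higher
#' scores mean predicted interaction.
#'
#' @param classifier An `lpi_classifier`.
#' @param features A `feature_table`.
#' @return Data frame `lncRNA`, `protein`, `score`.
#' @export
score_pairs <- function(classifier, features) {
  if (!identical(unname(features$columns), unname(classifier$columns)))
    stop("feature columns do not match the classifier's training columns")
  xs <- apply_scaling(features$values, classifier$scaling)
  pred <- stats::predict(classifier$model, xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 labels the decision column "a/b": positive values favor class a
  if (startsWith(colnames(dv)[1L], "0/")) dv <- -dv
  data.frame(lncRNA = features$pairs$lncRNA,
             protein = features$pairs$protein,
             score = as.numeric(dv[, 1L]))
}

#' Rank all candidate proteins for one lncRNA
#'
#' Scores every protein in the network against the query lncRNA and sorts
#' descending by decision score, ties broken by protein id ascending.
#'
#' @param network A `hetero_network`.
#' @param classifier An `lpi_classifier`.
#' @param lncRNA_id Query lncRNA identifier.
#' @param paths Metapath list matching the classifier's columns.
#' @param beta Damping constant used for the features.
#' @return Data frame `protein`, `score`, `rank`.
#' @export
rank_candidate_proteins <- function(network, classifier, lncRNA_id,
                                    paths = canonical_metapaths(),
                                    beta = classifier$config$beta) {
  if (is.na(network$index$L[lncRNA_id]))
    stop("unknown lncRNA id: ", lncRNA_id)
  proteins <- names(network$index$P)
  pairs <- data.frame(lncRNA = lncRNA_id, protein = proteins)
  feats <- build_feature_table(network, pairs, paths, beta)
  scored <- score_pairs(classifier, feats)
  ord <- order(-scored$score, scored$protein)
  out <- scored[ord, c("protein", "score")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
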