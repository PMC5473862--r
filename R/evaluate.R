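#' Confusion counts
#'
#' @param labels,predictions Equal-length binary (0/1) vectors; `labels`
#'   are the truth, `predictions` the classifier calls.
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("'labels' and 'predictions' must have equal length")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop("'labels' and 'predictions' must be binary (0/1)")
  structure(list(TP = sum(labels == 1 & predictions == 1),
                 FP = sum(labels == 0 & predictions == 1),
                 TN = sum(labels == 0 & predictions == 0),
                 FN = sum(labels == 1 & predictions == 0)),
            class = "confusion_counts")
}

div0 <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Scalar classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)`, Matthews correlation
#' coefficient `(TP*TN - FP*FN)/sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))` and
#' F1 `2*PRE*SEN/(PRE+SEN)`. Any metric whose denominator is zero returns
#' 0 with a warning.
#'
#' @param counts A [confusion_counts()] result.
#' @return Named list `SEN`, `SPE`, `ACC`, `PRE`, `MCC`, `F1`.
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  if (total == 0) stop("empty confusion table")
  SEN <- div0(TP, TP + FN, "SEN")
  SPE <- div0(TN, TN + FP, "SPE")
  ACC <- (TP + TN) / total
  PRE <- div0(TP, TP + FP, "PRE")
  MCC <- div0(TP * TN - FP * FN,
              sqrt((TP + FN) * (TP + FP) * (TN + FN) * (TN + FP)), "MCC")
  F1 <- div0(2 * PRE * SEN, PRE + SEN, "F1")
  list(SEN = SEN, SPE = SPE, ACC = ACC, PRE = PRE, MCC = MCC, F1 = F1)
}

#' ROC curve and AUC
#'
#' Traces the ROC curve over every distinct score threshold (tied scores
#' share a step), from (0,0) to (1,1). The AUC is computed as the
#' Mann-Whitney statistic — the probability that a random positive
#' outscores a random negative, ties counting one half — which equals the
#' trapezoidal area under the returned curve.
#'
#' @param labels Binary 0/1 truth vector; both classes must be present.
#' @param scores Numeric decision scores, higher = more positive.
#' @return List with `roc` (data frame `FPR`, `TPR`) and `auc`.
#' @export
#' @examples
#' roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))$auc  # 0.75
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("'labels' and 'scores' must have equal length")
  if (!all(labels %in% c(0, 1)))
    stop("'labels' must be binary (0/1)")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y)[!duplicated(grp, fromLast = TRUE)]
  fp <- cumsum(1 - y)[!duplicated(grp, fromLast = TRUE)]
  roc <- data.frame(FPR = c(0, fp / n0), TPR = c(0, tp / n1))
  r <- rank(scores)  # average ranks handle ties with the 1/2 convention
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc = roc, auc = auc)
}

scores_to_report <- function(labels, scores, threshold) {
  ra <- roc_auc(labels, scores)
  counts <- confusion_counts(labels, as.integer(scores > threshold))
  metrics <- withCallingHandlers(metrics_from_counts(counts),
                                 warning = function(w) invokeRestart("muffleWarning"))
  c(metrics, list(counts = counts, roc = ra$roc, auc = ra$auc))
}

#' Leave-one-out cross-validation of the interaction classifier
#'
#' Each labeled pair is held out in turn: its own lncRNA-protein
#' association edge (if present) is removed from the network, its damped
#' metapath features are recomputed on that edited network so the pair
#' never sees its own edge, a classifier is trained on all remaining
#' labeled pairs, and the held-out decision score is recorded. The final
#' report pools all held-out scores. If a round's remaining training pairs
#' are all one class (possible only for very small labeled sets), that
#' round scores the held-out pair by signed distance from the remaining
#' class's feature centroid instead of a fitted margin.
#' `strict = TRUE` additionally removes
#' every other association edge incident to the held-out pair's
#' endpoints before computing its features.
#'
#' @param network A `hetero_network`.
#' @param labeled A `labeled_pair_set` with both classes present.
#' @param paths Metapath list used as features.
#' @param config A [classifier_config()].
#' @param threshold Decision-score operating point for the confusion
#'   metrics (default 0).
#' @param strict Use the strict leakage control (see above).
#' @return List with `scores` (data frame `lncRNA`, `protein`, `label`,
#'   `score`) and `metrics` (scalars, confusion counts, ROC, AUC).
#' @export
loocv <- function(network, labeled, paths = canonical_metapaths(),
                  config = classifier_config(), threshold = 0,
                  strict = FALSE) {
  if (nrow(labeled) < 2L || length(unique(labeled$label)) < 2L)
    stop("LOOCV needs at least one pair of each class")
  base <- build_feature_table(network, labeled, paths, config$beta)
  adj <- relation_matrix(network, "L", "P")
  held <- numeric(nrow(labeled))
  for (i in seq_len(nrow(labeled))) {
    l <- labeled$lncRNA[i]; p <- labeled$protein[i]
    has_edge <- adj[l, p] > 0
    feats_i <- if (has_edge || strict) {
      net_i <- if (strict) remove_incident_lp_edges(network, l, p)
               else remove_lp_edge(network, l, p)
      build_feature_table(net_i, labeled[i, , drop = FALSE], paths,
                          config$beta)
    } else {
      # a negative pair has no edge to remove; its features are unchanged
      structure(list(pairs = base$pairs[i, , drop = FALSE],
                     columns = base$columns,
                     values = base$values[i, , drop = FALSE],
                     beta = base$beta),
                class = "feature_table")
    }
    train_feats <- structure(list(pairs = base$pairs[-i, , drop = FALSE],
                                  columns = base$columns,
                                  values = base$values[-i, , drop = FALSE],
                                  beta = base$beta),
                             class = "feature_table")
    rest <- labeled[-i, , drop = FALSE]
    if (length(unique(rest$label)) < 2L) {
      # single-class residue (only possible for tiny labeled sets): fall
      # back to signed distance from the remaining class's feature centroid
      centroid <- colMeans(train_feats$values)
      d <- sqrt(sum((feats_i$values[1L, ] - centroid)^2))
      held[i] <- if (rest$label[1L] == 1L) -d else d
    } else {
      clf <- train_classifier(train_feats, rest, config)
      held[i] <- score_pairs(clf, feats_i)$score
    }
  }
  scores <- data.frame(lncRNA = labeled$lncRNA, protein = labeled$protein,
                       label = labeled$label, score = held)
  list(scores = scores,
       metrics = scores_to_report(labeled$label, held, threshold))
}

#' Independent-test evaluation
#'
#' Fits the classifier once on the training pairs' features (computed on
#' the full network) and evaluates on a disjoint test set whose positive
#' association edges are all removed from the network before the test
#' features are computed, so no test pair's own edge leaks into its
#' features.
#'
#' @param train_set,test_set Disjoint `labeled_pair_set`s.
#' @param network A `hetero_network`.
#' @param paths Metapath list used as features.
#' @param config A [classifier_config()].
#' @param threshold Operating point for the confusion metrics.
#' @return List with `scores` (test pairs) and `metrics`.
#' @export
independent_test <- function(train_set, test_set, network,
                             paths = canonical_metapaths(),
                             config = classifier_config(), threshold = 0) {
  overlap <- intersect(pair_key(train_set$lncRNA, train_set$protein),
                       pair_key(test_set$lncRNA, test_set$protein))
  if (length(overlap) > 0L)
    stop("train and test pair sets overlap (", length(overlap), " pair(s))")
  train_feats <- build_feature_table(network, train_set, paths, config$beta)
  clf <- train_classifier(train_feats, train_set, config)

  adj <- relation_matrix(network, "L", "P")
  edited <- network
  pos <- test_set[test_set$label == 1L, , drop = FALSE]
  for (i in seq_len(nrow(pos)))
    if (adj[pos$lncRNA[i], pos$protein[i]] > 0)
      edited <- remove_lp_edge(edited, pos$lncRNA[i], pos$protein[i])
  test_feats <- build_feature_table(edited, test_set, paths, config$beta)
  scored <- score_pairs(clf, test_feats)
  scored$label <- test_set$label
  list(scores = scored,
       metrics = scores_to_report(test_set$label, scored$score, threshold))
}
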