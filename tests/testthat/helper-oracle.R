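# Brute-force oracles, deliberately written with explicit loops over nodes
# and walks so they stay independent of the matrix-product implementation.

# Probability distribution over end-type nodes of a type-constrained walk
# started at one node, accumulated edge by edge.
oracle_reach_row <- function(network, types, start_id) {
  ids <- names(network$index[[types[1L]]])
  v <- stats::setNames(rep(0, length(ids)), ids)
  v[start_id] <- 1
  if (length(types) == 1L) return(v)
  for (k in seq_len(length(types) - 1L)) {
    A <- relation_matrix(network, types[k], types[k + 1L])
    nxt <- stats::setNames(rep(0, ncol(A)), colnames(A))
    for (i in rownames(A)) {
      if (v[[i]] == 0) next
      deg <- sum(A[i, ])
      if (deg == 0) next
      for (j in colnames(A))
        nxt[[j]] <- nxt[[j]] + v[[i]] * A[i, j] / deg
    }
    v <- nxt
  }
  v
}

oracle_hetesim <- function(network, path, source_id, target_id) {
  types <- path$types
  n <- length(types) - 1L
  mids <- if (n %% 2L == 0L) n %/% 2L + 1L else c((n + 1L) %/% 2L,
                                                  (n + 3L) %/% 2L)
  total <- 0
  for (mid in mids) {
    vl <- oracle_reach_row(network, types[seq_len(mid)], source_id)
    vr <- oracle_reach_row(network, rev(types[seq(mid, n + 1L)]), target_id)
    num <- sum(vl * vr)
    denom <- sqrt(sum(vl^2)) * sqrt(sum(vr^2))
    total <- total + if (denom == 0) 0 else num / denom
  }
  total / length(mids)
}

# Trapezoidal area under an ROC curve returned by roc_auc().
trapezoid_auc <- function(roc) {
  sum(diff(roc$FPR) * (utils::head(roc$TPR, -1) + utils::tail(roc$TPR, -1)) / 2)
}
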