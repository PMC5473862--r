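two_type_toy <- function() {
  # L-P reinterpretation of the worked example so feature paths apply
  m <- matrix(c(1, 0, 0, 1,
                0, 1, 0, 0,
                0, 1, 1, 1), 3, byrow = TRUE,
              dimnames = list(c("l1", "l2", "l3"), sprintf("p%d", 1:4)))
  ll <- matrix(c(0, 1, 0,
                 1, 0, 1,
                 0, 1, 0), 3, byrow = TRUE,
               dimnames = list(c("l1", "l2", "l3"), c("l1", "l2", "l3")))
  pp <- matrix(0, 4, 4, dimnames = list(sprintf("p%d", 1:4),
                                        sprintf("p%d", 1:4)))
  pp[cbind(c(1, 2), c(2, 1))] <- 1
  hetero_network_from_matrices(list("L|P" = m, "L|L" = ll, "P|P" = pp))
}

test_that("features are beta-damped HeteSim scores, keyed to node count", {
  net <- two_type_toy()
  pairs <- data.frame(lncRNA = "l1", protein = "p2")
  paths <- list(parse_metapath("LLP"), parse_metapath("LPP"))
  ft <- build_feature_table(net, pairs, paths, beta = 0.5)
  expect_equal(ft$columns, c("LLP", "LPP"))
  expect_equal(unname(ft$values[1, "LLP"]),
               0.5 * hetesim_pair(net, paths[[1]], "l1", "p2"),
               tolerance = 1e-12)
  expect_equal(unname(ft$values[1, "LPP"]),
               0.5 * hetesim_pair(net, paths[[2]], "l1", "p2"),
               tolerance = 1e-12)
  # beta = 1 leaves raw scores
  ft1 <- build_feature_table(net, pairs, paths, beta = 1)
  expect_equal(unname(ft1$values[1, "LLP"]),
               hetesim_pair(net, paths[[1]], "l1", "p2"), tolerance = 1e-12)
  expect_error(build_feature_table(net, data.frame(lncRNA = "lX",
                                                   protein = "p1"),
                                   paths, 0.5), "unknown lncRNA")
})

test_that("the 14-path table matches independent per-pair recomputation", {
  net <- random_lp_network(7, 6, seed = 21)
  paths <- canonical_metapaths()
  pairs <- expand.grid(lncRNA = sprintf("l%d", 1:7),
                       protein = sprintf("p%d", 1:6),
                       stringsAsFactors = FALSE)
  beta <- 0.2
  ft <- build_feature_table(net, pairs, paths, beta)
  for (r in c(1L, 9L, 25L, 42L)) {
    for (p in paths) {
      damp <- beta^(length(p$types) - 2L)
      expect_equal(unname(ft$values[r, p$name]),
                   damp * oracle_hetesim(net, p, pairs$lncRNA[r],
                                         pairs$protein[r]),
                   tolerance = 1e-10)
    }
  }
  # bounds implied by damping: beta^(k-2) per k-node path
  for (p in paths) {
    damp <- beta^(length(p$types) - 2L)
    expect_true(all(ft$values[, p$name] >= 0 &
                      ft$values[, p$name] <= damp + 1e-12))
  }
})

test_that("shrinking beta never increases a longer-path feature", {
  net <- random_lp_network(6, 5, seed = 8)
  pairs <- data.frame(lncRNA = c("l1", "l4"), protein = c("p2", "p5"))
  paths <- canonical_metapaths()
  f_hi <- build_feature_table(net, pairs, paths, beta = 0.7)$values
  f_lo <- build_feature_table(net, pairs, paths, beta = 0.3)$values
  long_cols <- names(which(nchar(colnames(f_hi)) > 3L))
  expect_true(all(f_lo[, long_cols] <= f_hi[, long_cols] + 1e-12))
})

test_that("training-pair sampling is seeded, balanced and guarded", {
  sim <- generate_network(synthetic_spec(n_lnc = 20, n_prot = 12,
                                         n_blocks = 2, seed = 4))
  net <- sim$network
  lab1 <- sample_training_pairs(net, net, 30, 30, seed = 99)
  lab2 <- sample_training_pairs(net, net, 30, 30, seed = 99)
  expect_identical(as.data.frame(lab1), as.data.frame(lab2))
  expect_equal(sum(lab1$label == 1), 30)
  expect_equal(sum(lab1$label == 0), 30)
  adj <- relation_matrix(net, "L", "P")
  pos <- lab1[lab1$label == 1, ]
  expect_true(all(adj[cbind(pos$lncRNA, pos$protein)] > 0))
  neg <- lab1[lab1$label == 0, ]
  expect_true(all(adj[cbind(neg$lncRNA, neg$protein)] == 0))
  expect_false(any(duplicated(paste(lab1$lncRNA, lab1$protein))))

  # exhaustive positive draw returns the full edge set
  n_edges <- sum(adj > 0)
  all_pos <- sample_training_pairs(net, net, n_edges, 1, seed = 1)
  expect_equal(sum(all_pos$label == 1), n_edges)
  expect_error(sample_training_pairs(net, net, n_edges + 1, 1, seed = 1),
               "positives")

  # a complete bipartite negative source has no non-edges to draw
  full <- matrix(1, 3, 3, dimnames = list(sprintf("l%d", 1:3),
                                          sprintf("p%d", 1:3)))
  net_full <- hetero_network_from_matrices(list("L|P" = full))
  expect_error(sample_training_pairs(net_full, net_full, 2, 1, seed = 1),
               "non-edges")
})

test_that("mandatory positives are forced into the draw", {
  sim <- generate_network(synthetic_spec(n_lnc = 20, n_prot = 12,
                                         n_blocks = 2, seed = 4))
  net <- sim$network
  adj <- relation_matrix(net, "L", "P")
  edges <- which(adj > 0, arr.ind = TRUE)
  gold <- data.frame(lncRNA = rownames(adj)[edges[1:3, 1]],
                     protein = colnames(adj)[edges[1:3, 2]])
  lab <- sample_training_pairs(net, net, 10, 10, seed = 2,
                               mandatory_positives = gold)
  keys <- paste(lab$lncRNA, lab$protein)[lab$label == 1]
  expect_true(all(paste(gold$lncRNA, gold$protein) %in% keys))
  bogus <- data.frame(lncRNA = "l001", protein = "nonexistent")
  expect_error(sample_training_pairs(net, net, 10, 10, seed = 2,
                                     mandatory_positives = bogus),
               "not edges")
})

test_that("balanced subsampling of a labeled set is seeded and exact", {
  sim <- generate_network(synthetic_spec(n_lnc = 16, n_prot = 8,
                                         n_blocks = 2, seed = 5))
  sub1 <- subsample_labeled(sim$truth, 20, 20, seed = 3)
  sub2 <- subsample_labeled(sim$truth, 20, 20, seed = 3)
  expect_identical(as.data.frame(sub1), as.data.frame(sub2))
  expect_equal(table(sub1$label), table(factor(c(rep(0, 20), rep(1, 20)))),
               ignore_attr = TRUE)
  expect_error(subsample_labeled(sim$truth, 1e6, 1, seed = 1), "more pairs")
})

test_that("a separable problem trains to perfect self-consistency", {
  values <- withr::with_seed(12, rbind(matrix(stats::runif(40, 0.7, 1), 20, 2),
                                       matrix(stats::runif(40, 0, 0.3), 20, 2)))
  colnames(values) <- c("LLP", "LPP")
  pairs <- data.frame(lncRNA = sprintf("l%d", 1:40),
                      protein = sprintf("p%d", 1:40))
  ft <- structure(list(pairs = pairs, columns = colnames(values),
                       values = values, beta = 0.2),
                  class = "feature_table")
  lab <- structure(cbind(pairs, label = rep(c(1L, 0L), each = 20)),
                   class = c("labeled_pair_set", "data.frame"))
  clf <- train_classifier(ft, lab, classifier_config(seed = 1))
  sc <- score_pairs(clf, ft)
  expect_equal(as.integer(sc$score > 0), lab$label)
  # scoring is deterministic: duplicated rows get identical scores
  ft2 <- ft
  ft2$values <- ft$values[c(1, 1, 21, 21), ]
  ft2$pairs <- ft$pairs[c(1, 1, 21, 21), ]
  sc2 <- score_pairs(clf, ft2)
  expect_equal(sc2$score[1], sc2$score[2])
  expect_equal(sc2$score[3], sc2$score[4])
  expect_gt(sc2$score[1], sc2$score[3])

  one_class <- lab
  one_class$label <- 1L
  expect_error(train_classifier(ft, one_class, classifier_config()),
               "single class")
})

test_that("scoring enforces the training column schema", {
  net <- random_lp_network(5, 4, seed = 30)
  lab <- sample_training_pairs(net, net, 5, 5, seed = 1)
  paths <- canonical_metapaths()
  ft <- build_feature_table(net, lab, paths, 0.2)
  clf <- train_classifier(ft, lab, classifier_config(seed = 1))
  permuted <- ft
  permuted$columns <- rev(ft$columns)
  permuted$values <- ft$values[, rev(colnames(ft$values))]
  expect_error(score_pairs(clf, permuted), "columns do not match")
})

test_that("candidate ranking is descending with id tie-breaks", {
  sim <- generate_network(synthetic_spec(n_lnc = 16, n_prot = 10,
                                         n_blocks = 2, seed = 6))
  net <- sim$network
  lab <- subsample_labeled(sim$truth, 30, 30, seed = 2)
  ft <- build_feature_table(net, lab, canonical_metapaths(), 0.2)
  clf <- train_classifier(ft, lab, classifier_config(seed = 2))
  ranked <- rank_candidate_proteins(net, clf, "l001")
  expect_equal(nrow(ranked), 10)
  expect_equal(ranked$rank, 1:10)
  expect_true(all(diff(ranked$score) <= 0))
  ties <- ranked$protein[duplicated(ranked$score) |
                           duplicated(ranked$score, fromLast = TRUE)]
  if (length(ties) > 1) expect_equal(ties, sort(ties))
  # a same-block protein should outrank a cross-block one
  expect_lt(ranked$rank[ranked$protein == "p001"],
            ranked$rank[ranked$protein == "p002"])
  expect_error(rank_candidate_proteins(net, clf, "zzz"), "unknown lncRNA")
})

test_that("end-to-end training is reproducible given config and seed", {
  sim <- generate_network(synthetic_spec(n_lnc = 16, n_prot = 10,
                                         n_blocks = 2, seed = 6))
  run <- function() {
    lab <- subsample_labeled(sim$truth, 20, 20, seed = 5)
    ft <- build_feature_table(sim$network, lab, canonical_metapaths(), 0.2)
    clf <- train_classifier(ft, lab, classifier_config(seed = 5))
    score_pairs(clf, ft)$score
  }
  expect_identical(run(), run())
})
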