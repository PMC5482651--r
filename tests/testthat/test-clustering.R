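test_that("sample distances match a brute-force double loop", {
  m1 <- matrix(c(0, 0), 1, 2, dimnames = list("P1", c("a", "b")))
  expect_equal(as.matrix(euclidean_distances(m1))["a", "b"], 0)
  m2 <- matrix(c(0, 3), 1, 2, dimnames = list("P1", c("a", "b")))
  expect_equal(as.matrix(euclidean_distances(m2))["a", "b"], 3)

  set.seed(14)
  m <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("P", 1:10), paste0("S", 1:6)))
  d <- as.matrix(euclidean_distances(m))
  for (i in 1:6) {
    for (j in 1:6) {
      expect_equal(d[i, j], sqrt(sum((m[, i] - m[, j])^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("complete linkage agrees with a naive agglomerator", {
  # 1-D points: the two tight pairs merge first
  x <- matrix(c(0, 0.1, 10, 10.1), 1, 4,
              dimnames = list("P1", paste0("S", 1:4)))
  tree <- complete_linkage(euclidean_distances(x))
  expect_equal(sort(tree$height[1:2]), c(0.1, 0.1))
  expect_equal(unname(cutree(tree, 2)), c(1, 1, 2, 2))

  # two samples: one merge at their distance
  x2 <- matrix(c(1, 4), 1, 2, dimnames = list("P1", c("a", "b")))
  tree2 <- complete_linkage(euclidean_distances(x2))
  expect_equal(tree2$height, 3)

  set.seed(23)
  for (rep in 1:3) {
    m <- matrix(rnorm(12 * 5), 5, 12,
                dimnames = list(paste0("P", 1:5), paste0("S", 1:12)))
    d <- euclidean_distances(m)
    tree <- complete_linkage(d)
    ref <- complete_linkage_reference(d)
    expect_equal(tree$height, ref$heights, tolerance = 1e-12)
    for (step in seq_len(10)) {  # partition after each merge
      k <- 12 - step
      expect_equal(canonical_partition(labels_to_partition(cutree(tree, k))),
                   canonical_partition(ref$partitions[[step]]))
    }
    # heights are monotone non-decreasing
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("CH index matches its scatter-matrix definition", {
  data <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  labels <- c(1, 1, 2, 2)
  expect_equal(ch_index(data, labels), 20000, tolerance = 1e-9)

  set.seed(9)
  m <- matrix(rnorm(40), 10, 4)
  for (k in 2:4) {
    labels <- cutree(complete_linkage(dist(m)), k)
    expect_equal(ch_index(m, labels), ch_reference(m, labels),
                 tolerance = 1e-9)
  }
  # structured labels beat random labels on separated data
  blob <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 8), 10, 2))
  good <- rep(1:2, each = 10)
  expect_gt(ch_index(blob, good), ch_index(blob, rep(1:2, 10)))
  # zero within-scatter yields the +Inf sentinel
  dup <- matrix(c(0, 0, 5, 5), 4, 1)
  expect_equal(ch_index(dup, c(1, 1, 2, 2)), Inf)
})

test_that("CH selection recovers three planted clusters", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    centers <- matrix(c(0, 6, 12), 3, 10)
    m <- t(centers[rep(1:3, each = 8), ] + rnorm(24 * 10, sd = 0.8))
    colnames(m) <- paste0("S", 1:24)
    rownames(m) <- paste0("P", 1:10)
    select_k(m, k_range = 2:8)$k_best == 3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("CH selection is invariant to sample duplication", {
  set.seed(61)
  m <- t(matrix(c(0, 7), 2, 6)[rep(1:2, each = 6), ] + rnorm(72, sd = 0.5))
  colnames(m) <- paste0("S", 1:12)
  rownames(m) <- paste0("P", 1:6)
  dup <- cbind(m, m)
  colnames(dup) <- paste0("S", 1:24)
  expect_equal(select_k(dup, k_range = 2:6)$k_best,
               select_k(m, k_range = 2:6)$k_best)
})

test_that("cluster contrasts flag planted differences with the right sign", {
  sim <- simulate_array(array_sim_config(n_probes = 60, n_human_probes = 6,
                                         n_cancer = 12, n_matched = 2,
                                         n_nonmatched = 2, seed = 19))
  norm <- normalize_signals(sim$experiment, sim$annotation)
  cancer <- names(norm$groups)[norm$groups == "cancer"]
  n <- norm$n[, cancer]
  # plant one taxon higher in the second half of the cancer samples
  taxon_probes <- sim$annotation$probe_id[sim$annotation$taxon == "fillertaxon001"]
  n[taxon_probes, 7:12] <- n[taxon_probes, 7:12] + 4
  norm2 <- as_norm(n, stats::setNames(rep("cancer", 12), cancer))
  assignments <- stats::setNames(rep(c("c1", "c2"), each = 6), cancer)
  res <- cluster_contrasts(norm2, assignments, sim$annotation)
  hit <- res[res$taxon == "fillertaxon001", ]
  expect_true(hit$detected)
  expect_lt(hit$logFC, 0)  # higher in cluster 2 = negative c1 - c2 contrast

  # copied columns: the two clusters are identical, nothing is detected
  n_same <- cbind(norm$n[, cancer[1:6]], norm$n[, cancer[1:6]])
  colnames(n_same) <- cancer
  norm3 <- as_norm(n_same, stats::setNames(rep("cancer", 12), cancer))
  res_same <- cluster_contrasts(norm3, assignments, sim$annotation)
  expect_true(all(!res_same$detected))

  # undersized clusters are excluded with a warning
  bad <- stats::setNames(c("c1", rep("c2", 11)), cancer)
  expect_warning(expect_error(cluster_contrasts(norm2, bad, sim$annotation),
                              "at least two clusters"),
                 "fewer than 2")
})
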