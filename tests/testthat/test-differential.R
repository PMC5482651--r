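test_that("Welch t test matches its closed form and stats::t.test", {
  res <- welch_t_test(c(1, 2, 3), c(3, 4, 5))
  expect_equal(res$t, -2.449490, tolerance = 1e-6)
  expect_equal(res$df, 4.0, tolerance = 1e-9)
  expect_equal(res$p, 0.07048399, tolerance = 1e-6)

  # identical samples are uninformative
  res0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)

  # oracle: stats::t.test over random rows, Welch and Student forms
  set.seed(101)
  for (i in 1:10) {
    x <- rnorm(7, sd = runif(1, 0.5, 2))
    y <- rnorm(5, mean = runif(1, -1, 1))
    for (ve in c(FALSE, TRUE)) {
      mine <- welch_t_test(x, y, var_equal = ve)
      ref <- stats::t.test(x, y, var.equal = ve)
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("Welch p-value agrees with a permutation test", {
  set.seed(77)
  gaps <- replicate(5, {
    x <- rnorm(10); y <- rnorm(10)
    abs(welch_t_test(x, y)$p - permutation_p(x, y, n_perm = 10000))
  })
  expect_lt(mean(gaps), 0.02)
})

test_that("BH adjustment reproduces the hand step-up rule", {
  expect_equal(bh_adjust(c(0.02, 0.04)), c(0.04, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  p <- runif(50)
  expect_equal(bh_adjust(p), bh_reference(p), tolerance = 1e-12)
  # permutation invariance
  perm <- sample.int(50)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  # adjusted values never fall below the raw ones
  expect_true(all(bh_adjust(p) >= p))
})

test_that("detection applies the conjunctive adjusted-p / logFC gate", {
  # one strongly planted taxon among nulls
  taxa <- data.frame(name = "Planted", family = "PlantedFam",
                     group = "grp", kingdom = "virus", n_probes = 5,
                     planted_group = "cancer", effect_size = 3,
                     prevalence_target = 1)
  hits <- vapply(1:20, function(s) {
    sim <- simulate_array(array_sim_config(n_probes = 100,
                                           n_human_probes = 10,
                                           n_cancer = 6, n_matched = 3,
                                           n_nonmatched = 3, taxa = taxa,
                                           seed = 1000 + s))
    norm <- normalize_signals(sim$experiment, sim$annotation)
    st <- detect_signatures(norm)
    all(st$detected[match(strsplit(sim$truth$probes, ";")[[1]],
                          st$probe_id)])
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # sub-threshold fold change is never detected, however small p is
  taxa$effect_size <- 0.4
  sim <- simulate_array(array_sim_config(n_probes = 50, n_human_probes = 5,
                                         n_cancer = 10, n_matched = 5,
                                         n_nonmatched = 5, taxa = taxa,
                                         noise_sd = 0.01, seed = 2))
  norm <- normalize_signals(sim$experiment, sim$annotation)
  st <- detect_signatures(norm)
  planted <- strsplit(sim$truth$probes, ";")[[1]]
  expect_true(all(st$p_adj[match(planted, st$probe_id)] < 0.05))
  expect_false(any(st$detected[match(planted, st$probe_id)]))

  # a group with fewer than 2 samples is a hard error
  sim1 <- simulate_array(array_sim_config(n_probes = 20, n_human_probes = 2,
                                          n_cancer = 1, n_matched = 2,
                                          n_nonmatched = 2, seed = 3))
  norm1 <- normalize_signals(sim1$experiment, sim1$annotation)
  expect_error(detect_signatures(norm1), "at least 2 samples")
})

test_that("raising the fold-change gate never adds detections", {
  sim <- simulate_array(array_sim_config(n_probes = 200, n_human_probes = 10,
                                         n_cancer = 8, n_matched = 4,
                                         n_nonmatched = 4, seed = 11))
  norm <- normalize_signals(sim$experiment, sim$annotation)
  det_gated <- detect_signatures(norm, lambda = 0.5)$detected
  det_free <- detect_signatures(norm, lambda = 0)$detected
  expect_true(all(det_free[det_gated]))
})

test_that("control-side detection uses the nominal p value", {
  sim <- simulate_array(array_sim_config(n_probes = 200, n_human_probes = 10,
                                         n_cancer = 8, n_matched = 4,
                                         n_nonmatched = 4, seed = 12))
  norm <- normalize_signals(sim$experiment, sim$annotation)
  st <- detect_signatures(norm, "control_vs_cancer",
                          control_group = "matched_control")
  expect_equal(st$detected, st$p < 0.05 & st$logFC > 0.5)
})

test_that("prevalence counts present samples and rounds to integer percent", {
  # direct construction: taxon A present in 10 of 11 cancer samples
  samples <- sprintf("S%02d", 1:11)
  n <- matrix(-1, 2, 11, dimnames = list(c("P1", "P2"), samples))
  n["P1", 1:10] <- 3
  n["P2", ] <- 3  # taxon B present everywhere
  groups <- stats::setNames(rep("cancer", 11), samples)
  ann <- probe_annotation(c("P1", "P2"), c("A", "B"), c("TaxA", "TaxB"),
                          c("FamA", "FamB"), c("G", "G"),
                          c("virus", "virus"), c("specific", "specific"),
                          "m", c(1, 100), c(60, 159))
  st <- data.frame(probe_id = c("P1", "P2"), detected = c(TRUE, TRUE))
  prev <- compute_prevalence(as_norm(n, groups), ann, st)
  expect_equal(prev$prevalence[prev$taxon == "TaxA"], 91L)  # 10/11
  expect_equal(prev$prevalence[prev$taxon == "TaxB"], 100L)
  # a taxon with no detected probes is excluded
  st2 <- data.frame(probe_id = c("P1", "P2"), detected = c(TRUE, FALSE))
  prev2 <- compute_prevalence(as_norm(n, groups), ann, st2)
  expect_false("TaxB" %in% prev2$taxon)
})

test_that("planted prevalence is recovered within 5 points", {
  taxa <- data.frame(name = "Planted", family = "PlantedFam",
                     group = "grp", kingdom = "virus", n_probes = 10,
                     planted_group = "cancer", effect_size = 3,
                     prevalence_target = 0.6)
  recovered <- vapply(1:5, function(s) {
    sim <- simulate_array(array_sim_config(n_probes = 200,
                                           n_human_probes = 10,
                                           n_cancer = 20, n_matched = 10,
                                           n_nonmatched = 10, taxa = taxa,
                                           seed = 400 + s))
    norm <- normalize_signals(sim$experiment, sim$annotation)
    st <- detect_signatures(norm)
    prev <- compute_prevalence(norm, sim$annotation, st)
    prev$prevalence[prev$taxon == "Planted"]
  }, integer(1))
  expect_true(all(abs(recovered - 60L) <= 5L))
})

test_that("signal aggregation means probes and sums families", {
  st <- data.frame(probe_id = c("P1", "P2", "P3"),
                   mean_case = c(2, 4, 1.5),
                   detected = TRUE)
  ann <- probe_annotation(c("P1", "P2", "P3"), "A", c("T1", "T1", "T2"),
                          c("F1", "F1", "F2"), c("G1", "G1", "G1"),
                          "virus", "specific", "m",
                          c(1, 100, 200), c(60, 159, 259))
  fam <- aggregate_signal(st, ann, "family")
  expect_equal(fam$avg_signal[fam$family == "F1"], 3.0)  # mean(2, 4)
  grp <- aggregate_signal(st, ann, "group")
  expect_equal(grp$avg_signal, 4.5)  # 3.0 + 1.5
  # descending order and permutation invariance
  perm <- st[c(3, 1, 2), ]
  expect_equal(aggregate_signal(perm, ann, "family"), fam)
  expect_true(all(diff(fam$avg_signal) <= 0))
})
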