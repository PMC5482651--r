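test_that("seven-way partition reproduces the published counts", {
  fix <- load_table1_fixture()
  bact <- membership_detected_sets(fix, "bacteria")
  cmp <- compare_sets(bact$cancer, bact$mc, bact$nc)
  expect_equal(unname(cmp$counts["only_cancer"]), 52L)
  expect_equal(unname(cmp$counts["cancer_nc"]), 5L)
  expect_equal(unname(cmp$counts["cancer_mc"]), 3L)
  expect_equal(unname(cmp$counts["all_three"]), 0L)

  fung <- membership_detected_sets(fix, "fungus")
  expect_equal(unname(compare_sets(fung$cancer, fung$mc,
                                   fung$nc)$counts["only_cancer"]), 18L)
  vir <- membership_detected_sets(fix, "virus")
  expect_equal(unname(compare_sets(vir$cancer, vir$mc,
                                   vir$nc)$counts["only_cancer"]), 10L)
})

test_that("partition is exhaustive, disjoint, and input-order invariant", {
  cmp <- compare_sets(character(0), character(0), character(0))
  expect_true(all(cmp$counts == 0))

  set.seed(8)
  pool <- paste0("tax", 1:30)
  ca <- sample(pool, 15); mc <- sample(pool, 10); nc <- sample(pool, 12)
  cmp <- compare_sets(ca, mc, nc)
  members <- unlist(cmp$sets, use.names = FALSE)
  expect_equal(anyDuplicated(members), 0L)
  expect_setequal(members, union(ca, union(mc, nc)))
  # duplicates and order do not matter
  cmp2 <- compare_sets(rev(c(ca, ca[1])), sample(mc), c(nc, nc))
  expect_equal(cmp2$counts, cmp$counts)
  expect_equal(lapply(cmp2$sets, sort), lapply(cmp$sets, sort))
})

test_that("phylum distribution reproduces the published percentages", {
  fix <- load_table1_fixture()
  bact <- membership_detected_sets(fix, "bacteria")
  cmp <- compare_sets(bact$cancer, bact$mc, bact$nc)
  dist <- phylum_distribution(cmp, attr(fix, "phylum_of"))
  expect_equal(unname(dist["Proteobacteria"]), 52L)  # 31/60
  expect_equal(unname(dist["Firmicutes"]), 22L)      # 13/60

  toy <- compare_sets(c("a", "b"), character(0), character(0))
  expect_equal(unname(phylum_distribution(toy, c(a = "X", b = "X"))["X"]),
               100L)
  expect_error(phylum_distribution(toy, c(a = "X")), "b")
})

test_that("tumorigenic fraction of cancer-detected viral families is 23%", {
  fix <- load_table1_fixture()
  vir <- membership_detected_sets(fix, "virus")
  cmp <- compare_sets(vir$cancer, vir$mc, vir$nc)
  expect_equal(tumorigenic_fraction(cmp), 23L)  # 6 of 26
  expect_equal(tumorigenic_fraction(cmp, tumorigenic = "Nosuchviridae"), 0L)
  expect_equal(tumorigenic_fraction(cmp, tumorigenic = c(
    vir$cancer)), 100L)
  empty <- compare_sets(character(0), "x", "y")
  expect_error(tumorigenic_fraction(empty), "no cancer-detected")
})

test_that("planted group-specific taxa recover their set structure", {
  taxa <- data.frame(
    name = c("OnlyCancer", "Shared", "OnlyMC"),
    family = paste0("Fam", 1:3), group = "grp", kingdom = "bacteria",
    n_probes = 6,
    planted_group = c("cancer", "cancer", "matched_control"),
    effect_size = 4, prevalence_target = 1)
  # "Shared" planted in both cancer and matched controls
  taxa <- rbind(taxa, within(taxa[2, ], planted_group <- "matched_control"))
  sim <- simulate_array(array_sim_config(n_probes = 100, n_human_probes = 10,
                                         n_cancer = 8, n_matched = 6,
                                         n_nonmatched = 6, taxa = taxa,
                                         noise_sd = 0.3, seed = 31))
  norm <- normalize_signals(sim$experiment, sim$annotation)
  det_taxa <- function(...) {
    st <- detect_signatures(norm, ...)
    unique(sim$annotation$taxon[match(st$probe_id[st$detected],
                                      sim$annotation$probe_id)])
  }
  ca <- det_taxa("cancer_vs_controls")
  mc <- det_taxa("control_vs_cancer", control_group = "matched_control")
  nc <- det_taxa("control_vs_cancer", control_group = "nonmatched_control")
  cmp <- compare_sets(intersect(ca, taxa$name), intersect(mc, taxa$name),
                      intersect(nc, taxa$name))
  expect_true("OnlyCancer" %in% cmp$sets$only_cancer)
  expect_true("OnlyMC" %in% cmp$sets$only_mc)
  # Shared has cancer-elevated probes and MC-elevated probes, so both
  # one-sided contrasts flag it and it lands in the cancer+MC region
  expect_true("Shared" %in% cmp$sets$cancer_mc)
})
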