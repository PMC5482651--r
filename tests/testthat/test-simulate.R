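test_that("the array generator is deterministic under a fixed seed", {
  cfg <- array_sim_config(n_probes = 60, n_human_probes = 6, n_cancer = 4,
                          n_matched = 3, n_nonmatched = 3, seed = 17)
  a <- simulate_array(cfg)
  b <- simulate_array(cfg)
  expect_identical(a$experiment$green, b$experiment$green)
  expect_identical(a$experiment$red, b$experiment$red)
  expect_identical(a$truth, b$truth)
  c <- simulate_array(array_sim_config(n_probes = 60, n_human_probes = 6,
                                       n_cancer = 4, n_matched = 3,
                                       n_nonmatched = 3, seed = 18))
  expect_false(identical(a$experiment$green, c$experiment$green))
})

test_that("array configs are validated before any output", {
  expect_error(array_sim_config(seed = 1, noise_sd = 0), "noise_sd")
  expect_error(array_sim_config(seed = 1, taxa = data.frame(
    name = "t", family = "f", group = "g", kingdom = "virus", n_probes = 5,
    planted_group = "cancer", effect_size = -1, prevalence_target = 0.5)),
    "effect_size")
  expect_error(array_sim_config(seed = 1, taxa = data.frame(
    name = "t", family = "f", group = "g", kingdom = "virus", n_probes = 5,
    planted_group = "cancer", effect_size = 1, prevalence_target = 1.5)),
    "prevalence_target")
  expect_error(array_sim_config(seed = 1, n_probes = 4, taxa = data.frame(
    name = "t", family = "f", group = "g", kingdom = "virus", n_probes = 5,
    planted_group = "cancer", effect_size = 1, prevalence_target = 0.5)),
    "exceed")
  expect_error(array_sim_config(n_probes = 10), "seed")
})

test_that("a null simulation stays near the nominal false-positive level", {
  # no planted effects: BH + fold-change gate yields almost no detections
  n_det <- vapply(1:5, function(s) {
    sim <- simulate_array(array_sim_config(n_probes = 500,
                                           n_human_probes = 10,
                                           n_cancer = 10, n_matched = 5,
                                           n_nonmatched = 5, seed = 500 + s))
    norm <- normalize_signals(sim$experiment, sim$annotation)
    sum(detect_signatures(norm)$detected)
  }, numeric(1))
  expect_lte(mean(n_det), 0.05 * 500)
})

test_that("reference simulation is deterministic with balanced composition", {
  cfg <- read_sim_config(seed = 33)
  refs <- simulate_references(cfg)
  refs2 <- simulate_references(cfg)
  expect_identical(refs$viral, refs2$viral)
  expect_identical(refs$host, refs2$host)
  expect_identical(refs$genes, refs2$genes)
  # GC content of a 100 kb uniform sequence is 0.5 within binomial error
  gc <- mean(strsplit(refs$host[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.02)
  expect_error(simulate_references(read_sim_config(
    seed = 1, chrom_length = 5000, genes_per_chrom = 3, gene_length = 4000)),
    "infeasible gene packing")
})

test_that("simulated references round-trip through the format readers", {
  refs <- simulate_references(read_sim_config(seed = 34))
  dir <- withr::local_tempdir()
  fa_v <- file.path(dir, "viral.fasta")
  fa_h <- file.path(dir, "host.fasta")
  gff <- file.path(dir, "genes.gff3")
  write_sequences(refs$viral, fa_v)
  write_sequences(refs$host, fa_h)
  write_gene_models_gff3(refs$genes, gff)
  expect_equal(as.character(read_sequences(fa_v)), refs$viral)
  expect_equal(as.character(read_sequences(fa_h)), refs$host)
  back <- read_gene_models(gff)
  expect_equal(back$genes[order(back$genes$gene_id), ],
               refs$genes$genes[order(refs$genes$genes$gene_id), ],
               ignore_attr = TRUE)
})

test_that("read simulation honours breakpoint margins and seeds", {
  refs <- simulate_references(read_sim_config(seed = 35))
  bad <- data.frame(virus = "virus1", virus_pos = 50, host_chrom = "chr1",
                    host_pos = 5000, n_spanning_reads = 2)
  expect_error(simulate_reads(refs, read_sim_config(seed = 35,
                                                    integrations = bad)),
               "virus1:50")
  set.seed(36)
  ints <- sample_integration_sites(refs, 2, n_spanning_reads = 4)
  cfg <- read_sim_config(seed = 37, integrations = ints,
                         n_background_host = 10, n_background_virus = 10)
  r1 <- simulate_reads(refs, cfg)
  r2 <- simulate_reads(refs, cfg)
  expect_identical(as.character(r1$reads), as.character(r2$reads))
  expect_equal(r1$truth, ints)
  # read count is planted spanning reads plus background
  expect_length(r1$reads, sum(ints$n_spanning_reads) + 20)
})
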