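make_alignment <- function(read_seq, ref = "V", ref_start, ref_end,
                           read_start, read_end, cigar) {
  structure(list(read_id = "r1", ref = ref, strand = "+", score = 0L,
                 ref_start = ref_start, ref_end = ref_end,
                 read_start = read_start, read_end = read_end,
                 cigar = cigar, n_match = NA, n_mismatch = NA, n_gap = 0L,
                 second_score = 0L, read_seq = read_seq),
            class = "alignment")
}

test_that("terminal soft clips are extracted with their anchors", {
  seq100 <- strrep("A", 100)
  right <- make_alignment(seq100, ref_start = 941, ref_end = 1000,
                          read_start = 1, read_end = 60, cigar = "60M40S")
  clips <- extract_soft_clips(right)
  expect_equal(nrow(clips), 1)
  expect_equal(clips$side, "right")
  expect_equal(nchar(clips$clip_seq), 40)
  expect_equal(clips$anchor_ref_coord, 1000)

  left <- make_alignment(seq100, ref_start = 200, ref_end = 269,
                         read_start = 31, read_end = 100, cigar = "30S70M")
  clips_l <- extract_soft_clips(left)
  expect_equal(clips_l$side, "left")
  expect_equal(clips_l$anchor_ref_coord, 200)

  full <- make_alignment(seq100, ref_start = 1, ref_end = 100,
                         read_start = 1, read_end = 100, cigar = "100M")
  expect_equal(nrow(extract_soft_clips(full)), 0)

  short <- make_alignment(seq100, ref_start = 1, ref_end = 90,
                          read_start = 11, read_end = 100, cigar = "10S90M")
  expect_equal(nrow(extract_soft_clips(short, min_clip = 20)), 0)
})

test_that("clips map uniquely to the host or are suppressed", {
  set.seed(51)
  host <- random_seqs(1, 8000, "chr")
  clip <- substr(host[[1]], 3001, 3040)
  hit <- map_clip_to_host(clip, host)
  expect_equal(hit$chrom, "chr1")
  expect_equal(hit$start, 3001)

  # one substitution in 40 bp: identity 0.975 still maps
  clip_mm <- clip
  substr(clip_mm, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                     substr(clip_mm, 20, 20))[1]
  hit_mm <- map_clip_to_host(clip_mm, host)
  expect_equal(hit_mm$start, 3001)
  expect_lt(hit_mm$identity, 1)

  # a clip present at two loci is ambiguous and suppressed
  host2 <- host
  host2[[1]] <- paste0(substr(host2[[1]], 1, 6000), clip,
                       substr(host2[[1]], 6041, 8000))
  expect_null(map_clip_to_host(clip, host2))
})

test_that("planted integrations are called exactly with summed support", {
  refs <- simulate_references(read_sim_config(seed = 71))
  set.seed(72)
  ints <- sample_integration_sites(refs, 1, n_spanning_reads = 8)
  cfg <- read_sim_config(seed = 73, integrations = ints,
                         n_background_host = 30, n_background_virus = 30)
  rs <- simulate_reads(refs, cfg)
  calls <- call_integrations(as.character(rs$reads), refs$viral, refs$host)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$virus, ints$virus)
  expect_equal(calls$virus_bp, ints$virus_pos)
  expect_equal(calls$chrom, ints$host_chrom)
  expect_equal(calls$host_bp, ints$host_pos)
  expect_equal(calls$support, 8L)
})

test_that("pure background reads never produce calls", {
  refs <- simulate_references(read_sim_config(seed = 74))
  cfg <- read_sim_config(seed = 75, integrations = NULL,
                         n_background_host = 150, n_background_virus = 150)
  rs <- simulate_reads(refs, cfg)
  calls <- call_integrations(as.character(rs$reads), refs$viral, refs$host)
  expect_equal(nrow(calls), 0)
})

test_that("multiple integrations tally by chromosome", {
  refs <- simulate_references(read_sim_config(seed = 76))
  set.seed(77)
  repeat {  # two integrations on distinct chromosomes
    ints <- sample_integration_sites(refs, 2, n_spanning_reads = 5)
    if (length(unique(ints$host_chrom)) == 2) break
  }
  cfg <- read_sim_config(seed = 78, integrations = ints,
                         n_background_host = 20, n_background_virus = 20)
  rs <- simulate_reads(refs, cfg)
  calls <- call_integrations(as.character(rs$reads), refs$viral, refs$host)
  expect_equal(nrow(calls), 2)
  tal <- tally_by_chromosome(calls)
  expect_setequal(tal$chrom, ints$host_chrom)
  expect_true(all(tal$n_insertions == 1))
  expect_equal(nrow(tally_by_chromosome(calls[0, ])), 0)

  direct <- data.frame(chrom = c("chr1", "chr1", "chr1", "chrX"))
  tal2 <- tally_by_chromosome(direct)
  expect_equal(tal2$n_insertions[tal2$chrom == "chr1"], 3L)
  expect_equal(tal2$n_insertions[tal2$chrom == "chrX"], 1L)
})

test_that("breakpoints get their strand-aware gene context", {
  genes <- gene_model_set(
    data.frame(gene_id = c("gPlus", "gMinus"), chrom = "chr1",
               strand = c("+", "-"), start = c(10000, 50000),
               end = c(12000, 52000)),
    data.frame(gene_id = c("gPlus", "gMinus"), start = c(10000, 50000),
               end = c(10500, 50200)))
  expect_equal(annotate_breakpoint("chr1", 10250, genes)$relation, "exonic")
  expect_equal(annotate_breakpoint("chr1", 11000, genes)$relation, "intronic")
  up <- annotate_breakpoint("chr1", 9000, genes)
  expect_equal(up$relation, "upstream")
  expect_equal(up$distance, 1000L)
  down <- annotate_breakpoint("chr1", 13000, genes)
  expect_equal(down$relation, "downstream")
  # minus-strand gene: upstream lies at higher coordinates
  up_m <- annotate_breakpoint("chr1", 53000, genes)
  expect_equal(up_m$relation, "upstream")
  expect_equal(up_m$gene_id, "gMinus")
  down_m <- annotate_breakpoint("chr1", 49000, genes)
  expect_equal(down_m$relation, "downstream")
  far <- annotate_breakpoint("chr1", 500000, genes)
  expect_equal(far$relation, "intergenic")
  expect_true(is.na(far$gene_id))
})

test_that("region read counts assign each read to its best region", {
  aln <- data.frame(found = TRUE, ref = c("v1", "v1", "v1", "v1"),
                    ref_start = c(100, 150, 180, 900),
                    ref_end = c(349, 399, 429, 1149))
  regions <- data.frame(chrom = "v1", start = c(101, 2000),
                        end = c(300, 2200), name = c("capA", "capB"))
  counts <- count_reads_in_regions(aln, regions, ref_names = "v1")
  expect_equal(counts$count[counts$name == "capA"], 3L)
  expect_equal(counts$count[counts$name == "capB"], 0L)

  # tie on overlap: the lower-start region wins
  aln2 <- data.frame(found = TRUE, ref = "v1", ref_start = 90, ref_end = 110)
  regions2 <- data.frame(chrom = "v1", start = c(81, 101), end = c(100, 120),
                         name = c("low", "high"))
  c2 <- count_reads_in_regions(aln2, regions2, ref_names = "v1")
  expect_equal(c2$count[c2$name == "low"], 1L)
  expect_equal(c2$count[c2$name == "high"], 0L)

  expect_equal(sum(count_reads_in_regions(aln[0, ], regions,
                                          ref_names = "v1")$count), 0L)
  expect_error(count_reads_in_regions(aln, data.frame(
    chrom = "nope", start = 1, end = 10), ref_names = "v1"),
    "unknown reference")
})

test_that("capture-enriched simulated reads concentrate at probe regions", {
  refs <- simulate_references(read_sim_config(seed = 81))
  cfg <- read_sim_config(seed = 82, n_background_host = 0,
                         n_background_virus = 200)
  rs <- simulate_reads(refs, cfg)
  aln <- align_reads(as.character(rs$reads), refs$viral, min_score = 30)
  counts <- count_reads_in_regions(aln, refs$capture,
                                   ref_names = names(refs$viral))
  # the capture regions hold the clear majority of the virus reads
  expect_gt(sum(counts$count), 0.6 * sum(aln$found))
})

test_that("externally supplied SAM alignments feed the call path", {
  set.seed(83)
  virus <- random_seqs(1, 3000, "V")
  host <- random_seqs(1, 9000, "chr")
  jh <- getFromNamespace("junction_homology", "pathosig")
  vp <- 1500; hp <- 4000
  repeat {
    host <- random_seqs(1, 9000, "chr")
    if (jh(virus[[1]], vp, host[[1]], hp) == 0) break
  }
  read <- paste0(substr(virus[[1]], vp - 149, vp),
                 substr(host[[1]], hp, hp + 99))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:V1\tLN:3000",
    paste("chimera", 0, "V1", vp - 149, 60, "150M100S", "*", 0, 0,
          read, strrep("I", 250), sep = "\t")), sam)
  alns <- sam_to_alignments(sam)
  expect_length(alns, 1)
  expect_equal(alns[[1]]$cigar, "150M100S")
  expect_equal(alns[[1]]$ref_end, vp)
  calls <- call_integrations(alignments = alns, viral_refs = virus,
                             host_genome = host)
  expect_equal(calls$virus_bp, vp)
  expect_equal(calls$host_bp, hp)
  expect_equal(calls$chrom, "chr1")
})
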