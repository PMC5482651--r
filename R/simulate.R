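#' Configuration for the array simulator
#'
#' Defines the study conditions the array generator emulates: a
#' desk-scale pan-pathogen array (2,000 non-human probes plus human
#' reference probes) screened over cancer, matched-control and
#' non-matched-control samples, with log-normal signal noise on the log2
#' scale and optional planted taxa whose probes are shifted by a group
#' effect in a chosen fraction of that group's samples.
#'
#' @param n_probes number of non-human probes (default 2000).
#' @param n_human_probes number of human reference probes (default 100).
#' @param n_cancer,n_matched,n_nonmatched samples per group (default
#'   20/10/10).
#' @param taxa `NULL` (null simulation) or a data.frame with columns name,
#'   family, group, kingdom, n_probes, planted_group (one of the three
#'   group labels), effect_size (log2 units, >= 0), prevalence_target
#'   (fraction in \[0, 1\]).
#' @param noise_sd per-probe log2 noise sd (default 0.5).
#' @param baseline baseline normalized log2 signal of unplanted probes
#'   (default 0: sample channel equal to the corrected reference channel).
#' @param ref_log2 log2 intensity of the red reference channel (default 10).
#' @param scale_factor planted per-sample channel scale factor s*; scalar
#'   or one value per sample (default 1.5).
#' @param human_noise_sd log2 noise on human reference probes (default 0,
#'   making s* exactly recoverable).
#' @param seed mandatory integer seed.
#' @return list of class `array_sim_config`.
#' @export
array_sim_config <- function(n_probes = 2000, n_human_probes = 100,
                             n_cancer = 20, n_matched = 10,
                             n_nonmatched = 10, taxa = NULL,
                             noise_sd = 0.5, baseline = 0, ref_log2 = 10,
                             scale_factor = 1.5, human_noise_sd = 0,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(n_probes = n_probes, n_human_probes = n_human_probes,
              n_cancer = n_cancer, n_matched = n_matched,
              n_nonmatched = n_nonmatched, taxa = taxa,
              noise_sd = noise_sd, baseline = baseline, ref_log2 = ref_log2,
              scale_factor = scale_factor, human_noise_sd = human_noise_sd,
              seed = as.integer(seed))
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.null(taxa)) {
    taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
    if (any(taxa$effect_size < 0)) stop("effect_size must be >= 0")
    if (any(taxa$prevalence_target < 0 | taxa$prevalence_target > 1)) {
      stop("prevalence_target must lie in [0, 1]")
    }
    if (sum(taxa$n_probes) > n_probes) stop("planted probes exceed n_probes")
    if (!all(taxa$planted_group %in% group_levels)) {
      stop("unknown planted_group")
    }
    cfg$taxa <- taxa
  }
  class(cfg) <- "array_sim_config"
  cfg
}

#' Simulate a two-channel array experiment with known ground truth
#'
#' Green intensities are `2^(ref_log2 + n_true + noise)` scaled by the
#' planted per-sample scale factor, red intensities are `2^ref_log2 / s*`
#' structured so that the planted scale factor is recoverable from the
#' human reference probes; the true normalized signal `n_true` is the
#' baseline plus the planted group effect for probes of a planted taxon in
#' the samples where that taxon is present. Presence is assigned to
#' exactly `round(prevalence_target * n_group)` samples of the planted
#' group. Human probes carry no group effect.
#'
#' @param config an [array_sim_config()].
#' @return list: `experiment` ([array_experiment()]), `annotation`
#'   ([probe_annotation()]), `truth` (data.frame: taxon, family, kingdom,
#'   planted_group, effect_size, prevalence_target, probe ids), `presence`
#'   (planted-taxon x sample logical matrix).
#' @export
simulate_array <- function(config) {
  stopifnot(inherits(config, "array_sim_config"))
  set.seed(config$seed)
  samples <- c(sprintf("OC%02d", seq_len(config$n_cancer)),
               sprintf("MC%02d", seq_len(config$n_matched)),
               sprintf("NC%02d", seq_len(config$n_nonmatched)))
  groups <- stats::setNames(
    rep(group_levels, c(config$n_cancer, config$n_matched,
                        config$n_nonmatched)), samples)
  n_s <- length(samples)
  s_star <- rep(config$scale_factor, length.out = n_s)

  # probe universe: planted taxa first, fillers after, then human probes
  taxa <- config$taxa
  n_planted <- if (is.null(taxa)) 0L else sum(taxa$n_probes)
  n_filler <- config$n_probes - n_planted
  probe_tab <- list()
  if (n_planted > 0) {
    probe_tab[[1]] <- data.frame(
      taxon = rep(taxa$name, taxa$n_probes),
      family = rep(taxa$family, taxa$n_probes),
      group = rep(taxa$group, taxa$n_probes),
      kingdom = rep(taxa$kingdom, taxa$n_probes),
      stringsAsFactors = FALSE)
  }
  if (n_filler > 0) {
    taxon_idx <- (seq_len(n_filler) - 1) %/% 10 + 1  # 10 probes per filler
    probe_tab[[length(probe_tab) + 1]] <- data.frame(
      taxon = sprintf("fillertaxon%03d", taxon_idx),
      family = sprintf("fillerfamily%03d", taxon_idx),
      group = "filler group",
      kingdom = c("virus", "bacteria")[(taxon_idx - 1) %% 2 + 1],
      stringsAsFactors = FALSE)
  }
  probe_tab <- do.call(rbind, probe_tab)
  probe_ids <- sprintf("P%05d", seq_len(config$n_probes))
  human_ids <- sprintf("H%04d", seq_len(config$n_human_probes))
  annotation <- probe_annotation(
    probe_id = c(probe_ids, human_ids),
    target_accession = c(paste0("ACC_", probe_tab$taxon), rep("ACC_HS", config$n_human_probes)),
    taxon = c(probe_tab$taxon, rep("Homo", config$n_human_probes)),
    family = c(probe_tab$family, rep("Hominidae", config$n_human_probes)),
    group = c(probe_tab$group, rep("human reference", config$n_human_probes)),
    kingdom = c(probe_tab$kingdom, rep("human", config$n_human_probes)),
    probe_class = c(rep(c("conserved", "specific"),
                        length.out = config$n_probes),
                    rep("human_reference", config$n_human_probes)),
    metagenome_chrom = "meta1",
    start = seq_len(config$n_probes + config$n_human_probes) * 100L,
    end = seq_len(config$n_probes + config$n_human_probes) * 100L + 59L)

  # true normalized signal
  n_true <- matrix(config$baseline, nrow = config$n_probes, ncol = n_s,
                   dimnames = list(probe_ids, samples))
  presence <- NULL
  if (n_planted > 0) {
    presence <- matrix(FALSE, nrow = nrow(taxa), ncol = n_s,
                       dimnames = list(taxa$name, samples))
    offset <- 0L
    for (ti in seq_len(nrow(taxa))) {
      rows <- offset + seq_len(taxa$n_probes[ti])
      offset <- offset + taxa$n_probes[ti]
      in_group <- which(groups == taxa$planted_group[ti])
      k <- round_half_up(taxa$prevalence_target[ti] * length(in_group))
      present <- sample(in_group, k)
      presence[ti, present] <- TRUE
      n_true[rows, present] <- n_true[rows, present] + taxa$effect_size[ti]
    }
  }
  noise <- matrix(stats::rnorm(config$n_probes * n_s, 0, config$noise_sd),
                  nrow = config$n_probes)
  red_nh <- matrix(2^config$ref_log2 / rep(s_star, each = config$n_probes),
                   nrow = config$n_probes, dimnames = list(probe_ids, samples))
  green_nh <- red_nh * rep(s_star, each = config$n_probes) *
    2^(n_true + noise)
  h_noise <- if (config$human_noise_sd > 0) {
    matrix(stats::rnorm(config$n_human_probes * n_s, 0,
                        config$human_noise_sd),
           nrow = config$n_human_probes)
  } else 0
  green_h <- matrix(2^(config$ref_log2 + h_noise),
                    nrow = config$n_human_probes, ncol = n_s,
                    dimnames = list(human_ids, samples))
  red_h <- sweep(green_h, 2, s_star, "/")
  experiment <- array_experiment(rbind(green_nh, green_h),
                                 rbind(red_nh, red_h), groups)
  truth <- if (is.null(taxa)) {
    data.frame(taxon = character(), family = character(),
               kingdom = character(), planted_group = character(),
               effect_size = numeric(), prevalence_target = numeric(),
               probes = character(), stringsAsFactors = FALSE)
  } else {
    offs <- cumsum(c(0, head(taxa$n_probes, -1)))
    data.frame(taxon = taxa$name, family = taxa$family,
               kingdom = taxa$kingdom, planted_group = taxa$planted_group,
               effect_size = taxa$effect_size,
               prevalence_target = taxa$prevalence_target,
               probes = vapply(seq_len(nrow(taxa)), function(i) {
                 paste(probe_ids[offs[i] + seq_len(taxa$n_probes[i])],
                       collapse = ";")
               }, character(1)), stringsAsFactors = FALSE)
  }
  list(experiment = experiment, annotation = annotation, truth = truth,
       presence = presence)
}

#' Configuration for the sequencing-read simulator
#'
#' @param n_viruses,virus_length viral metagenome shape (default 3 x 8 kb).
#' @param n_chroms,chrom_length host genome shape (default 2 x 100 kb).
#' @param genes_per_chrom non-overlapping genes per chromosome (default 5).
#' @param gene_length gene span in bp (default 4000).
#' @param capture_per_virus,capture_length capture-probe regions per viral
#'   reference and their width (default 3 x 200 bp).
#' @param integrations `NULL` or a data.frame with columns virus,
#'   virus_pos, host_chrom, host_pos, n_spanning_reads.
#' @param read_length read length in nt (default 250, matching deep
#'   sequencing with 250-nt reads; emitted single-end).
#' @param min_clip margin from the host-side read end within which no
#'   breakpoint is placed (default 20, so every spanning read carries a
#'   host clip long enough to extract); `read_length >= 2 * min_clip`
#'   required.
#' @param min_anchor minimum virus-side anchor length of a spanning read
#'   (default 30): at least the breakpoint caller's minimum alignment
#'   score, so that every spanning read is alignable to the virus.
#' @param n_background_host,n_background_virus pure host / pure virus
#'   background reads (default 100 each).
#' @param substitution_rate per-base substitution error rate (default 0).
#' @param seed mandatory integer seed.
#' @return list of class `read_sim_config`.
#' @export
read_sim_config <- function(n_viruses = 3, virus_length = 8000,
                            n_chroms = 2, chrom_length = 100000,
                            genes_per_chrom = 5, gene_length = 4000,
                            capture_per_virus = 3, capture_length = 200,
                            integrations = NULL, read_length = 250,
                            min_clip = 20, min_anchor = 30,
                            n_background_host = 100,
                            n_background_virus = 100,
                            substitution_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (read_length < 2 * min_clip) stop("read_length must be >= 2 * min_clip")
  if (min_anchor < min_clip) stop("min_anchor must be >= min_clip")
  if (substitution_rate < 0 || substitution_rate >= 1) {
    stop("substitution_rate must lie in [0, 1)")
  }
  structure(list(n_viruses = n_viruses, virus_length = virus_length,
                 n_chroms = n_chroms, chrom_length = chrom_length,
                 genes_per_chrom = genes_per_chrom,
                 gene_length = gene_length,
                 capture_per_virus = capture_per_virus,
                 capture_length = capture_length,
                 integrations = integrations, read_length = read_length,
                 min_clip = min_clip, min_anchor = min_anchor,
                 n_background_host = n_background_host,
                 n_background_virus = n_background_virus,
                 substitution_rate = substitution_rate,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate reference sequences, gene models and capture regions
#'
#' Uniform-random viral and host references; genes placed non-overlapping
#' on each chromosome with 1-3 exons; capture regions placed uniformly on
#' the viral references.
#'
#' @param config a [read_sim_config()].
#' @return list: `viral` and `host` (named character vectors), `genes`
#'   ([gene_model_set()]), `capture` (regions data.frame, 1-based).
#' @export
simulate_references <- function(config) {
  stopifnot(inherits(config, "read_sim_config"))
  set.seed(config$seed)
  viral <- stats::setNames(
    vapply(seq_len(config$n_viruses), function(i) random_dna(config$virus_length),
           character(1)),
    sprintf("virus%d", seq_len(config$n_viruses)))
  host <- stats::setNames(
    vapply(seq_len(config$n_chroms), function(i) random_dna(config$chrom_length),
           character(1)),
    sprintf("chr%d", seq_len(config$n_chroms)))
  slot <- config$chrom_length %/% config$genes_per_chrom
  if (slot < config$gene_length + 2) {
    stop("infeasible gene packing: ", config$genes_per_chrom, " genes of ",
         config$gene_length, " bp on a ", config$chrom_length, " bp chromosome")
  }
  genes <- list(); exons <- list()
  for (ch in seq_len(config$n_chroms)) {
    for (gi in seq_len(config$genes_per_chrom)) {
      start <- (gi - 1L) * slot +
        sample.int(slot - config$gene_length - 1L, 1)
      end <- start + config$gene_length - 1L
      gid <- sprintf("gene_%d_%d", ch, gi)
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = gid, chrom = names(host)[ch],
        strand = sample(c("+", "-"), 1), start = start, end = end,
        stringsAsFactors = FALSE)
      n_ex <- sample(1:3, 1)
      bounds <- sort(sample(seq(start, end - 1), 2 * n_ex))
      for (e in seq_len(n_ex)) {
        exons[[length(exons) + 1]] <- data.frame(
          gene_id = gid, start = bounds[2 * e - 1], end = bounds[2 * e],
          stringsAsFactors = FALSE)
      }
    }
  }
  capture <- do.call(rbind, lapply(seq_len(config$n_viruses), function(v) {
    starts <- sample.int(config$virus_length - config$capture_length,
                         config$capture_per_virus)
    data.frame(chrom = names(viral)[v], start = starts,
               end = starts + config$capture_length - 1L,
               name = sprintf("%s_cap%d", names(viral)[v],
                              seq_len(config$capture_per_virus)),
               stringsAsFactors = FALSE)
  }))
  list(viral = viral, host = host,
       genes = gene_model_set(do.call(rbind, genes), do.call(rbind, exons)),
       capture = capture)
}

substitute_bases <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1)
  }
  paste(bases, collapse = "")
}

#' Simulate capture-sequencing reads with known integration breakpoints
#'
#' For each planted integration, emits `n_spanning_reads` chimeric reads
#' whose junction (last virus base `virus_pos`, first host base
#' `host_pos`) falls at least `min_clip` bases from both read ends;
#' background reads are pure host (drawn near and away from genes) and
#' pure virus (drawn within capture regions when available, emulating
#' capture enrichment). Each read is reverse-complemented with
#' probability 1/2 and substituted at `substitution_rate`.
#'
#' @param refs output of [simulate_references()].
#' @param config a [read_sim_config()] (its `integrations`, read length,
#'   background counts and error rate are used; the seed is advanced
#'   deterministically from `config$seed`).
#' @return list: `reads` (`QualityScaledDNAStringSet`), `truth` (the
#'   integrations table with exact breakpoints).
#' @export
simulate_reads <- function(refs, config) {
  stopifnot(inherits(config, "read_sim_config"))
  set.seed(config$seed + 1L)
  L <- config$read_length
  mc <- config$min_clip
  ints <- config$integrations
  reads <- character(0)
  if (!is.null(ints) && nrow(ints) > 0) {
    for (i in seq_len(nrow(ints))) {
      v <- ints$virus[i]; vp <- ints$virus_pos[i]
      hc <- ints$host_chrom[i]; hp <- ints$host_pos[i]
      if (vp < L - mc || hp + L - mc - 1 > nchar(refs$host[[hc]])) {
        stop("breakpoint too close to a reference end for integration ",
             v, ":", vp, " | ", hc, ":", hp)
      }
      if (junction_homology(refs$viral[[v]], vp, refs$host[[hc]], hp) > 0) {
        warning("junction microhomology at integration ", v, ":", vp, " | ",
                hc, ":", hp, "; recovered breakpoints will shift by the ",
                "homology length (see sample_integration_sites)")
      }
      for (r in seq_len(ints$n_spanning_reads[i])) {
        u <- sample(seq(config$min_anchor, L - mc), 1)  # virus-side length
        seq <- paste0(substr(refs$viral[[v]], vp - u + 1, vp),
                      substr(refs$host[[hc]], hp, hp + (L - u) - 1))
        reads[sprintf("int%d_r%d", i, r)] <- seq
      }
    }
  }
  if (config$n_background_host > 0) {
    for (r in seq_len(config$n_background_host)) {
      ch <- sample(names(refs$host), 1)
      p <- sample.int(nchar(refs$host[[ch]]) - L, 1)
      reads[sprintf("hostbg_r%d", r)] <- substr(refs$host[[ch]], p, p + L - 1)
    }
  }
  if (config$n_background_virus > 0) {
    caps <- refs$capture
    for (r in seq_len(config$n_background_virus)) {
      if (!is.null(caps) && nrow(caps) > 0 && stats::runif(1) < 0.8) {
        # capture-enriched: overlap a capture region
        reg <- caps[sample.int(nrow(caps), 1), ]
        lo <- max(1, reg$start - L + 1)
        hi <- min(nchar(refs$viral[[reg$chrom]]) - L + 1, reg$end)
        p <- sample(seq(lo, hi), 1)
        v <- reg$chrom
      } else {
        v <- sample(names(refs$viral), 1)
        p <- sample.int(nchar(refs$viral[[v]]) - L, 1)
      }
      reads[sprintf("virusbg_r%d", r)] <- substr(refs$viral[[v]], p, p + L - 1)
    }
  }
  flip <- stats::runif(length(reads)) < 0.5
  for (i in which(flip)) reads[i] <- revcomp(reads[i])
  if (config$substitution_rate > 0) {
    reads[] <- vapply(reads, substitute_bases, character(1),
                      rate = config$substitution_rate)
  }
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads), function(n) strrep("I", n), character(1)))
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads), qual)
  truth <- if (is.null(ints)) {
    data.frame(virus = character(), virus_pos = integer(),
               host_chrom = character(), host_pos = integer(),
               n_spanning_reads = integer(), stringsAsFactors = FALSE)
  } else ints
  list(reads = out, truth = truth)
}

# number of bases by which a local aligner extends the virus match through
# the junction: the argmax over extension lengths of the cumulative
# match/mismatch score of host[hp..] against virus[vp+1..] (0 when no
# extension scores positive). Both reported breakpoints shift right by
# this amount, so a junction is single-base resolvable only when it is 0.
junction_homology <- function(viral_seq, vp, host_seq, hp,
                              match = 1, mismatch = -2, max_ext = 60L) {
  best_e <- 0L; best_score <- 0; cum <- 0
  for (e in seq_len(max_ext)) {
    if (vp + e > nchar(viral_seq) || hp + e - 1 > nchar(host_seq)) break
    same <- substr(viral_seq, vp + e, vp + e) ==
      substr(host_seq, hp + e - 1, hp + e - 1)
    cum <- cum + if (same) match else mismatch
    if (cum > best_score) { best_score <- cum; best_e <- e }
  }
  best_e
}

#' Draw integration sites with unambiguous junctions
#'
#' Samples planted integration breakpoints (last virus base, first host
#' base) uniformly, keeping a margin of one read length from every
#' reference end and rejecting junctions with sequence microhomology
#' (host side continuing the virus sequence), at which any local aligner
#' necessarily shifts the breakpoint — such junctions are not single-base
#' resolvable from read evidence alone. Uses the current RNG state.
#'
#' @param refs output of [simulate_references()].
#' @param n number of integrations.
#' @param read_length margin kept from reference ends (default 250).
#' @param n_spanning_reads supporting reads per integration; recycled.
#' @return integrations data.frame for [read_sim_config()].
#' @export
sample_integration_sites <- function(refs, n, read_length = 250,
                                     n_spanning_reads = 8) {
  out <- vector("list", n)
  viruses <- names(refs$viral)
  chroms <- names(refs$host)
  for (i in seq_len(n)) {
    repeat {
      v <- sample(viruses, 1)
      ch <- sample(chroms, 1)
      vp <- sample(seq(read_length, nchar(refs$viral[[v]]) - read_length), 1)
      hp <- sample(seq(read_length, nchar(refs$host[[ch]]) - read_length), 1)
      if (junction_homology(refs$viral[[v]], vp, refs$host[[ch]], hp) == 0L) break
    }
    out[[i]] <- data.frame(virus = v, virus_pos = vp, host_chrom = ch,
                           host_pos = hp, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out$n_spanning_reads <- rep(n_spanning_reads, length.out = n)
  out
}
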