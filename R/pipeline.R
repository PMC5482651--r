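#' End-to-end array analysis
#'
#' Runs the full microarray branch on an [array_experiment()]: scale
#' factors from human reference probes, normalization, cancer-side
#' detection (BH-adjusted) and the two control-side detections (nominal),
#' prevalence and taxon/family/group aggregation for the cancer
#' signatures, the per-kingdom seven-way set partition, and hierarchical
#' clustering of the cancer samples with CH-index selection of k. When
#' `outdir` is given every stage result is written as TSV together with a
#' YAML manifest (parameters and per-stage record counts).
#'
#' @param experiment an [array_experiment()].
#' @param annotation a [probe_annotation()].
#' @param alpha,lambda,theta,eps analysis parameters (defaults 0.05, 0.5,
#'   0.5, 1).
#' @param scale_method see [compute_scale_factor()].
#' @param k_range candidate cluster numbers (default 2:10).
#' @param outdir optional output directory.
#' @return list: scale_factors, norm, stats_cancer, stats_mc, stats_nc,
#'   prevalence, taxa, families, groups_table, comparison (per kingdom),
#'   clusters.
#' @export
run_array_pipeline <- function(experiment, annotation, alpha = 0.05,
                               lambda = 0.5, theta = 0.5, eps = 1,
                               scale_method = "ratio-of-sums",
                               k_range = 2:10, outdir = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (lambda < 0) stop("lambda must be >= 0")
  if (eps < 0) stop("eps must be >= 0")
  s <- compute_scale_factor(experiment, annotation, method = scale_method)
  norm <- normalize_signals(experiment, annotation, s, eps = eps)
  stats_cancer <- detect_signatures(norm, "cancer_vs_controls",
                                    alpha = alpha, lambda = lambda)
  stats_mc <- detect_signatures(norm, "control_vs_cancer",
                                control_group = "matched_control",
                                alpha = alpha, lambda = lambda)
  stats_nc <- detect_signatures(norm, "control_vs_cancer",
                                control_group = "nonmatched_control",
                                alpha = alpha, lambda = lambda)
  prevalence <- compute_prevalence(norm, annotation, stats_cancer,
                                   group = "cancer", theta = theta)
  taxa <- aggregate_signal(stats_cancer, annotation, "taxon")
  families <- aggregate_signal(stats_cancer, annotation, "family")
  groups_table <- aggregate_signal(stats_cancer, annotation, "group")
  taxon_of <- function(st) {
    det <- st$probe_id[st$detected]
    ann <- annotation[match(det, annotation$probe_id), ]
    split(ann$taxon, ann$kingdom)
  }
  t_ca <- taxon_of(stats_cancer)
  t_mc <- taxon_of(stats_mc)
  t_nc <- taxon_of(stats_nc)
  kingdoms <- sort(unique(c(names(t_ca), names(t_mc), names(t_nc))))
  comparison <- lapply(stats::setNames(kingdoms, kingdoms), function(k) {
    compare_sets(t_ca[[k]] %||% character(0), t_mc[[k]] %||% character(0),
                 t_nc[[k]] %||% character(0))
  })
  cancer_cols <- names(norm$groups)[norm$groups == "cancer"]
  cancer_norm <- structure(list(n = norm$n[, cancer_cols, drop = FALSE],
                                scale_factors = norm$scale_factors,
                                groups = norm$groups),
                           class = "normalized_matrix")
  clusters <- select_k(cancer_norm, k_range = k_range)
  res <- list(scale_factors = s, norm = norm, stats_cancer = stats_cancer,
              stats_mc = stats_mc, stats_nc = stats_nc,
              prevalence = prevalence, taxa = taxa, families = families,
              groups_table = groups_table, comparison = comparison,
              clusters = clusters)
  if (!is.null(outdir)) {
    write_array_results(res, outdir,
                        params = list(alpha = alpha, lambda = lambda,
                                      theta = theta, eps = eps,
                                      scale_method = scale_method,
                                      k_range = range(k_range)))
  }
  res
}

write_array_results <- function(res, outdir, params) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(outdir, name)
  write_normalized_matrix(res$norm, out("normalized.tsv"))
  for (nm in c("stats_cancer", "stats_mc", "stats_nc", "prevalence",
               "taxa", "families", "groups_table")) {
    utils::write.table(res[[nm]], out(paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  comp_path <- out("set_comparison.tsv")
  tabs <- lapply(names(res$comparison), function(k) {
    comp <- res$comparison[[k]]
    data.frame(kingdom = k, partition = names(comp$sets),
               count = unname(comp$counts),
               members = vapply(comp$sets, paste, character(1),
                                collapse = ";"),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, tabs), comp_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ch <- data.frame(k = as.integer(names(res$clusters$ch_of_k)),
                   ch = unname(res$clusters$ch_of_k))
  utils::write.table(ch, out("ch_index.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_dendrogram_newick(res$clusters$tree, out("dendrogram.nwk"))
  write_manifest(outdir, params, stage_counts = list(
    probes_tested = nrow(res$stats_cancer),
    probes_detected_cancer = sum(res$stats_cancer$detected),
    probes_detected_mc = sum(res$stats_mc$detected),
    probes_detected_nc = sum(res$stats_nc$detected),
    taxa_with_prevalence = nrow(res$prevalence),
    k_best = res$clusters$k_best))
}

#' End-to-end integration analysis
#'
#' Aligns reads to the viral metagenome, calls and annotates integration
#' breakpoints, tallies insertions per chromosome, and counts aligned
#' reads over capture-probe regions. When `outdir` is given the calls,
#' tally and region counts are written as TSV with a YAML manifest.
#'
#' @param reads named character vector / `DNAStringSet` /
#'   `QualityScaledDNAStringSet`.
#' @param viral_refs,host_genome named character vectors or `DNAStringSet`.
#' @param genes optional [gene_model_set()] for annotation.
#' @param capture optional regions table (or BED path) for read counting.
#' @param window annotation window (default 100000).
#' @param min_clip,merge_radius,min_score see [call_integrations()].
#' @param outdir optional output directory.
#' @return list: alignments (per-read table), calls, tally,
#'   region_counts.
#' @export
run_integration_pipeline <- function(reads, viral_refs, host_genome,
                                     genes = NULL, capture = NULL,
                                     window = 100000, min_clip = 20,
                                     merge_radius = 5, min_score = 30,
                                     outdir = NULL) {
  reads <- as_sequence_character(reads)
  if (length(reads) == 0) {
    warning("no reads supplied; outputs are empty")
    aln <- data.frame()
    calls <- empty_integration_calls(data.frame(read_id = character(),
                                                reason = character()))
  } else {
    aln <- align_reads(reads, viral_refs, min_score = min_score)
    alignments <- lapply(which(aln$found), function(i) {
      alignment_from_row(aln[i, ], reads[[i]])
    })
    calls <- call_integrations(alignments = alignments,
                               viral_refs = viral_refs,
                               host_genome = host_genome,
                               min_clip = min_clip,
                               merge_radius = merge_radius)
  }
  if (!is.null(genes) && nrow(calls) > 0) {
    calls <- annotate_calls(calls, genes, window = window)
  }
  tally <- tally_by_chromosome(calls)
  region_counts <- NULL
  if (!is.null(capture) && length(reads) > 0) {
    region_counts <- count_reads_in_regions(aln, capture,
                                            ref_names = names(viral_refs))
  }
  res <- list(alignments = aln, calls = calls, tally = tally,
              region_counts = region_counts)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(calls), file.path(outdir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tally, file.path(outdir, "chrom_tally.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(region_counts)) {
      utils::write.table(region_counts,
                         file.path(outdir, "region_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_manifest(outdir, params = list(window = window,
                                         min_clip = min_clip,
                                         merge_radius = merge_radius,
                                         min_score = min_score),
                   stage_counts = list(
                     reads_processed = length(reads),
                     reads_aligned_to_virus = if (nrow(aln)) sum(aln$found) else 0L,
                     calls_merged = nrow(calls)))
  }
  res
}

# sidecar YAML manifest: parameters, stage record counts, file digests
write_manifest <- function(outdir, params, stage_counts) {
  files <- setdiff(list.files(outdir), "manifest.yaml")
  digests <- lapply(files, function(f) {
    unname(tools::md5sum(file.path(outdir, f)))
  })
  names(digests) <- files
  yaml::write_yaml(list(parameters = params, counts = stage_counts,
                        files = digests),
                   file.path(outdir, "manifest.yaml"))
  invisible(NULL)
}
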