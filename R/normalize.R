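#' Per-sample channel scale factors from human reference probes
#'
#' For each sample (array column) the scale factor is the ratio of summed
#' green to summed red intensity over the human reference probes,
#' `s = sum(g_human) / sum(r_human)` (the "ratio of sums" estimator).
#' A mean-of-ratios variant, `s = mean(g_human / r_human)`, is available via
#' `method`; it is more sensitive to near-zero red intensities.
#'
#' @param experiment an [array_experiment()].
#' @param annotation a [probe_annotation()] covering the experiment's probes.
#' @param method `"ratio-of-sums"` (default) or `"mean-of-ratios"`.
#' @return Named numeric vector of scale factors, one per sample.
#' @export
compute_scale_factor <- function(experiment, annotation,
                                 method = c("ratio-of-sums", "mean-of-ratios")) {
  method <- match.arg(method)
  human <- annotation$probe_id[annotation$probe_class == "human_reference"]
  human <- intersect(rownames(experiment$green), human)
  if (length(human) == 0) stop("no human reference probes in experiment")
  g <- experiment$green[human, , drop = FALSE]
  r <- experiment$red[human, , drop = FALSE]
  if (method == "ratio-of-sums") {
    rs <- colSums(r)
    if (any(rs <= 0)) {
      stop("zero red-channel sum over human probes in sample: ",
           paste(colnames(r)[rs <= 0], collapse = ", "))
    }
    s <- colSums(g) / rs
  } else {
    if (any(r <= 0)) {
      bad <- colnames(r)[apply(r <= 0, 2, any)]
      stop("non-positive red intensity among human probes in sample: ",
           paste(bad, collapse = ", "))
    }
    s <- colMeans(g / r)
  }
  stats::setNames(as.numeric(s), colnames(experiment$green))
}

#' Normalized hybridization signal
#'
#' Computes, for every non-human probe and sample, the normalized log2
#' signal `n = log2(g + eps) - log2(s * r + eps)`: the green (sample)
#' channel over the scale-factor-corrected red (reference) channel. Human
#' reference probes are excluded from the output. The pseudocount `eps`
#' guards against zero intensities; at typical intensities it is
#' negligible.
#'
#' @param experiment an [array_experiment()].
#' @param annotation a [probe_annotation()].
#' @param scale_factors named vector from [compute_scale_factor()]; computed
#'   if missing.
#' @param eps pseudocount in intensity units (default 1).
#' @return A `normalized_matrix`: list with `n` (matrix, non-human probes x
#'   samples, log2 units), `scale_factors`, and `groups`.
#' @export
normalize_signals <- function(experiment, annotation, scale_factors = NULL,
                              eps = 1) {
  if (is.null(scale_factors)) {
    scale_factors <- compute_scale_factor(experiment, annotation)
  }
  if (any(experiment$green < 0) || any(experiment$red < 0)) {
    stop("negative intensity")
  }
  s <- scale_factors[colnames(experiment$green)]
  if (any(is.na(s))) stop("missing scale factor for some samples")
  if (any(s <= 0)) stop("scale factors must be positive")
  nonhuman <- annotation$probe_id[annotation$probe_class != "human_reference"]
  keep <- rownames(experiment$green) %in% nonhuman
  g <- experiment$green[keep, , drop = FALSE]
  r <- experiment$red[keep, , drop = FALSE]
  n <- log2(g + eps) - log2(sweep(r, 2, s, "*") + eps)
  structure(list(n = n, scale_factors = s, groups = experiment$groups),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x$n), "probes x", ncol(x$n), "samples",
      "(log2 signal)\n")
  invisible(x)
}

#' Read / write a normalized matrix as TSV
#'
#' The signal matrix is written probe x sample; scale factors and groups
#' travel in a small sidecar TSV so the object round-trips.
#'
#' @param norm a `normalized_matrix`.
#' @param path signal matrix TSV path; the sidecar is `<path>.samples.tsv`.
#' @export
write_normalized_matrix <- function(norm, path) {
  write_matrix_tsv(norm$n, path)
  side <- data.frame(sample = colnames(norm$n),
                     scale_factor = unname(norm$scale_factors[colnames(norm$n)]),
                     group = unname(norm$groups[colnames(norm$n)]))
  utils::write.table(side, paste0(path, ".samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_normalized_matrix
#' @export
read_normalized_matrix <- function(path) {
  n <- read_matrix_tsv(path)
  side <- utils::read.delim(paste0(path, ".samples.tsv"),
                            stringsAsFactors = FALSE)
  structure(list(n = n,
                 scale_factors = stats::setNames(side$scale_factor, side$sample),
                 groups = stats::setNames(side$group, side$sample)),
            class = "normalized_matrix")
}
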