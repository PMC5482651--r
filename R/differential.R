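#' Welch two-sample t test
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite degrees
#' of freedom and a two-sided p value. Degenerate cases follow the
#' detection pipeline's conventions: if both groups are constant and equal
#' the probe is uninformative (`t = 0`, `p = 1`); if either group has fewer
#' than two observations the result is `NA` and the probe is excluded
#' downstream.
#'
#' @param x,y numeric vectors (case and control observations).
#' @param var_equal use the pooled-variance Student form instead of Welch.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  res <- row_t_test(matrix(x, nrow = 1), matrix(y, nrow = 1),
                    var_equal = var_equal)
  list(t = res$t[1], df = res$df[1], p = res$p[1])
}

# Row-wise Welch/Student t over matching rows of two matrices.
# Vectorised over probes; stats::t.test is the oracle in the unit tests.
row_t_test <- function(X, Y, var_equal = FALSE) {
  nx <- ncol(X)
  ny <- ncol(Y)
  mx <- rowMeans(X)
  my <- rowMeans(Y)
  if (nx < 2 || ny < 2) {
    n <- nrow(X)
    return(data.frame(mean_case = mx, mean_control = my,
                      t = rep(NA_real_, n), df = rep(NA_real_, n),
                      p = rep(NA_real_, n)))
  }
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(se))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  p <- 2 * stats::pt(-abs(t), df)
  # both groups constant: equal means -> uninformative; unequal -> certain
  degen <- se == 0
  if (any(degen)) {
    eq <- degen & (mx == my)
    t[eq] <- 0; df[eq] <- nx + ny - 2; p[eq] <- 1
    ne <- degen & (mx != my)
    t[ne] <- sign(mx - my)[ne] * Inf; df[ne] <- nx + ny - 2; p[ne] <- 0
  }
  data.frame(mean_case = mx, mean_control = my, t = t, df = df, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p values: with the inputs sorted ascending,
#' `q_i = min_{j >= i} (p_j * m / j)` capped at 1, returned in input order.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return numeric vector of adjusted p values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Detect differential probe signatures
#'
#' The detection statistic of the pipeline: per non-human probe, a
#' two-sample t test on the normalized signal between the case group and
#' the control group, with an asymmetric significance rule.
#'
#' For `direction = "cancer_vs_controls"` the case group is cancer, the
#' control group pools matched and non-matched controls, p values are
#' BH-adjusted across all tested probes, and a probe is detected when
#' `p_adj < alpha` and `logFC > lambda`.
#'
#' For `direction = "control_vs_cancer"` one control group (chosen by
#' `control_group`) is the case side, cancer is the comparison side, and
#' detection uses the nominal p value (`p < alpha` and `logFC > lambda`)
#' with no multiple-testing correction — control-side hits are reported as
#' suggestive only. BH-adjusted values are still computed and returned.
#'
#' @param norm a `normalized_matrix` from [normalize_signals()].
#' @param direction `"cancer_vs_controls"` or `"control_vs_cancer"`.
#' @param control_group for the control direction, which control group is
#'   tested: `"matched_control"` or `"nonmatched_control"`.
#' @param alpha significance level (default 0.05).
#' @param lambda log2 fold-change gate (default 0.5).
#' @param adjust apply BH to the detection rule (default `TRUE` for the
#'   cancer direction, `FALSE` for the control direction, as described).
#' @param var_equal pass-through to the t test (default Welch).
#' @return data.frame of class `probe_stats`: probe_id, mean_case,
#'   mean_control, logFC, t, df, p, p_adj, detected.
#' @export
detect_signatures <- function(norm,
                              direction = c("cancer_vs_controls",
                                            "control_vs_cancer"),
                              control_group = c("matched_control",
                                                "nonmatched_control"),
                              alpha = 0.05, lambda = 0.5,
                              adjust = NULL, var_equal = FALSE) {
  direction <- match.arg(direction)
  control_group <- match.arg(control_group)
  groups <- norm$groups[colnames(norm$n)]
  if (direction == "cancer_vs_controls") {
    case_idx <- which(groups == "cancer")
    ctrl_idx <- which(groups %in% c("matched_control", "nonmatched_control"))
    adjust <- adjust %||% TRUE
  } else {
    case_idx <- which(groups == control_group)
    ctrl_idx <- which(groups == "cancer")
    adjust <- adjust %||% FALSE
  }
  if (length(case_idx) < 2 || length(ctrl_idx) < 2) {
    stop("each compared group needs at least 2 samples (case ",
         length(case_idx), ", control ", length(ctrl_idx), ")")
  }
  res <- row_t_test(norm$n[, case_idx, drop = FALSE],
                    norm$n[, ctrl_idx, drop = FALSE], var_equal = var_equal)
  res$logFC <- res$mean_case - res$mean_control
  res$p_adj <- bh_adjust(res$p)
  p_gate <- if (adjust) res$p_adj else res$p
  res$detected <- p_gate < alpha & res$logFC > lambda
  out <- data.frame(probe_id = rownames(norm$n), res,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[, c("probe_id", "mean_case", "mean_control", "logFC",
                 "t", "df", "p", "p_adj", "detected")]
  attr(out, "direction") <- direction
  attr(out, "alpha") <- alpha
  attr(out, "lambda") <- lambda
  attr(out, "adjust") <- adjust
  class(out) <- c("probe_stats", "data.frame")
  out
}

#' Per-taxon prevalence of detected signatures
#'
#' A taxon counts as present in a sample when its detected (significant)
#' probes exceed the presence threshold `theta` there: under the default
#' `"mean"` rule the mean normalized signal of the taxon's detected probes
#' must exceed `theta`; under the `"any"` rule a single probe above
#' `theta` suffices (more sensitive, but its per-sample false-presence
#' rate grows with the number of probes). Prevalence is the percentage of
#' the group's samples in which the taxon is present, rounded half away
#' from zero to an integer. Taxa with no detected probes are excluded
#' (prevalence undefined).
#'
#' @param norm a `normalized_matrix`.
#' @param annotation a [probe_annotation()].
#' @param probe_stats output of [detect_signatures()].
#' @param group which sample group prevalence is computed over.
#' @param theta per-sample presence threshold on the normalized signal
#'   (default 0.5, the same margin as the fold-change gate).
#' @param level aggregate presence at `"taxon"` (default) or `"family"`.
#' @param presence_rule `"mean"` (default) or `"any"`, see above.
#' @return data.frame: taxon (or family), kingdom, n_probes_detected,
#'   n_samples_present, prevalence (integer percent). Per-probe prevalence
#'   is attached as attribute `"per_probe"`.
#' @export
compute_prevalence <- function(norm, annotation, probe_stats,
                               group = "cancer", theta = 0.5,
                               level = c("taxon", "family"),
                               presence_rule = c("mean", "any")) {
  level <- match.arg(level)
  presence_rule <- match.arg(presence_rule)
  groups <- norm$groups[colnames(norm$n)]
  cols <- which(groups %in% group)
  if (length(cols) == 0) stop("no samples in group: ", group)
  det <- probe_stats$probe_id[probe_stats$detected]
  det <- intersect(det, rownames(norm$n))
  sig <- norm$n[det, cols, drop = FALSE]
  sub <- sig > theta
  per_probe <- data.frame(
    probe_id = det,
    prevalence = as.integer(round_half_up(100 * rowMeans(sub))),
    stringsAsFactors = FALSE)
  ann <- annotation[match(det, annotation$probe_id), ]
  unit <- if (level == "taxon") ann$taxon else ann$family
  tab <- do.call(rbind, lapply(split(seq_along(det), unit), function(idx) {
    present <- if (presence_rule == "any") {
      colSums(sub[idx, , drop = FALSE]) >= 1
    } else {
      colMeans(sig[idx, , drop = FALSE]) > theta
    }
    data.frame(
      unit = unit[idx[1]],
      kingdom = ann$kingdom[idx[1]],
      n_probes_detected = length(idx),
      n_samples_present = sum(present),
      prevalence = as.integer(round_half_up(100 * mean(present))),
      stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) {
    tab <- data.frame(unit = character(), kingdom = character(),
                      n_probes_detected = integer(),
                      n_samples_present = integer(), prevalence = integer())
  }
  names(tab)[1] <- level
  rownames(tab) <- NULL
  tab <- tab[order(-tab$prevalence, tab[[level]]), ]
  attr(tab, "per_probe") <- per_probe
  tab
}

#' Aggregate detected probe signal to taxa, families or groups
#'
#' The average hybridization signal of a taxon or family is the mean of
#' `mean_case` over its detected probes; a group's total is the sum of its
#' families' averages (the "sum of average hybridization signal" used for
#' the group-level bar summaries). Output is sorted by descending signal.
#'
#' @param probe_stats output of [detect_signatures()].
#' @param annotation a [probe_annotation()].
#' @param level `"taxon"`, `"family"` or `"group"`.
#' @return data.frame: unit name, kingdom, avg_signal (log2 units),
#'   n_probes_detected.
#' @export
aggregate_signal <- function(probe_stats, annotation,
                             level = c("taxon", "family", "group")) {
  level <- match.arg(level)
  det <- probe_stats[probe_stats$detected, ]
  ann <- annotation[match(det$probe_id, annotation$probe_id), ]
  if (level == "group") {
    fam <- aggregate_by(det$mean_case, ann$family, ann$kingdom, "mean")
    grp_of_fam <- ann$group[match(fam$unit, ann$family)]
    out <- aggregate_by(fam$avg_signal, grp_of_fam, fam$kingdom, "sum")
    nprobe <- tapply(det$probe_id, ann$group, length)
    out$n_probes_detected <- as.integer(nprobe[out$unit])
  } else {
    unit <- if (level == "taxon") ann$taxon else ann$family
    out <- aggregate_by(det$mean_case, unit, ann$kingdom, "mean")
    out$n_probes_detected <- as.integer(table(unit)[out$unit])
  }
  names(out)[1] <- level
  out <- out[order(-out$avg_signal, out[[level]]), ]
  rownames(out) <- NULL
  out
}

aggregate_by <- function(value, unit, kingdom, fun) {
  idx <- split(seq_along(value), unit)
  data.frame(
    unit = names(idx),
    kingdom = vapply(idx, function(i) kingdom[i[1]], character(1)),
    avg_signal = vapply(idx, function(i) {
      if (fun == "mean") mean(value[i]) else sum(value[i])
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}
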