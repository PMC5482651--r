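#' Euclidean distances between samples
#'
#' Distance between sample columns of the normalized signal matrix:
#' `d(i, j) = sqrt(sum_probes (n_pi - n_pj)^2)`. Signals enter unadjusted;
#' optional per-probe z-scoring is available but off by default.
#'
#' @param norm a `normalized_matrix` (or a plain probes x samples matrix).
#' @param scale z-score each probe across samples first (default `FALSE`).
#' @return a [stats::dist] over samples.
#' @export
euclidean_distances <- function(norm, scale = FALSE) {
  m <- if (inherits(norm, "normalized_matrix")) norm$n else as.matrix(norm)
  if (ncol(m) < 2) stop("need at least 2 samples")
  if (scale) m <- t(scale(t(m)))
  stats::dist(t(m), method = "euclidean")
}

#' Complete-linkage agglomerative clustering
#'
#' Thin wrapper over [stats::hclust] with complete linkage (cluster
#' distance = maximum pairwise member distance), whose merge heights are
#' monotone non-decreasing.
#'
#' @param dist a [stats::dist].
#' @return an `hclust` tree.
#' @export
complete_linkage <- function(dist) {
  stats::hclust(dist, method = "complete")
}

#' Calinski-Harabasz index
#'
#' `CH = [trace(B) / (k - 1)] / [trace(W) / (n - k)]` with `B` and `W` the
#' between- and within-cluster scatter about the cluster and grand
#' centroids. Larger is better: the index rewards separated, compact
#' clusters. If every within-cluster scatter is zero (all-singleton or
#' duplicated points) the index is `+Inf` by convention.
#'
#' @param data samples x features numeric matrix (for sample clustering on
#'   a `normalized_matrix`, pass `t(norm$n)`).
#' @param labels cluster assignment vector, length `nrow(data)`.
#' @return numeric CH index.
#' @export
ch_index <- function(data, labels) {
  data <- as.matrix(data)
  n <- nrow(data)
  labels <- as.vector(labels)
  if (length(labels) != n) stop("labels must match rows of data")
  k <- length(unique(labels))
  if (k < 2 || k >= n) stop("need 2 <= k < n")
  grand <- colMeans(data)
  trB <- 0; trW <- 0
  for (cl in unique(labels)) {
    rows <- data[labels == cl, , drop = FALSE]
    cen <- colMeans(rows)
    trW <- trW + sum(sweep(rows, 2, cen)^2)
    trB <- trB + nrow(rows) * sum((cen - grand)^2)
  }
  if (trW == 0) return(Inf)
  (trB / (k - 1)) / (trW / (n - k))
}

#' Choose the number of clusters by the CH index
#'
#' Cuts the complete-linkage tree of the samples at each `k` in `k_range`,
#' scores each cut with [ch_index()], and returns the cut maximising the
#' index (first maximum on ties).
#'
#' @param norm a `normalized_matrix` or probes x samples matrix.
#' @param k_range candidate cluster numbers; capped at `n - 1`.
#' @param scale pass-through to [euclidean_distances()].
#' @return An object of class `cluster_result`: list with `tree` (hclust),
#'   `assignments` (samples x k matrix from [stats::cutree]), `ch_of_k`
#'   (named numeric), and `k_best`.
#' @export
select_k <- function(norm, k_range = 2:10, scale = FALSE) {
  m <- if (inherits(norm, "normalized_matrix")) norm$n else as.matrix(norm)
  n <- ncol(m)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("no feasible k in range for ", n, " samples")
  tree <- complete_linkage(euclidean_distances(m, scale = scale))
  cuts <- stats::cutree(tree, k = k_range)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1,
                                         dimnames = list(colnames(m), k_range))
  ch <- vapply(seq_along(k_range), function(i) ch_index(t(m), cuts[, i]),
               numeric(1))
  names(ch) <- k_range
  structure(list(tree = tree, assignments = cuts, ch_of_k = ch,
                 k_best = k_range[which.max(ch)]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: k_best =", x$k_best, "\nCH by k:\n")
  print(round(x$ch_of_k, 2))
  invisible(x)
}

#' Export a dendrogram as newick
#'
#' @param tree an `hclust` (e.g. `cluster_result$tree`).
#' @param path output path.
#' @export
write_dendrogram_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Taxon-level contrasts between sample clusters
#'
#' For every pair of clusters with at least two samples each, aggregates
#' the normalized signal to taxa (mean over each taxon's probes per
#' sample), applies the Welch t test per taxon between the two clusters,
#' and BH-adjusts within the pair. Clusters with fewer than two samples are
#' excluded with a warning.
#'
#' @param norm a `normalized_matrix`.
#' @param assignments named cluster label vector over samples.
#' @param annotation a [probe_annotation()].
#' @param alpha significance level on the adjusted p value (default 0.05).
#' @return data.frame: cluster_a, cluster_b, taxon, kingdom, logFC, t, df,
#'   p, p_adj, detected.
#' @export
cluster_contrasts <- function(norm, assignments, annotation, alpha = 0.05) {
  samples <- colnames(norm$n)
  assignments <- assignments[samples]
  if (any(is.na(assignments))) stop("assignment missing for some samples")
  ann <- annotation[match(rownames(norm$n), annotation$probe_id), ]
  agg <- rowsum(norm$n, group = ann$taxon) /
    as.vector(table(ann$taxon)[sort(unique(ann$taxon))])
  kingdom_of <- vapply(split(ann$kingdom, ann$taxon), `[`, character(1), 1)
  sizes <- table(assignments)
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < length(sizes)) {
    warning("excluding clusters with fewer than 2 samples: ",
            paste(setdiff(names(sizes), usable), collapse = ", "))
  }
  if (length(usable) < 2) {
    stop("need at least two clusters with >= 2 samples")
  }
  out <- list()
  for (i in seq_along(usable)) {
    for (j in seq_along(usable)) {
      if (j <= i) next
      a <- usable[i]; b <- usable[j]
      res <- row_t_test(agg[, assignments == a, drop = FALSE],
                        agg[, assignments == b, drop = FALSE])
      res$p_adj <- bh_adjust(res$p)
      out[[paste(a, b)]] <- data.frame(
        cluster_a = a, cluster_b = b,
        taxon = rownames(agg),
        kingdom = unname(kingdom_of[rownames(agg)]),
        logFC = res$mean_case - res$mean_control,
        t = res$t, df = res$df, p = res$p, p_adj = res$p_adj,
        detected = res$p_adj < alpha,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}
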