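# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementation paths.

# quadratic Smith-Waterman (score only), affine gaps: gap of length L
# costs open + L * ext
sw_score_reference <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 3, gap_ext = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_ext,
                             E[i + 1, j] - gap_ext)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_ext,
                             F[i, j + 1] - gap_ext)
      s <- if (a[i] == b[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s,
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# naive O(n^3) complete-linkage agglomeration; returns merge heights and
# the partition after each merge
complete_linkage_reference <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (list of index vectors) for comparison
canonical_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, min, numeric(1)))]
}

# cutree labels -> partition as list of index vectors
labels_to_partition <- function(labels) {
  unname(split(seq_along(labels), labels))
}

# CH index via explicit scatter matrices (outer products), independent of
# the trace shortcut used by the package
ch_reference <- function(data, labels) {
  data <- as.matrix(data)
  n <- nrow(data)
  k <- length(unique(labels))
  grand <- colMeans(data)
  B <- matrix(0, ncol(data), ncol(data))
  W <- matrix(0, ncol(data), ncol(data))
  for (cl in unique(labels)) {
    rows <- data[labels == cl, , drop = FALSE]
    cen <- colMeans(rows)
    for (r in seq_len(nrow(rows))) {
      v <- rows[r, ] - cen
      W <- W + outer(v, v)
    }
    u <- cen - grand
    B <- B + nrow(rows) * outer(u, u)
  }
  (sum(diag(B)) / (k - 1)) / (sum(diag(W)) / (n - k))
}

# hand step-up BH (sorting formulation), independent of stats::p.adjust
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# two-sided permutation p-value for the Welch statistic
permutation_p <- function(x, y, n_perm = 20000) {
  z <- c(x, y)
  nx <- length(x)
  welch_t <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  obs <- abs(welch_t(x, y))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(z), nx)
    if (abs(welch_t(z[idx], z[-idx])) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}
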