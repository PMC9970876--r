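# Independent brute-force oracles shared across test files.

# dense grid search on the Paule-Mandel defining equation
pm_grid_oracle <- function(betas, ses, hi = 1, levels = 3) {
  q_fun <- function(tau2) {
    w <- 1 / (ses^2 + tau2)
    bh <- sum(w * betas) / sum(w)
    sum(w * (betas - bh)^2)
  }
  k <- length(betas)
  if (q_fun(0) <= k - 1) return(0)
  lo <- 0
  while (q_fun(hi) > k - 1) hi <- hi * 4
  for (l in seq_len(levels)) {
    grid <- seq(lo, hi, length.out = 2001)
    qs <- vapply(grid, q_fun, numeric(1))
    i <- which.min(abs(qs - (k - 1)))
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
  }
  (lo + hi) / 2
}

# O(n^3) agglomerative single-linkage merge heights
sl_heights_oracle <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- min(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# direct evaluation of every Benjamini-Hochberg step-up threshold
bh_flags_oracle <- function(p, q_level) {
  m <- length(p)
  ord <- order(p)
  flags <- logical(m)
  ks <- which(p[ord] <= seq_len(m) / m * q_level)
  if (length(ks)) flags[ord[seq_len(max(ks))]] <- TRUE
  flags
}
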