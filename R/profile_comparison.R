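# Stage-one pooled comparison of per-trait effects between profiles
# (Paule-Mandel random-effects pooling + delta test + FDR), stage-two
# shadow-feature random-forest relevance selection, and single-linkage
# outlier detection within profiles.

#' Paule-Mandel random-effects pooling
#'
#' Estimates the between-SNP variance tau^2 as the solution of the
#' generalized Q equation
#' `sum(w_i(tau2) * (beta_i - betahat(tau2))^2) = k - 1` with
#' `w_i = 1 / (se_i^2 + tau2)`, solved by bisection to relative
#' tolerance 1e-10 (Q is monotone decreasing in tau2). If the Q statistic
#' at `tau2 = 0` does not exceed `k - 1`, `tau2 = 0` and the estimator
#' coincides with fixed-effect inverse-variance pooling.
#'
#' @param betas Effect estimates.
#' @param ses Standard errors (all positive).
#' @return A list: `beta_hat`, `se`, `tau2`, `k`, `p` (two-sided normal
#'   p-value of `beta_hat`).
#' @export
pm_meta <- function(betas, ses) {
  keep <- !is.na(betas) & !is.na(ses)
  betas <- betas[keep]; ses <- ses[keep]
  k <- length(betas)
  if (k == 0L) stop("no effect estimates to pool")
  if (any(ses <= 0)) stop("standard errors must be positive")
  q_fun <- function(tau2) {
    w <- 1 / (ses^2 + tau2)
    bh <- sum(w * betas) / sum(w)
    sum(w * (betas - bh)^2)
  }
  tau2 <- 0
  if (k > 1 && q_fun(0) > k - 1) {
    hi <- stats::var(betas)
    while (q_fun(hi) > k - 1) hi <- hi * 2
    lo <- 0
    while ((hi - lo) > 1e-10 * max(hi, 1e-12)) {
      mid <- (lo + hi) / 2
      if (q_fun(mid) > k - 1) lo <- mid else hi <- mid
    }
    tau2 <- (lo + hi) / 2
  }
  w <- 1 / (ses^2 + tau2)
  beta_hat <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(beta_hat = beta_hat, se = se, tau2 = tau2, k = k,
       p = 2 * stats::pnorm(-abs(beta_hat / se)))
}

#' Profile difference (delta) test
#'
#' Tests `delta = |beta_C - beta_D|` with
#' `SE_delta^2 = SE_C^2 + SE_D^2`, referring `delta / SE_delta` to the
#' standard normal (two-sided). Symmetric in its two arguments.
#'
#' @param pooled_c,pooled_d Pooled estimates (lists with `beta_hat` and
#'   `se`, e.g. from [pm_meta()]).
#' @return A list: `delta`, `se_delta`, `z`, `p`.
#' @export
delta_test <- function(pooled_c, pooled_d) {
  delta <- abs(pooled_c$beta_hat - pooled_d$beta_hat)
  se_delta <- sqrt(pooled_c$se^2 + pooled_d$se^2)
  z <- delta / se_delta
  list(delta = delta, se_delta = se_delta, z = z,
       p = 2 * (1 - stats::pnorm(z)))
}

#' Delta test from reported estimates and 95% confidence intervals
#'
#' Reconstructs standard errors as `CI width / (2 * 1.96)` and runs
#' [delta_test()]. For odds or hazard ratios set `log_scale = TRUE`: the
#' estimates and interval bounds are log-transformed first, since
#' normality holds on the log scale.
#'
#' @param est_c,lo_c,hi_c Estimate and 95% CI for the first profile.
#' @param est_d,lo_d,hi_d Estimate and 95% CI for the second profile.
#' @param log_scale Work on the log scale (for ORs/HRs).
#' @return As [delta_test()].
#' @export
delta_test_ci <- function(est_c, lo_c, hi_c, est_d, lo_d, hi_d,
                          log_scale = FALSE) {
  tf <- if (log_scale) log else identity
  pc <- list(beta_hat = tf(est_c), se = (tf(hi_c) - tf(lo_c)) / (2 * 1.96))
  pd <- list(beta_hat = tf(est_d), se = (tf(hi_d) - tf(lo_d)) / (2 * 1.96))
  delta_test(pc, pd)
}

#' Benjamini-Hochberg FDR adjustment with significance flags
#'
#' @param p Vector of p-values.
#' @param q_level FDR level for the flags (default 0.05).
#' @return A list: `q` (BH-adjusted q-values, order-preserving) and
#'   `significant` (`q <= q_level`).
#' @export
bh_fdr <- function(p, q_level = 0.05) {
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, significant = q <= q_level)
}

#' Shadow-feature random-forest relevance selection
#'
#' Each iteration appends `shadow_copies` column-wise permuted shadow
#' copies of every trait to the SNP x trait matrix, fits a random-forest
#' classifier of the profile labels, and scores a "hit" for every real
#' trait whose importance (Z-score of out-of-bag permutation importance)
#' exceeds the maximum shadow importance. Two shadow copies per trait
#' (the default) sharpen the max-shadow reference when the matrix is
#' wide relative to the number of SNPs, keeping chance in-sample
#' correlations from being flagged. After `n_iter`
#' iterations, each trait's hit count is referred to a two-sided binomial
#' test against 0.5 with Holm (stepwise) correction: significantly more
#' hits than expected confirms the trait, significantly fewer rejects
#' it, anything else stays tentative. Constant columns carry no
#' importance and end up rejected. Deterministic given `seed`.
#'
#' @param z_matrix SNP x trait matrix (complete; use [scan_z_matrix()]).
#' @param labels Profile label per row (two classes required).
#' @param n_iter Number of shadow iterations (default 1000).
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 500).
#' @param alpha Binomial test level before correction (default 0.01).
#' @param shadow_copies Permuted shadow copies per trait (default 2).
#' @return A tibble: `trait_id`, `decision` in
#'   `{confirmed, tentative, rejected}`, `mean_importance`,
#'   `shadow_max_mean`, `hits`, `n_iter`.
#' @export
boruta_select <- function(z_matrix, labels, n_iter = 1000, seed = 1,
                          num_trees = 500, alpha = 0.01,
                          shadow_copies = 2) {
  if (length(unique(labels)) < 2) stop("labels must contain two classes")
  if (min(table(labels)) < 2) stop("need at least 2 SNPs per class")
  if (anyNA(z_matrix)) stop("z_matrix must be complete; impute first")
  p <- ncol(z_matrix)
  traits <- colnames(z_matrix) %||% paste0("trait", seq_len(p))
  y <- factor(labels)
  with_seed_(seed, {
    hits <- integer(p)
    imp_sum <- numeric(p)
    shadow_max_sum <- 0
    for (it in seq_len(n_iter)) {
      shadow <- do.call(cbind, lapply(seq_len(shadow_copies), function(cp) {
        apply(z_matrix, 2, sample)
      }))
      colnames(shadow) <- paste0("shadow_", seq_len(ncol(shadow)))
      dat <- data.frame(cbind(z_matrix, shadow))
      dat$.y <- y
      # Z-score of out-of-bag permutation importance, as in the
      # published algorithm: raw impurity importance lets a trait with a
      # chance in-sample correlation beat the shadows too consistently
      fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                            num.trees = num_trees, importance = "permutation",
                            scale.permutation.importance = TRUE,
                            num.threads = 1, verbose = FALSE,
                            seed = sample.int(.Machine$integer.max, 1))
      imp <- fit$variable.importance
      real_imp <- imp[seq_len(p)]
      smax <- max(imp[-seq_len(p)])
      hits <- hits + as.integer(real_imp > smax)
      imp_sum <- imp_sum + real_imp
      shadow_max_sum <- shadow_max_sum + smax
    }
  })
  p_more <- stats::pbinom(hits - 1L, n_iter, 0.5, lower.tail = FALSE)
  p_less <- stats::pbinom(hits, n_iter, 0.5)
  p_more_adj <- stats::p.adjust(p_more, method = "holm")
  p_less_adj <- stats::p.adjust(p_less, method = "holm")
  decision <- rep("tentative", p)
  decision[p_more_adj <= alpha] <- "confirmed"
  decision[p_less_adj <= alpha & decision == "tentative"] <- "rejected"
  tibble::tibble(trait_id = traits, decision = decision,
                 mean_importance = imp_sum / n_iter,
                 shadow_max_mean = shadow_max_sum / n_iter,
                 hits = hits, n_iter = n_iter)
}

#' Single-linkage clustering with last-joined-leaf report
#'
#' Agglomerative single-linkage clustering over the rows of a
#' SNP x trait matrix. The leaf with the greatest first-merge height is
#' the SNP most distal from every other SNP in its set - the profile's
#' outlier candidate.
#'
#' @param z_matrix Numeric matrix, SNP rows.
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (`1 - Pearson r` between rows).
#' @return A list of class `cluster_tree`: `merge`, `height`, `labels`,
#'   `order` (as [stats::hclust()]), `leaf_heights` (height of each
#'   leaf's first merge) and `last_joined_leaf`.
#' @export
single_linkage_outliers <- function(z_matrix,
                                    distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  if (nrow(z_matrix) < 2) stop("need at least two rows to cluster")
  d <- switch(distance,
    euclidean = stats::dist(z_matrix),
    correlation = stats::as.dist(1 - stats::cor(t(z_matrix)))
  )
  hc <- stats::hclust(d, method = "single")
  n <- nrow(z_matrix)
  leaf_heights <- numeric(n)
  for (step in seq_len(n - 1L)) {
    for (side in 1:2) {
      node <- hc$merge[step, side]
      if (node < 0) leaf_heights[-node] <- hc$height[step]
    }
  }
  labels <- rownames(z_matrix) %||% as.character(seq_len(n))
  names(leaf_heights) <- labels
  last <- labels[which.max(leaf_heights)]
  structure(list(merge = hc$merge, height = hc$height, labels = labels,
                 order = hc$order, leaf_heights = leaf_heights,
                 last_joined_leaf = last),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves; last joined: %s (height %.4g)\n",
              length(x$labels), x$last_joined_leaf, max(x$leaf_heights)))
  invisible(x)
}

#' Stage-one profile comparison across a trait panel
#'
#' Per trait: pools concordant and discordant standardized effects
#' separately with [pm_meta()] (missing cells are simply excluded from
#' the pool), runs the [delta_test()], then applies BH-FDR in two
#' families - one over all per-profile p-values, one over the delta
#' p-values - optionally within phenotypic domains. Traits where any
#' pooled estimate AND the delta are significant at `q_level` form the
#' stage-two selection.
#'
#' @param scan Long harvest tibble from [harvest()] (QC-failed rows are
#'   dropped).
#' @param q_level FDR level (default 0.05).
#' @param domains Optional named character vector mapping `trait_id` to a
#'   domain; FDR families are corrected within domain when given.
#' @return A list: `pooled` (tibble trait x profile), `delta` (tibble
#'   with `delta`, `se_delta`, `z`, `p`, `q`, `significant_any_profile`,
#'   `selected`), `selected_traits`.
#' @export
compare_profiles <- function(scan, q_level = 0.05, domains = NULL) {
  scan <- scan[scan$qc_keep, , drop = FALSE]
  trait_ids <- unique(scan$trait_id)
  if (!length(trait_ids)) {
    return(list(pooled = tibble::tibble(), delta = tibble::tibble(),
                selected_traits = character()))
  }
  pooled_rows <- list()
  delta_rows <- list()
  skipped <- 0L
  for (tid in trait_ids) {
    sub <- scan[scan$trait_id == tid, ]
    if (!any(sub$label == "concordant") || !any(sub$label == "discordant")) {
      skipped <- skipped + 1L  # cannot compare with a profile fully missing
      next
    }
    pc <- pm_meta(sub$beta_std[sub$label == "concordant"],
                  sub$se_std[sub$label == "concordant"])
    pd <- pm_meta(sub$beta_std[sub$label == "discordant"],
                  sub$se_std[sub$label == "discordant"])
    dt <- delta_test(pc, pd)
    pooled_rows[[tid]] <- tibble::tibble(
      trait_id = tid, profile = c("C", "D"),
      beta_hat = c(pc$beta_hat, pd$beta_hat), se = c(pc$se, pd$se),
      tau2 = c(pc$tau2, pd$tau2), k = c(pc$k, pd$k), p = c(pc$p, pd$p)
    )
    delta_rows[[tid]] <- tibble::tibble(
      trait_id = tid, delta = dt$delta, se_delta = dt$se_delta,
      z = dt$z, p = dt$p
    )
  }
  log_count("traits skipped with a profile fully missing", skipped)
  if (!length(pooled_rows)) {
    return(list(pooled = tibble::tibble(), delta = tibble::tibble(),
                selected_traits = character()))
  }
  pooled <- dplyr::bind_rows(pooled_rows)
  delta <- dplyr::bind_rows(delta_rows)

  dom_of <- function(tids) {
    if (is.null(domains)) rep("all", length(tids))
    else dplyr::coalesce(domains[tids], "all")
  }
  pooled$q <- NA_real_
  for (d in unique(dom_of(pooled$trait_id))) {
    ii <- dom_of(pooled$trait_id) == d
    pooled$q[ii] <- bh_fdr(pooled$p[ii], q_level)$q
  }
  delta$q <- NA_real_
  for (d in unique(dom_of(delta$trait_id))) {
    ii <- dom_of(delta$trait_id) == d
    delta$q[ii] <- bh_fdr(delta$p[ii], q_level)$q
  }
  any_prof <- tapply(pooled$q <= q_level, pooled$trait_id, any)
  delta$significant_any_profile <- as.logical(any_prof[delta$trait_id])
  delta$selected <- delta$significant_any_profile & delta$q <= q_level
  list(pooled = pooled, delta = delta,
       selected_traits = delta$trait_id[delta$selected])
}
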