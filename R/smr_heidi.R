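# Summary-based Mendelian randomization (SMR) with the HEIDI
# heterogeneity test, and the screen for genes with opposite-direction
# pleiotropic effects on BMI and T2D.

# align outcome records to the eQTL table's effect alleles; returns
# outcome columns (beta, se, p, n) ordered as eqtl rows, NA when absent
# or allele-mismatched
align_outcome_to_eqtl <- function(eqtl, outcome_ss) {
  idx <- match(eqtl$snp_id, outcome_ss$snp_id)
  beta <- se <- p <- rep(NA_real_, nrow(eqtl))
  found <- !is.na(idx)
  if (any(found)) {
    o <- outcome_ss[idx[found], ]
    same <- o$ea == eqtl$ea[found] & o$oa == eqtl$oa[found]
    flip <- o$ea == eqtl$oa[found] & o$oa == eqtl$ea[found]
    b <- ifelse(flip, -o$beta, o$beta)
    b[!(same | flip)] <- NA
    beta[found] <- b
    se[found] <- ifelse(same | flip, o$se, NA)
    p[found] <- ifelse(same | flip, o$p, NA)
  }
  tibble::tibble(beta_out = beta, se_out = se, p_out = p)
}

#' Select the lead cis-eQTL instrument for a gene
#'
#' Among the gene's SNPs within `window_bp` of the transcription start
#' site with `p_eqtl < p_gw` AND BMI `p < p_gw` (instruments must be
#' genome-wide significant for the exposure trait as well), returns the
#' minimum-`p_eqtl` record; ties broken by position, then id.
#'
#' @param eqtls Tibble of eQTL records (summary-statistics columns plus
#'   `gene`, `tissue`, `tss`).
#' @param gene Gene id.
#' @param tss Transcription start site (defaults to the table's `tss`).
#' @param window_bp cis window half-width (default 500 kb).
#' @param bmi_ss BMI summary statistics (for the dual-significance
#'   condition); `NULL` disables it.
#' @param p_gw Significance threshold (default 5e-8).
#' @return The lead record (one-row tibble) or `NULL`.
#' @export
top_cis_eqtl <- function(eqtls, gene, tss = NULL, window_bp = 500000,
                         bmi_ss = NULL, p_gw = 5e-8) {
  sub <- eqtls[eqtls$gene == gene, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  tss <- tss %||% sub$tss[1]
  sub <- sub[abs(sub$pos - tss) <= window_bp & sub$p < p_gw, , drop = FALSE]
  if (!is.null(bmi_ss) && nrow(sub)) {
    al <- align_outcome_to_eqtl(sub, bmi_ss)
    sub <- sub[!is.na(al$p_out) & al$p_out < p_gw, , drop = FALSE]
  }
  if (!nrow(sub)) return(NULL)
  sub[order(sub$p, sub$pos, sub$snp_id), ][1, , drop = FALSE]
}

#' SMR pleiotropy test
#'
#' Wald-ratio effect of expression on the outcome through the lead
#' instrument: `b_smr = beta_outcome / beta_eqtl`, with combined
#' statistic `T = z_out^2 * z_eqtl^2 / (z_out^2 + z_eqtl^2)` referred to
#' chi-square with 1 df, and `se_smr = |b_smr| / sqrt(T)`.
#'
#' @param beta_eqtl,se_eqtl Instrument effect on expression.
#' @param beta_out,se_out Instrument effect on the outcome (same effect
#'   allele).
#' @return A list: `b_smr`, `se_smr`, `t_smr`, `p_smr`.
#' @export
smr_test <- function(beta_eqtl, se_eqtl, beta_out, se_out) {
  if (beta_eqtl == 0) stop("degenerate instrument: zero eQTL effect")
  z_e <- beta_eqtl / se_eqtl
  z_o <- beta_out / se_out
  t_smr <- z_o^2 * z_e^2 / (z_o^2 + z_e^2)
  b_smr <- beta_out / beta_eqtl
  list(b_smr = b_smr,
       se_smr = abs(b_smr) / sqrt(t_smr),
       t_smr = t_smr,
       p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE))
}

# tail probability of a positively weighted chi-square mixture by
# Imhof's numeric inversion; Monte-Carlo fallback with a fixed seed
weighted_chisq_tail <- function(q, lambda, mc_draws = 1e6, mc_seed = 20220131) {
  lambda <- lambda[lambda > 1e-12]
  if (!length(lambda)) return(1)
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  p <- tryCatch({
    val <- stats::integrate(integrand, lower = 0, upper = Inf,
                            subdivisions = 10000L, rel.tol = 1e-10,
                            stop.on.error = FALSE)$value
    0.5 + val / pi
  }, error = function(e) NA_real_)
  if (is.na(p) || p < -1e-4 || p > 1 + 1e-4) {
    p <- with_seed_(mc_seed, {
      draws <- colSums(lambda * matrix(stats::rchisq(length(lambda) * mc_draws,
                                                     df = 1),
                                       nrow = length(lambda)))
      mean(draws > q)
    })
  }
  min(max(p, 1e-300), 1)
}

#' HEIDI heterogeneity test
#'
#' Tests whether Wald ratios at SNPs in LD with the lead instrument are
#' homogeneous (a single shared causal variant, i.e. pleiotropy) or
#' heterogeneous (linkage). Secondary SNPs are those with
#' `r^2` to the lead inside `r2_window` and `p_eqtl` below
#' `eqtl_p_floor`; the strongest (smallest eQTL p) `max_snps` are used.
#' Differences `d_i = b_smr(i) - b_smr(lead)` get a delta-method
#' covariance from the LD correlations; the statistic
#' `sum((d_i / sd(d_i))^2)` follows an eigenvalue-weighted chi-square
#' mixture under homogeneity, inverted numerically (Monte-Carlo fallback
#' at 1e6 draws with fixed seed). Small p indicates linkage.
#'
#' @param eqtl Tibble of the region's eQTL records.
#' @param outcome_ss Outcome summary statistics.
#' @param ld Signed SNP correlation matrix with snp_id dimnames.
#' @param lead_snp Lead instrument id.
#' @param r2_window Inclusive r-squared window for secondary SNPs
#'   (default `c(0.05, 0.9)`; near-perfect proxies are uninformative).
#' @param max_snps Maximum secondary SNPs (default 20).
#' @param eqtl_p_floor eQTL significance floor for secondary SNPs
#'   (default 1.57e-3, i.e. chi-square > 10).
#' @return A list: `p_heidi` (`NA` when no secondary SNP qualifies),
#'   `n_used`, `stat`.
#' @export
heidi_test <- function(eqtl, outcome_ss, ld, lead_snp,
                       r2_window = c(0.05, 0.9), max_snps = 20,
                       eqtl_p_floor = 1.57e-3) {
  al <- align_outcome_to_eqtl(eqtl, outcome_ss)
  ok <- !is.na(al$beta_out) & eqtl$snp_id %in% rownames(ld)
  eqtl <- eqtl[ok, , drop = FALSE]
  al <- al[ok, , drop = FALSE]
  li <- match(lead_snp, eqtl$snp_id)
  if (is.na(li)) stop("lead SNP absent from region")
  r_lead <- ld[eqtl$snp_id, lead_snp]
  r2 <- r_lead^2
  sec <- which(eqtl$snp_id != lead_snp &
                 r2 >= r2_window[1] & r2 <= r2_window[2] &
                 eqtl$p < eqtl_p_floor)
  if (!length(sec)) return(list(p_heidi = NA_real_, n_used = 0L, stat = NA_real_))
  sec <- sec[order(eqtl$p[sec])]
  sec <- sec[seq_len(min(length(sec), max_snps))]

  sel <- c(li, sec)
  ids <- eqtl$snp_id[sel]
  be <- eqtl$beta[sel]; se_e <- eqtl$se[sel]
  bo <- al$beta_out[sel]; se_o <- al$se_out[sel]
  R <- ld[ids, ids]
  b <- bo / be
  m <- length(sel)
  # delta-method covariance of the Wald ratios
  cov_b <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    cov_b[i, j] <- R[i, j] * se_o[i] * se_o[j] / (be[i] * be[j]) +
      bo[i] * bo[j] * R[i, j] * se_e[i] * se_e[j] / (be[i]^2 * be[j]^2)
  }
  k <- m - 1L
  d <- b[-1] - b[1]
  cov_d <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cov_d[i, j] <- cov_b[i + 1, j + 1] - cov_b[i + 1, 1] -
      cov_b[1, j + 1] + cov_b[1, 1]
  }
  sd_d <- sqrt(diag(cov_d))
  zd <- d / sd_d
  corr_d <- cov_d / outer(sd_d, sd_d)
  stat <- sum(zd^2)
  lambda <- eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  list(p_heidi = weighted_chisq_tail(stat, lambda), n_used = k, stat = stat)
}

#' Screen for genes with discordant pleiotropic effects on BMI and T2D
#'
#' Per gene x tissue: the lead cis-eQTL instrument (dual-significant for
#' expression and BMI) is Wald-ratio tested against both outcomes;
#' BH-FDR is applied across all tests separately per outcome; HEIDI must
#' support pleiotropy (`p_heidi > heidi_cut`) for both outcomes. Genes
#' passing all conditions with opposite-signed SMR effects on BMI and
#' T2D form the discordant list.
#'
#' @param genes Tibble `gene`, `tissue`, `tss`.
#' @param eqtls eQTL summary table (with `gene`, `tissue`, `tss`).
#' @param bmi_ss,t2d_ss Outcome summary statistics.
#' @param ld Signed correlation matrix, or a named list of matrices
#'   keyed by gene.
#' @param q_level FDR level (default 0.05).
#' @param heidi_cut HEIDI pleiotropy cut-off (default 0.01).
#' @param p_gw Instrument significance threshold (default 5e-8).
#' @param window_bp cis window (default 500 kb).
#' @return A list: `results` (tibble, one row per gene x tissue x
#'   outcome: lead SNP, `b_smr`, `se_smr`, `p_smr`, `q_smr`, `p_heidi`,
#'   `n_heidi_snps`), `genes` (per gene x tissue summary with `passes`
#'   and `discordant`), `discordant_genes`.
#' @export
discordant_gene_screen <- function(genes, eqtls, bmi_ss, t2d_ss, ld,
                                   q_level = 0.05, heidi_cut = 0.01,
                                   p_gw = 5e-8, window_bp = 500000) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene[i]; tis <- genes$tissue[i]
    sub <- eqtls[eqtls$gene == g & eqtls$tissue == tis, , drop = FALSE]
    if (!nrow(sub)) next
    lead <- top_cis_eqtl(sub, g, tss = genes$tss[i], window_bp = window_bp,
                         bmi_ss = bmi_ss, p_gw = p_gw)
    if (is.null(lead)) next
    ldm <- if (is.list(ld) && !is.matrix(ld)) ld[[g]] else ld
    for (out_name in c("BMI", "T2D")) {
      oss <- if (out_name == "BMI") bmi_ss else t2d_ss
      alo <- align_outcome_to_eqtl(lead, oss)
      if (is.na(alo$beta_out)) next
      sm <- smr_test(lead$beta, lead$se, alo$beta_out, alo$se_out)
      hd <- heidi_test(sub, oss, ldm, lead$snp_id)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = g, tissue = tis, outcome = out_name,
        lead_snp = lead$snp_id, b_smr = sm$b_smr, se_smr = sm$se_smr,
        p_smr = sm$p_smr, p_heidi = hd$p_heidi,
        n_heidi_snps = hd$n_used
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  if (!nrow(results)) {
    return(list(results = results, genes = tibble::tibble(),
                discordant_genes = character()))
  }
  results$q_smr <- NA_real_
  for (out_name in unique(results$outcome)) {
    ii <- results$outcome == out_name
    results$q_smr[ii] <- bh_fdr(results$p_smr[ii], q_level)$q
  }
  wide <- tidyr::pivot_wider(results,
                             id_cols = c("gene", "tissue", "lead_snp"),
                             names_from = "outcome",
                             values_from = c("b_smr", "q_smr", "p_heidi"))
  wide$passes <- !is.na(wide$q_smr_BMI) & !is.na(wide$q_smr_T2D) &
    wide$q_smr_BMI <= q_level & wide$q_smr_T2D <= q_level &
    !is.na(wide$p_heidi_BMI) & wide$p_heidi_BMI > heidi_cut &
    !is.na(wide$p_heidi_T2D) & wide$p_heidi_T2D > heidi_cut
  wide$discordant <- wide$passes &
    sign(wide$b_smr_BMI) != sign(wide$b_smr_T2D)
  list(results = results, genes = wide,
       discordant_genes = unique(wide$gene[wide$discordant]))
}
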