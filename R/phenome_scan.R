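# Phenome-wide harvest of per-SNP effects across a trait panel, with QC
# filtering, effect standardization and alignment to the BMI-increasing
# allele.

#' z-score of an association estimate
#' @param beta Effect estimate.
#' @param se Standard error (must be positive).
#' @return `beta / se`.
#' @export
zscore <- function(beta, se) {
  if (any(se <= 0)) stop("standard errors must be positive")
  beta / se
}

#' Standardized effect size from z, MAF and sample size
#'
#' `se_std = 1 / sqrt(2 * maf * (1 - maf) * (n + z^2))` and
#' `beta_std = z * se_std`, placing effects from heterogeneous studies on
#' a common per-s.d. scale as a function of allele frequency and sample
#' size only.
#'
#' @param z z-score.
#' @param maf Minor allele frequency in (0, 1).
#' @param n Sample size.
#' @return A list with `se_std` and `beta_std` (vectorized).
#' @export
standardize_effect <- function(z, maf, n) {
  if (any(maf <= 0 | maf >= 1)) stop("maf must lie strictly in (0, 1)")
  if (any(n <= 0)) stop("n must be positive")
  se_std <- 1 / sqrt(2 * maf * (1 - maf) * (n + z^2))
  list(se_std = se_std, beta_std = z * se_std)
}

#' Study-level quality-control filter
#'
#' Drops studies with `n <= min_n`; for binary traits additionally drops
#' records where the expected minor-allele count in the smallest group,
#' `2 * maf * n_smallest_group`, falls below `min_minor_alleles`.
#'
#' @param n Sample size.
#' @param binary Logical, binary trait?
#' @param maf Minor allele frequency (needed for binary traits).
#' @param n_smallest_group Size of the smaller of cases/controls.
#' @param min_n Sample-size floor (default 500, exclusive).
#' @param min_minor_alleles Minor-allele floor for binary traits
#'   (default 25).
#' @return A list with logical `keep` and character `reason`
#'   (`NA` when kept), vectorized.
#' @export
qc_filter <- function(n, binary = FALSE, maf = NA, n_smallest_group = NA,
                      min_n = 500, min_minor_alleles = 25) {
  len <- max(length(n), length(binary), length(maf), length(n_smallest_group))
  n <- rep_len(n, len); binary <- rep_len(binary, len)
  maf <- rep_len(maf, len); n_smallest_group <- rep_len(n_smallest_group, len)
  reason <- rep(NA_character_, len)
  reason[n <= min_n] <- "small_n"
  few <- binary & is.na(reason) &
    (2 * maf * n_smallest_group < min_minor_alleles)
  reason[few] <- "few_minor_alleles"
  list(keep = is.na(reason), reason = reason)
}

# align trait records to the profile SNPs' BMI-increasing alleles
# (vectorized); returns aligned beta, NA on allele mismatch
align_to_bmi_allele <- function(ea, oa, beta, bmi_allele, other_allele) {
  same <- ea == bmi_allele & oa == other_allele
  flip <- ea == other_allele & oa == bmi_allele
  ifelse(same, beta, ifelse(flip, -beta, NA_real_))
}

#' Harvest SNP x trait associations with proxy fallback
#'
#' For every (profile SNP, trait): use the trait table's direct record if
#' present; otherwise search the panel for the best proxy among the
#' trait table's SNPs (`r^2 >= proxy_r2` within `window_bp`), aligning
#' the proxy effect to the index SNP through the sign of the
#' proxy-index dosage correlation. All effects end up on the
#' BMI-increasing allele, converted to z-scores and standardized
#' effects, QC-filtered via [qc_filter()].
#'
#' @param profile_snps Output of [assign_profiles()].
#' @param trait_tables Named list of summary-statistics tibbles, one per
#'   trait.
#' @param manifest Optional tibble `trait_id`, `binary`,
#'   `n_smallest_group` (defaults: all continuous).
#' @param panel A [reference_panel()] for proxy search (optional; no
#'   proxies without it).
#' @param proxy_r2 Proxy threshold (default 0.5).
#' @param window_bp Proxy window (default 500000).
#' @param exclude_patterns Character vector of regular expressions;
#'   traits whose id matches any pattern are excluded from the scan
#'   (used to keep diabetes phenotypes out of the comparison).
#' @return A long tibble of trait associations: `trait_id`, `snp_id`,
#'   `label`, `is_proxy`, `proxy_id`, `z`, `se_std`, `beta_std`, `maf`,
#'   `n`, `qc_keep`, `qc_reason`.
#' @export
harvest <- function(profile_snps, trait_tables, manifest = NULL,
                    panel = NULL, proxy_r2 = 0.5, window_bp = 500000,
                    exclude_patterns = character()) {
  trait_ids <- names(trait_tables)
  if (length(exclude_patterns)) {
    drop <- Reduce(`|`, lapply(exclude_patterns, grepl, x = trait_ids))
    log_count("traits excluded by pattern", sum(drop))
    trait_ids <- trait_ids[!drop]
  }
  rows <- list()
  for (tid in trait_ids) {
    tt <- trait_tables[[tid]]
    binary <- FALSE
    nsg <- NA_real_
    if (!is.null(manifest)) {
      mi <- match(tid, manifest$trait_id)
      if (!is.na(mi)) {
        binary <- isTRUE(manifest$binary[mi])
        nsg <- manifest$n_smallest_group[mi] %||% NA_real_
        if (length(nsg) != 1) nsg <- NA_real_
      }
    }
    k <- nrow(profile_snps)
    ri <- match(profile_snps$snp_id, tt$snp_id)
    found <- !is.na(ri)
    beta <- se <- eaf <- n <- rep(NA_real_, k)
    is_proxy <- rep(FALSE, k)
    proxy_id <- rep(NA_character_, k)
    if (any(found)) {
      rec <- tt[ri[found], ]
      beta[found] <- align_to_bmi_allele(rec$ea, rec$oa, rec$beta,
                                         profile_snps$bmi_allele[found],
                                         profile_snps$other_allele[found])
      se[found] <- rec$se
      eaf[found] <- rec$eaf
      n[found] <- rec$n
    }
    if (!is.null(panel)) {
      for (i in which(!found & profile_snps$snp_id %in% panel$snps$snp_id)) {
        ps <- profile_snps[i, ]
        pid <- find_proxy(panel, ps$snp_id, tt$snp_id, r2_min = proxy_r2,
                          window_bp = window_bp)
        if (is.null(pid)) next
        rec <- tt[match(pid, tt$snp_id), ]
        r_sign <- sign(ld_r_signed(panel, ps$snp_id, pid))
        # proxy effect on the proxy's counted (alt) allele, then the
        # dosage-correlation sign carries it onto the index SNP
        pa <- panel$snps[match(pid, panel$snps$snp_id), ]
        b <- if (rec$ea == pa$alt) rec$beta
             else if (rec$ea == pa$ref) -rec$beta else NA_real_
        idx_alt_is_bmi <- panel$snps$alt[match(ps$snp_id,
                                               panel$snps$snp_id)] ==
          ps$bmi_allele
        beta[i] <- r_sign * b * ifelse(idx_alt_is_bmi, 1, -1)
        se[i] <- rec$se
        eaf[i] <- rec$eaf
        n[i] <- rec$n
        is_proxy[i] <- TRUE
        proxy_id[i] <- pid
      }
    }
    ok <- !is.na(beta)  # mismatches and absences are empty cells
    if (!any(ok)) next
    z <- zscore(beta[ok], se[ok])
    maf <- maf_of(eaf[ok])
    std <- standardize_effect(z, maf, n[ok])
    qc <- qc_filter(n[ok], binary, maf, nsg)
    rows[[tid]] <- tibble::tibble(
      trait_id = tid, snp_id = profile_snps$snp_id[ok],
      label = profile_snps$label[ok],
      is_proxy = is_proxy[ok], proxy_id = proxy_id[ok],
      z = z, se_std = std$se_std, beta_std = std$beta_std,
      maf = maf, n = n[ok], qc_keep = qc$keep, qc_reason = qc$reason
    )
  }
  if (!length(rows)) {
    return(tibble::tibble(trait_id = character(), snp_id = character(),
                          label = character(), is_proxy = logical(),
                          proxy_id = character(), z = numeric(),
                          se_std = numeric(), beta_std = numeric(),
                          maf = numeric(), n = numeric(),
                          qc_keep = logical(), qc_reason = character()))
  }
  dplyr::bind_rows(rows)
}

#' Reshape a harvest into a SNP x trait z-matrix
#'
#' @param scan Output of [harvest()].
#' @param impute_missing Impute missing cells to 0 (required by the
#'   random-forest stage); the imputed count is logged.
#' @return A numeric matrix, SNP rows (rownames) x trait columns, with a
#'   `labels` attribute giving each row's profile label.
#' @export
scan_z_matrix <- function(scan, impute_missing = TRUE) {
  wide <- tidyr::pivot_wider(scan[, c("snp_id", "trait_id", "z")],
                             names_from = "trait_id", values_from = "z")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$snp_id
  n_miss <- sum(is.na(m))
  if (impute_missing && n_miss > 0) {
    log_count("z-matrix cells imputed to 0", n_miss)
    m[is.na(m)] <- 0
  }
  lab <- scan$label[match(rownames(m), scan$snp_id)]
  attr(m, "labels") <- lab
  m
}
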