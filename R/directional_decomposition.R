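# Directional decomposition: split BMI-associated instruments for a
# candidate mediating trait by the sign of the trait effect, and
# estimate each directional GRS's effect on T2D from summary statistics.

#' Select dual-significant, clumped instruments for a candidate trait
#'
#' SNPs genome-wide significant for both the candidate trait and BMI,
#' harmonized and clumped, then aligned to the BMI-increasing allele.
#' The returned table reports the trait effect (`beta_trait`) alongside
#' the BMI effect.
#'
#' @param trait_ss Candidate-trait summary statistics.
#' @param bmi_ss BMI summary statistics.
#' @param panel A [reference_panel()] for clumping.
#' @param p_gw Significance threshold applied to both traits
#'   (default 5e-8).
#' @param r2_max,window_bp Clumping parameters.
#' @return Tibble of instruments aligned to the BMI-increasing allele:
#'   `snp_id`, `chrom`, `pos`, `bmi_allele`, `other_allele`, `eaf`,
#'   `beta_bmi`, `se_bmi`, `p_bmi`, `beta_trait`, `se_trait`, `p_trait`.
#'   Empty (with a warning) when nothing qualifies.
#' @export
select_trait_instruments <- function(trait_ss, bmi_ss, panel, p_gw = 5e-8,
                                     r2_max = 0.01, window_bp = 500000) {
  cand <- cross_reference(bmi_ss, trait_ss, maf_min = 0, p_gw = p_gw)
  if (!nrow(cand)) {
    warning("no dual-significant instruments for the candidate trait")
    return(tibble::tibble())
  }
  clumped <- clump(cand, panel, r2_max = r2_max, window_bp = window_bp)
  prof <- assign_profiles(clumped)
  dplyr::rename(prof, beta_trait = "beta_t2d", se_trait = "se_t2d",
                p_trait = "p_t2d")[, c("snp_id", "chrom", "pos",
                                       "bmi_allele", "other_allele", "eaf",
                                       "beta_bmi", "se_bmi", "p_bmi",
                                       "beta_trait", "se_trait", "p_trait")]
}

#' Partition instruments by the sign of the trait effect
#'
#' After BMI-increasing alignment, instruments with a positive trait
#' effect form the `trait_up` group and negative ones `trait_down`;
#' exact zeros are excluded. Either group may be empty.
#'
#' @param instruments Output of [select_trait_instruments()].
#' @return A list with tibbles `trait_up` and `trait_down`.
#' @export
split_by_sign <- function(instruments) {
  zero <- instruments$beta_trait == 0
  log_count("zero trait effects excluded from sign split", sum(zero))
  x <- instruments[!zero, , drop = FALSE]
  list(trait_up = x[x$beta_trait > 0, , drop = FALSE],
       trait_down = x[x$beta_trait < 0, , drop = FALSE])
}

#' Pooled per-allele outcome effect of a directional GRS from summary
#' statistics
#'
#' Fixed-effect inverse-variance pooling of the member SNPs' per-allele
#' outcome log-ORs, aligned to each member's BMI-increasing allele:
#' `betahat = sum(w * beta) / sum(w)` with `w = 1 / se^2` and
#' `se = 1 / sqrt(sum(w))`. A single-member group reduces to that SNP's
#' Wald estimate. A random-effects variant (Paule-Mandel) is available.
#'
#' @param group Instrument tibble (needs `snp_id`, `bmi_allele`,
#'   `other_allele`).
#' @param outcome_ss Outcome (T2D) summary statistics.
#' @param method `"ivw"` (default) or `"pm"`.
#' @return A list: `beta` (pooled log-OR per allele), `se`, `p`, `or`,
#'   `lo`, `hi` (95% CI on the OR scale), `k`.
#' @export
summary_grs_effect <- function(group, outcome_ss, method = c("ivw", "pm")) {
  method <- match.arg(method)
  if (!nrow(group)) stop("empty instrument group")
  idx <- match(group$snp_id, outcome_ss$snp_id)
  found <- !is.na(idx)
  if (!any(found)) stop("no instruments found in outcome summary statistics")
  o <- outcome_ss[idx[found], ]
  g <- group[found, ]
  same <- o$ea == g$bmi_allele & o$oa == g$other_allele
  flip <- o$ea == g$other_allele & o$oa == g$bmi_allele
  ok <- same | flip
  beta <- ifelse(flip, -o$beta, o$beta)[ok]
  se <- o$se[ok]
  if (!length(beta)) stop("no allele-matched instruments in outcome")
  if (method == "ivw") {
    w <- 1 / se^2
    bh <- sum(w * beta) / sum(w)
    s <- 1 / sqrt(sum(w))
  } else {
    pm <- pm_meta(beta, se)
    bh <- pm$beta_hat
    s <- pm$se
  }
  list(beta = bh, se = s, p = 2 * stats::pnorm(-abs(bh / s)),
       or = exp(bh), lo = exp(bh - 1.96 * s), hi = exp(bh + 1.96 * s),
       k = length(beta))
}

#' Single cis instrument for a protein
#'
#' The strongest (smallest protein p) SNP within the gene's cis window
#' that is genome-wide significant for both the protein level and BMI;
#' ties broken by position, then id. `NULL` when no SNP qualifies.
#'
#' @param protein_ss Protein summary statistics.
#' @param bmi_ss BMI summary statistics.
#' @param tss Transcription start site of the encoding gene.
#' @param chrom Chromosome of the gene.
#' @param window_bp cis window half-width (default 500 kb).
#' @param p_gw Significance threshold for both traits (default 5e-8).
#' @return One harmonized row (protein = study A, BMI = study B
#'   columns) or `NULL`.
#' @export
cis_instrument <- function(protein_ss, bmi_ss, tss, chrom,
                           window_bp = 500000, p_gw = 5e-8) {
  h <- harmonized_kept(harmonize(protein_ss, bmi_ss))
  h <- h[h$chrom == chrom & abs(h$pos - tss) <= window_bp &
           h$p_a < p_gw & h$p_b < p_gw, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  h[order(h$p_a, h$pos, h$snp_id), ][1, , drop = FALSE]
}
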