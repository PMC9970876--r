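# Selection and labelling of concordant/discordant instruments from a
# paired BMI/T2D GWAS.

#' Cross-reference two GWAS and keep dual genome-wide-significant SNPs
#'
#' Retains SNPs present in both studies that survive harmonization
#' (biallelic single-base alleles, non-ambiguous palindromes), have
#' MAF > `maf_min`, and are associated with BOTH traits at `p < p_gw`.
#'
#' @param bmi_ss,t2d_ss Validated summary-statistics tibbles.
#' @param maf_min Minor-allele-frequency floor (default 0.01).
#' @param p_gw Genome-wide significance threshold (default 5e-8).
#' @param palindrome_maf_cut Passed to [harmonize()].
#' @return Harmonized candidate pairs (columns as [harmonize()], study A
#'   = BMI, study B = T2D), retained rows only. Emits a warning when the
#'   intersection is empty.
#' @export
cross_reference <- function(bmi_ss, t2d_ss, maf_min = 0.01, p_gw = 5e-8,
                            palindrome_maf_cut = 0.30) {
  h <- harmonized_kept(harmonize(bmi_ss, t2d_ss, palindrome_maf_cut))
  keep <- maf_of(h$eaf) > maf_min & h$p_a < p_gw & h$p_b < p_gw
  out <- h[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no SNPs pass the cross-reference filters")
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the top-ranked remaining SNP and removes all
#' remaining SNPs with `r^2 >= r2_max` within `window_bp` of it. The
#' output preserves selection order. Candidates absent from the panel are
#' dropped with a logged count.
#'
#' @param candidates Harmonized pairs from [cross_reference()] (needs
#'   `snp_id`, `chrom`, `pos`, `p_a`, `p_b`).
#' @param panel A [reference_panel()].
#' @param r2_max LD threshold (default 0.01; retained pairs within the
#'   window all have `r^2 < r2_max`).
#' @param window_bp Window half-width (default 500000, inclusive).
#' @param rank_stat Ranking statistic: `"sum_logp"` (default; sum of
#'   -log10 p across the two studies), `"min_p"`, or `"p_a"` (first
#'   study's p-value).
#' @return The retained rows of `candidates`, in selection order.
#' @export
clump <- function(candidates, panel, r2_max = 0.01, window_bp = 500000,
                  rank_stat = c("sum_logp", "min_p", "p_a")) {
  rank_stat <- match.arg(rank_stat)
  present <- candidates$snp_id %in% panel$snps$snp_id
  log_count("clump candidates absent from panel", sum(!present))
  cand <- candidates[present, , drop = FALSE]
  if (nrow(cand) == 0L) return(cand)
  score <- switch(rank_stat,
    sum_logp = -log10(cand$p_a) - log10(cand$p_b),
    min_p = -log10(pmin(cand$p_a, cand$p_b)),
    p_a = -log10(cand$p_a)
  )
  ord <- order(-score, cand$snp_id)  # deterministic tie-break by id
  cand <- cand[ord, , drop = FALSE]
  taken <- logical(nrow(cand))
  alive <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    taken[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive & cand$chrom == cand$chrom[i] &
                    abs(cand$pos - cand$pos[i]) <= window_bp)
    if (length(near)) {
      r2 <- vapply(cand$snp_id[near], function(s) {
        ld_r2(panel, cand$snp_id[i], s)
      }, numeric(1))
      alive[near[r2 >= r2_max]] <- FALSE
    }
  }
  cand[taken, , drop = FALSE]
}

#' Align to the BMI-increasing allele and label profiles
#'
#' Flips any pair with a negative BMI effect (both betas negated, alleles
#' and allele frequency swapped), so `beta_bmi > 0` for every retained
#' SNP, then labels each SNP `"concordant"` if its aligned T2D log-OR is
#' positive and `"discordant"` if negative. SNPs with `beta_t2d == 0`
#' (labels are sign-defined) or `beta_bmi == 0` are excluded with a
#' logged count.
#'
#' @param clumped Harmonized pairs (study A = BMI, study B = T2D).
#' @return A tibble of profile SNPs: `snp_id`, `chrom`, `pos`,
#'   `bmi_allele`, `other_allele`, `eaf` (frequency of the BMI-increasing
#'   allele), `beta_bmi`, `se_bmi`, `p_bmi`, `beta_t2d`, `se_t2d`,
#'   `p_t2d`, `label`.
#' @export
assign_profiles <- function(clumped) {
  zero <- clumped$beta_b == 0 | clumped$beta_a == 0
  log_count("SNPs with zero effect excluded from labelling", sum(zero))
  x <- clumped[!zero, , drop = FALSE]
  flip <- x$beta_a < 0
  tibble::tibble(
    snp_id = x$snp_id, chrom = x$chrom, pos = x$pos,
    bmi_allele = ifelse(flip, x$other_allele, x$effect_allele),
    other_allele = ifelse(flip, x$effect_allele, x$other_allele),
    eaf = ifelse(flip, 1 - x$eaf, x$eaf),
    beta_bmi = abs(x$beta_a), se_bmi = x$se_a, p_bmi = x$p_a,
    beta_t2d = ifelse(flip, -x$beta_b, x$beta_b),
    se_t2d = x$se_b, p_t2d = x$p_b,
    label = ifelse(ifelse(flip, -x$beta_b, x$beta_b) > 0,
                   "concordant", "discordant")
  )
}

#' Sign replication against an independent T2D GWAS
#'
#' For each profile SNP, aligns the replication record to the
#' BMI-increasing allele and records whether the replication T2D effect
#' has the same sign as the discovery effect. SNPs missing from the
#' replication study (or failing allele matching) are left `NA`.
#'
#' @param profiles Output of [assign_profiles()].
#' @param replication_ss Replication summary-statistics tibble.
#' @return `profiles` with a logical `replicated_sign` column.
#' @export
replicate_signs <- function(profiles, replication_ss) {
  rep_idx <- match(profiles$snp_id, replication_ss$snp_id)
  replicated <- rep(NA, nrow(profiles))
  found <- !is.na(rep_idx)
  if (any(found)) {
    r <- replication_ss[rep_idx[found], , drop = FALSE]
    same <- r$ea == profiles$bmi_allele[found] &
      r$oa == profiles$other_allele[found]
    flipped <- r$ea == profiles$other_allele[found] &
      r$oa == profiles$bmi_allele[found]
    beta_rep <- ifelse(flipped, -r$beta, r$beta)
    ok <- same | flipped
    replicated[found][ok] <-
      sign(beta_rep[ok]) == sign(profiles$beta_t2d[found][ok])
  }
  profiles$replicated_sign <- replicated
  profiles
}

#' End-to-end instrument selection
#'
#' Convenience wrapper: [cross_reference()], [clump()],
#' [assign_profiles()] and optionally [replicate_signs()].
#'
#' @inheritParams cross_reference
#' @inheritParams clump
#' @param replication_ss Optional replication summary statistics.
#' @return A profile-SNP tibble.
#' @export
select_instruments <- function(bmi_ss, t2d_ss, panel, maf_min = 0.01,
                               p_gw = 5e-8, r2_max = 0.01,
                               window_bp = 500000,
                               rank_stat = "sum_logp",
                               replication_ss = NULL) {
  cand <- cross_reference(bmi_ss, t2d_ss, maf_min = maf_min, p_gw = p_gw)
  clumped <- clump(cand, panel, r2_max = r2_max, window_bp = window_bp,
                   rank_stat = rank_stat)
  prof <- assign_profiles(clumped)
  if (!is.null(replication_ss)) prof <- replicate_signs(prof, replication_ss)
  prof
}
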