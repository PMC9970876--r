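# Tissue-of-action scoring: expression specificity combined with
# promoter/enhancer evidence at the lead instrument.

#' Expression specificity of a gene across tissues
#'
#' The fraction of the gene's summed median expression contributed by
#' each tissue: `fraction_t = median_TPM_t / sum_t(median_TPM_t)`.
#'
#' @param tpm_table Long tibble `tissue`, `gene`, `median_tpm`.
#' @param gene Gene id.
#' @return Named numeric vector of per-tissue fractions (sums to 1).
#' @export
specificity <- function(tpm_table, gene) {
  sub <- tpm_table[tpm_table$gene == gene, , drop = FALSE]
  if (!nrow(sub)) stop("gene not present in expression table: ", gene)
  total <- sum(sub$median_tpm)
  if (total <= 0) stop("gene has zero total expression: ", gene)
  stats::setNames(sub$median_tpm / total, sub$tissue)
}

EVIDENCE_LEVELS <- c(none = 0, enhancer = 1, promoter = 2, both = 3)

#' Epigenetic evidence per tissue at a lead instrument
#'
#' For each tissue, collects promoter/enhancer marks overlapping the
#' lead SNP or any of its LD proxies (`r^2 >= proxy_r2`) in any cell
#' line mapped to that tissue. A tissue with both mark types reports
#' `"both"`, otherwise the strongest single mark
#' (promoter > enhancer > none).
#'
#' @param lead_snp Lead instrument id.
#' @param proxies Tibble `snp_id`, `r2` of LD proxies (may be empty).
#' @param annotation Tibble `snp_id`, `cell_line`, `mark` with `mark` in
#'   `{promoter, enhancer}`.
#' @param cellline_map Tibble `cell_line`, `tissue`.
#' @param proxy_r2 Proxy propagation threshold (default 0.8).
#' @return Named character vector: evidence level per mapped tissue.
#' @export
epi_evidence <- function(lead_snp, proxies = NULL, annotation,
                         cellline_map, proxy_r2 = 0.8) {
  snps <- lead_snp
  if (!is.null(proxies) && nrow(proxies)) {
    snps <- c(snps, proxies$snp_id[proxies$r2 >= proxy_r2])
  }
  tissues <- unique(cellline_map$tissue)
  ev <- stats::setNames(rep("none", length(tissues)), tissues)
  hits <- annotation[annotation$snp_id %in% snps, , drop = FALSE]
  if (nrow(hits)) {
    hits$tissue <- cellline_map$tissue[match(hits$cell_line,
                                             cellline_map$cell_line)]
    hits <- hits[!is.na(hits$tissue), , drop = FALSE]
    for (tis in unique(hits$tissue)) {
      marks <- unique(hits$mark[hits$tissue == tis])
      ev[tis] <- if (all(c("promoter", "enhancer") %in% marks)) "both"
                 else if ("promoter" %in% marks) "promoter"
                 else "enhancer"
    }
  }
  ev
}

#' Tissue-of-action score and ranking
#'
#' Combines expression specificity with the epigenetic evidence level
#' multiplicatively: `score = specificity * weight(evidence)` with
#' default weights none = 1, enhancer = 2, promoter = 3, both = 4. The
#' combination rule is a package construction (the two raw criteria are
#' always emitted alongside it, and the weights are configurable); the
#' ranking sorts descending by score with ties broken by specificity and
#' then tissue name. `log10_score` is `NA` where the score is zero.
#'
#' @param spec Named specificity vector from [specificity()].
#' @param evidence Named evidence vector from [epi_evidence()] (tissues
#'   absent default to `"none"`).
#' @param weights Named numeric weights for the four evidence levels.
#' @return A tibble sorted by rank: `tissue`, `specificity`,
#'   `epi_evidence`, `score`, `log10_score`, `rank`.
#' @export
tissue_of_action <- function(spec, evidence = NULL,
                             weights = c(none = 1, enhancer = 2,
                                         promoter = 3, both = 4)) {
  tissues <- names(spec)
  ev <- stats::setNames(rep("none", length(tissues)), tissues)
  if (!is.null(evidence)) {
    shared <- intersect(tissues, names(evidence))
    ev[shared] <- evidence[shared]
  }
  score <- unname(spec) * weights[ev]
  out <- tibble::tibble(
    tissue = tissues,
    specificity = unname(spec),
    epi_evidence = unname(ev),
    score = unname(score),
    log10_score = ifelse(score > 0, log10(score), NA_real_)
  )
  out <- out[order(-out$score, -out$specificity, out$tissue), ]
  out$rank <- seq_len(nrow(out))
  out
}
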