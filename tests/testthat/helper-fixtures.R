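# Shared fixtures, built in code.

# minimal well-formed summary-statistics tibble
make_ss <- function(snp_id, ea, oa, beta, se = 0.01, p = NULL,
                    eaf = 0.3, chrom = "1", pos = NULL, n = 1e5) {
  k <- length(snp_id)
  tibble::tibble(
    snp_id = snp_id, chrom = rep_len(chrom, k),
    pos = if (is.null(pos)) seq_len(k) * 1000L else as.integer(pos),
    ea = ea, oa = oa, eaf = rep_len(eaf, k),
    beta = beta, se = rep_len(se, k),
    p = if (is.null(p)) 2 * stats::pnorm(-abs(beta / rep_len(se, k))) else p,
    n = rep_len(n, k)
  )
}

# tiny hand-built reference panel with known dosage columns
make_panel <- function(dosage_cols, pos = NULL, chrom = "1") {
  m <- length(dosage_cols)
  ids <- names(dosage_cols) %||% paste0("s", seq_len(m))
  snps <- tibble::tibble(
    snp_id = ids, chrom = rep_len(chrom, m),
    pos = if (is.null(pos)) seq_len(m) * 1000L else as.integer(pos),
    ref = "A", alt = "G"
  )
  reference_panel(snps, do.call(cbind, unname(dosage_cols)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# small synthetic world shared by several tests (cheap config)
small_config <- function(seed = 1, ...) {
  truth_config(seed = seed, n_blocks = 25, snps_per_block = 6,
               n_concordant = 12, n_discordant = 5, n_panel = 800, ...)
}
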