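# Reading, validation, harmonization and LD utilities for GWAS summary
# statistics and reference-panel genotypes.

SUMSTATS_REQUIRED <- c("snp_id", "chrom", "pos", "ea", "oa",
                       "eaf", "beta", "se", "p", "n")
SUMSTATS_OPTIONAL <- c("n_cases", "n_controls")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited file with a header row into a validated tibble of
#' per-SNP association records. Required columns are `snp_id`, `chrom`,
#' `pos`, `ea` (effect allele), `oa` (other allele), `eaf`, `beta`, `se`,
#' `p` and `n`; `n_cases`/`n_controls` are optional. Non-canonical headers
#' can be mapped via `column_map`.
#'
#' Rows violating the record invariants (non-single-base or identical
#' alleles, `se <= 0`, `p` outside (0, 1], `n <= 0`, inconsistent
#' case/control counts) are dropped; the number of dropped rows is
#' reported via [message()] and attached as attribute `n_dropped`.
#' A missing `eaf` is tolerated (it may be recovered from a second study
#' during harmonization).
#'
#' @param path Path to a delimited text file (tab-separated).
#' @param column_map Optional named character vector mapping canonical
#'   field names (names) to the column names used in the file (values),
#'   e.g. `c(p = "P_value")`.
#' @return A tibble of summary-statistic records.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  if (nrow(tbl) == 0L) stop("empty summary-statistics file: ", path)
  if (!is.null(column_map)) {
    bad <- setdiff(unname(column_map), names(tbl))
    if (length(bad)) stop("column_map refers to missing columns: ",
                          paste(bad, collapse = ", "))
    for (canon in names(column_map)) {
      names(tbl)[names(tbl) == column_map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(SUMSTATS_REQUIRED, names(tbl))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  keep <- intersect(c(SUMSTATS_REQUIRED, SUMSTATS_OPTIONAL), names(tbl))
  tbl <- tbl[keep]
  tbl$snp_id <- as.character(tbl$snp_id)
  tbl$chrom <- as.character(tbl$chrom)
  tbl$pos <- as.integer(tbl$pos)
  tbl$ea <- toupper(as.character(tbl$ea))
  tbl$oa <- toupper(as.character(tbl$oa))
  for (col in intersect(c("eaf", "beta", "se", "p", "n",
                          "n_cases", "n_controls"), names(tbl))) {
    tbl[[col]] <- as.numeric(tbl[[col]])
  }
  validate_sumstats(tibble::as_tibble(tbl))
}

validate_sumstats <- function(tbl) {
  ok <- is_single_base(tbl$ea) & is_single_base(tbl$oa) & tbl$ea != tbl$oa &
    !is.na(tbl$beta) & is.finite(tbl$beta) &
    !is.na(tbl$se) & tbl$se > 0 &
    !is.na(tbl$p) & tbl$p > 0 & tbl$p <= 1 &
    !is.na(tbl$n) & tbl$n > 0 &
    !is.na(tbl$pos) & tbl$pos >= 1
  ok <- ok & (is.na(tbl$eaf) | (tbl$eaf > 0 & tbl$eaf < 1))
  if (all(c("n_cases", "n_controls") %in% names(tbl))) {
    cc <- !is.na(tbl$n_cases) & !is.na(tbl$n_controls)
    ok[cc] <- ok[cc] & (tbl$n_cases[cc] + tbl$n_controls[cc] == tbl$n[cc])
  }
  dropped <- sum(!ok)
  log_count("summary-statistics rows dropped at validation", dropped)
  out <- tbl[ok, , drop = FALSE]
  attr(out, "n_dropped") <- dropped
  out
}

#' Write a summary-statistics table
#'
#' Writes tab-separated text that [read_sumstats()] reads back unchanged
#' (15 significant digits, enough for a bit-faithful double round trip in
#' practice).
#'
#' @param tbl Summary-statistics tibble.
#' @param path Output path.
#' @export
write_sumstats <- function(tbl, path) {
  fmt <- tbl
  num <- vapply(fmt, is.numeric, logical(1)) & !vapply(fmt, is.integer, logical(1))
  for (col in names(fmt)[num]) fmt[[col]] <- format(fmt[[col]], digits = 17,
                                                    trim = TRUE, scientific = NA)
  readr::write_tsv(fmt, path, progress = FALSE)
  invisible(path)
}

#' Harmonize two summary-statistics tables to a shared effect allele
#'
#' Records are matched by `snp_id`. When study B reports the effect on the
#' allele study A calls "other", B's beta sign is flipped and its allele
#' frequency complemented, so both effects end up expressed per copy of
#' A's effect allele. Strand flips are never attempted: allele sets that
#' do not match after this strand-free comparison are dropped.
#' Potentially ambiguous palindromic SNPs (A/T or C/G pairs) with
#' MAF > `palindrome_maf_cut` are dropped; MAF is `min(eaf, 1 - eaf)`
#' taken from study A (falling back to study B when A's `eaf` is
#' missing). SNPs with `eaf` missing in both studies are dropped.
#'
#' @param a,b Summary-statistics tibbles (study A fixes the reference
#'   orientation).
#' @param palindrome_maf_cut MAF threshold above which palindromic SNPs
#'   are considered ambiguous (default 0.30).
#' @return A tibble with one row per shared SNP: `snp_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `beta_a`, `se_a`,
#'   `p_a`, `n_a`, `beta_b`, `se_b`, `p_b`, `n_b` and `drop_reason`
#'   (`NA` for retained rows; effect fields are `NA` on dropped rows).
#' @export
harmonize <- function(a, b, palindrome_maf_cut = 0.30) {
  assert_scalar_number(palindrome_maf_cut, "palindrome_maf_cut", 0, 0.5)
  j <- dplyr::inner_join(a, b, by = "snp_id", suffix = c("_a", "_b"))
  if (nrow(j) == 0L) {
    return(tibble::tibble(snp_id = character(), chrom = character(),
                          pos = integer(), effect_allele = character(),
                          other_allele = character(), eaf = numeric(),
                          beta_a = numeric(), se_a = numeric(), p_a = numeric(),
                          n_a = numeric(), beta_b = numeric(), se_b = numeric(),
                          p_b = numeric(), n_b = numeric(),
                          drop_reason = character()))
  }
  same <- j$ea_b == j$ea_a & j$oa_b == j$oa_a
  flipped <- j$ea_b == j$oa_a & j$oa_b == j$ea_a

  eaf_b_aligned <- ifelse(flipped, 1 - j$eaf_b, j$eaf_b)
  eaf <- ifelse(!is.na(j$eaf_a), j$eaf_a, eaf_b_aligned)

  reason <- rep(NA_character_, nrow(j))
  reason[!(same | flipped)] <- "allele_mismatch"
  pal <- is_palindromic_pair(j$ea_a, j$oa_a)
  ambiguous <- pal & !is.na(eaf) & maf_of(eaf) > palindrome_maf_cut
  reason[is.na(reason) & ambiguous] <- "palindromic_ambiguous"
  reason[is.na(reason) & is.na(eaf)] <- "missing_eaf"

  keep <- is.na(reason)
  beta_b <- ifelse(flipped, -j$beta_b, j$beta_b)
  out <- tibble::tibble(
    snp_id = j$snp_id,
    chrom = j$chrom_a,
    pos = j$pos_a,
    effect_allele = j$ea_a,
    other_allele = j$oa_a,
    eaf = ifelse(keep, eaf, NA_real_),
    beta_a = ifelse(keep, j$beta_a, NA_real_),
    se_a = ifelse(keep, j$se_a, NA_real_),
    p_a = ifelse(keep, j$p_a, NA_real_),
    n_a = ifelse(keep, j$n_a, NA_real_),
    beta_b = ifelse(keep, beta_b, NA_real_),
    se_b = ifelse(keep, j$se_b, NA_real_),
    p_b = ifelse(keep, j$p_b, NA_real_),
    n_b = ifelse(keep, j$n_b, NA_real_),
    drop_reason = reason
  )
  log_count("SNPs dropped during harmonization", sum(!keep))
  out
}

#' Keep only successfully harmonized rows
#' @param h Output of [harmonize()].
#' @return The retained rows.
#' @export
harmonized_kept <- function(h) h[is.na(h$drop_reason), , drop = FALSE]

#' Construct a genotype reference panel
#'
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`
#'   (dosages count copies of `alt`).
#' @param dosage Numeric matrix, individuals x SNPs, values in \[0, 2\],
#'   columns in the order of `snps`.
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(snps, dosage) {
  stopifnot(is.matrix(dosage), nrow(snps) == ncol(dosage))
  if (any(dosage < 0 | dosage > 2)) stop("dosages must lie in [0, 2]")
  colnames(dosage) <- snps$snp_id
  structure(list(snps = tibble::as_tibble(snps), dosage = dosage),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %d individuals x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

panel_index <- function(panel, ids) {
  idx <- match(ids, panel$snps$snp_id)
  if (anyNA(idx)) stop("SNP(s) absent from panel: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Read a reference panel from a dosage-matrix TSV
#'
#' Expected layout: a SNP metadata block is not required; the first
#' column holds individual ids and each remaining column one SNP, with
#' the header carrying SNP ids. Coordinates and alleles come from a
#' companion metadata table.
#'
#' @param dosage_path TSV with individual ids in the first column and
#'   dosages in \[0, 2\] in the remaining columns.
#' @param snp_meta Tibble `snp_id`, `chrom`, `pos`, `ref`, `alt` (or a
#'   path to a TSV with those columns) covering every dosage column.
#' @return A [reference_panel()].
#' @export
read_panel_tsv <- function(dosage_path, snp_meta) {
  tbl <- readr::read_tsv(dosage_path, show_col_types = FALSE, progress = FALSE)
  if (is.character(snp_meta)) {
    snp_meta <- readr::read_tsv(snp_meta, show_col_types = FALSE,
                                progress = FALSE)
  }
  ids <- names(tbl)[-1]
  meta <- snp_meta[match(ids, snp_meta$snp_id), , drop = FALSE]
  if (anyNA(meta$snp_id)) stop("dosage columns missing from snp metadata")
  dosage <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(dosage) <- as.character(tbl[[1]])
  reference_panel(tibble::as_tibble(meta), dosage)
}

#' Read a reference panel from a VCF file
#'
#' Biallelic records only; dosages come from the DS FORMAT field when
#' present, otherwise from GT allele counts. Multiallelic records are
#' dropped with a logged count.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return A [reference_panel()].
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF panels requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT, fixed = TRUE)
  log_count("multiallelic VCF records dropped", sum(!biallelic))
  v <- v[biallelic, ]
  fix <- fix[biallelic, , drop = FALSE]
  fmt <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (all(is.na(fmt))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    fmt <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(a) sum(a == "1"), numeric(1))
    })
    if (is.null(dim(fmt))) fmt <- matrix(fmt, nrow = nrow(fix))
  }
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  snps <- tibble::tibble(snp_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT)
  reference_panel(snps, t(fmt))
}

#' Squared LD correlation between two panel SNPs
#'
#' Squared Pearson correlation of dosages; symmetric in its arguments and
#' invariant to allele recoding (dosage -> 2 - dosage).
#'
#' @param panel A [reference_panel()].
#' @param snp_i,snp_j SNP ids.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(panel, snp_i, snp_j) {
  idx <- panel_index(panel, c(snp_i, snp_j))
  x <- panel$dosage[, idx[1]]
  y <- panel$dosage[, idx[2]]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero-variance SNP dosage; LD undefined")
  }
  stats::cor(x, y)^2
}

#' Pairwise LD r-squared matrix for a set of panel SNPs
#' @param panel A [reference_panel()].
#' @param ids SNP ids.
#' @return Square matrix of squared dosage correlations.
#' @export
ld_matrix <- function(panel, ids) {
  idx <- panel_index(panel, ids)
  r <- stats::cor(panel$dosage[, idx, drop = FALSE])
  r2 <- r^2
  dimnames(r2) <- list(ids, ids)
  r2
}

# signed dosage correlation, used for proxy allele alignment
ld_r_signed <- function(panel, snp_i, snp_j) {
  idx <- panel_index(panel, c(snp_i, snp_j))
  stats::cor(panel$dosage[, idx[1]], panel$dosage[, idx[2]])
}

#' Find the best LD proxy for a target SNP
#'
#' Among `candidates` within `window_bp` of the target, returns the id
#' with maximal r-squared to the target provided it reaches `r2_min`;
#' otherwise `NULL`. Ties are broken by smaller base-pair distance, then
#' lexicographically by id. Windows are symmetric and inclusive:
#' `|pos_i - pos_j| <= window_bp`.
#'
#' @param panel A [reference_panel()].
#' @param target Target SNP id (must be present in the panel).
#' @param candidates Candidate SNP ids (absent ones are ignored).
#' @param r2_min Minimum r-squared (default 0.5).
#' @param window_bp Window half-width in base pairs (default 500000).
#' @return The best proxy id, or `NULL` if none qualifies.
#' @export
find_proxy <- function(panel, target, candidates, r2_min = 0.5,
                       window_bp = 500000) {
  ti <- panel_index(panel, target)
  tpos <- panel$snps$pos[ti]
  tchrom <- panel$snps$chrom[ti]
  cand <- setdiff(intersect(candidates, panel$snps$snp_id), target)
  if (!length(cand)) return(NULL)
  ci <- match(cand, panel$snps$snp_id)
  inwin <- panel$snps$chrom[ci] == tchrom &
    abs(panel$snps$pos[ci] - tpos) <= window_bp
  cand <- cand[inwin]
  ci <- ci[inwin]
  if (!length(cand)) return(NULL)
  tv <- panel$dosage[, ti]
  r2 <- vapply(ci, function(k) {
    v <- panel$dosage[, k]
    if (stats::var(v) == 0 || stats::var(tv) == 0) return(0)
    stats::cor(tv, v)^2
  }, numeric(1))
  dist <- abs(panel$snps$pos[ci] - tpos)
  ord <- order(-r2, dist, cand)
  best <- ord[1]
  if (r2[best] >= r2_min) cand[best] else NULL
}
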