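test_that("read_sumstats parses well-formed files and applies column maps", {
  tbl <- make_ss(c("rs1", "rs2"), ea = c("A", "C"), oa = c("G", "T"),
                 beta = c(0.1, -0.2))
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, f)
  got <- read_sumstats(f)
  expect_equal(nrow(got), 2)
  expect_equal(got$beta, tbl$beta)
  expect_equal(attr(got, "n_dropped"), 0)

  # remapped header must give the same records as the canonical copy
  tbl2 <- dplyr::rename(tbl, P_value = "p", Effect = "beta")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl2, f2)
  got2 <- read_sumstats(f2, column_map = c(p = "P_value", beta = "Effect"))
  expect_equal(as.data.frame(got2), as.data.frame(got))

  expect_error(read_sumstats(f2), "missing required columns")
})

test_that("rows violating record invariants are dropped and counted", {
  tbl <- make_ss(c("rs1", "rs2", "rs3"), ea = c("A", "C", "A"),
                 oa = c("G", "T", "G"), beta = c(0.1, 0.2, 0.3))
  tbl$se[2] <- 0            # invalid
  tbl$p[3] <- 1.5           # invalid
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, f)
  got <- suppressMessages(read_sumstats(f))
  expect_equal(nrow(got), 1)
  expect_equal(attr(got, "n_dropped"), 2)
  expect_equal(got$snp_id, "rs1")
})

test_that("write/read round trip preserves every retained field", {
  tbl <- make_ss(paste0("rs", 1:5), ea = rep("A", 5), oa = rep("G", 5),
                 beta = rnorm(5) * 1e-3, se = runif(5, 1e-4, 1e-2),
                 p = 10^-runif(5, 1, 30))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tbl, f)
  back <- read_sumstats(f)
  for (col in names(tbl)) expect_equal(back[[col]], tbl[[col]], info = col)
})

test_that("harmonize aligns flipped records and is involution-safe", {
  a <- make_ss("rs1", ea = "A", oa = "G", beta = 0.1)
  b <- make_ss("rs1", ea = "G", oa = "A", beta = 0.2, eaf = 0.7)
  h <- harmonize(a, b)
  expect_true(is.na(h$drop_reason))
  expect_equal(h$beta_b, -0.2)
  expect_equal(h$effect_allele, "A")

  # harmonizing the already-aligned pair again changes nothing
  b2 <- make_ss("rs1", ea = h$effect_allele, oa = h$other_allele,
                beta = h$beta_b, eaf = h$eaf)
  h2 <- harmonize(a, b2)
  expect_equal(h2$beta_b, h$beta_b)
  expect_equal(h2$effect_allele, h$effect_allele)
})

test_that("palindromic SNPs are dropped only above the MAF cut", {
  a_hi <- make_ss("rs1", ea = "A", oa = "T", beta = 0.1, eaf = 0.45)
  b_hi <- make_ss("rs1", ea = "A", oa = "T", beta = 0.2, eaf = 0.45)
  h_hi <- suppressMessages(harmonize(a_hi, b_hi))
  expect_equal(h_hi$drop_reason, "palindromic_ambiguous")
  expect_true(is.na(h_hi$beta_b))

  a_lo <- make_ss("rs1", ea = "A", oa = "T", beta = 0.1, eaf = 0.10)
  b_lo <- make_ss("rs1", ea = "A", oa = "T", beta = 0.2, eaf = 0.10)
  h_lo <- harmonize(a_lo, b_lo)
  expect_true(is.na(h_lo$drop_reason))
  expect_equal(h_lo$beta_b, 0.2)   # below cut, no flip

  a_mm <- make_ss("rs1", ea = "A", oa = "G", beta = 0.1)
  b_mm <- make_ss("rs1", ea = "A", oa = "C", beta = 0.2)
  expect_equal(suppressMessages(harmonize(a_mm, b_mm))$drop_reason,
               "allele_mismatch")
})

test_that("ld_r2 is symmetric, recode-invariant and exact on known columns", {
  x <- c(0, 1, 2, 1, 0, 2, 1, 1)
  panel <- make_panel(list(a = x, b = x, c = 2 - x,
                           d = c(0, 0, 1, 2, 2, 1, 0, 1)))
  expect_equal(ld_r2(panel, "a", "b"), 1.0)
  expect_equal(ld_r2(panel, "a", "c"), 1.0)  # reflection, sign-invariant
  expect_equal(ld_r2(panel, "a", "d"), ld_r2(panel, "d", "a"))
  panel0 <- make_panel(list(a = x, z = rep(1, 8)))
  expect_error(ld_r2(panel0, "a", "z"), "zero-variance")
})

test_that("independently simulated SNPs have r2 below the clumping cut", {
  hits <- 0
  for (s in 1:100) {
    withr::with_seed(s, {
      x <- rbinom(5000, 2, 0.3)
      y <- rbinom(5000, 2, 0.3)
    })
    p <- make_panel(list(a = x, b = y))
    if (ld_r2(p, "a", "b") < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("find_proxy respects threshold, window and tie rules", {
  withr::with_seed(42, {
    x <- rbinom(2000, 2, 0.4)
    noise <- function(k) ifelse(runif(2000) < k, sample(0:2, 2000, TRUE), x)
  })
  panel <- make_panel(list(t = x, perfect = x, weak = noise(0.9)),
                      pos = c(1e6, 1.1e6, 1.05e6))
  expect_equal(find_proxy(panel, "t", c("perfect", "weak")), "perfect")
  expect_true(ld_r2(panel, "t", "weak") < 0.5)
  expect_null(find_proxy(panel, "t", "weak"))

  # tie on r2: nearer candidate wins
  panel2 <- make_panel(list(t = x, far = x, near = x),
                       pos = c(1e6, 1e6 + 1e5, 1e6 + 1e4))
  expect_equal(find_proxy(panel2, "t", c("far", "near")), "near")
  # outside the window: no proxy
  panel3 <- make_panel(list(t = x, out = x), pos = c(1e6, 1.6e6))
  expect_null(find_proxy(panel3, "t", "out"))
  expect_error(find_proxy(panel3, "absent", "out"), "absent from panel")
})

test_that("reference panels load from dosage TSV and VCF text", {
  meta <- tibble::tibble(snp_id = c("rs1", "rs2"), chrom = "1",
                         pos = c(100L, 200L), ref = c("A", "C"),
                         alt = c("G", "T"))
  dosf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(individual_id = c("i1", "i2", "i3"),
                                  rs1 = c(0, 1, 2), rs2 = c(2, 1, 0)), dosf)
  p <- read_panel_tsv(dosf, meta)
  expect_s3_class(p, "reference_panel")
  expect_equal(unname(p$dosage[, "rs1"]), c(0, 1, 2))
  expect_equal(ld_r2(p, "rs1", "rs2"), 1)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ti1\ti2\ti3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0",
    "1\t300\trs3\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1"
  ), vcf)
  pv <- suppressMessages(read_panel_vcf(vcf))
  expect_equal(pv$snps$snp_id, c("rs1", "rs2"))  # multiallelic dropped
  expect_equal(unname(pv$dosage[, "rs1"]), c(0, 1, 2))
  expect_equal(unname(pv$dosage[, "rs2"]), c(2, 1, 0))
})
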