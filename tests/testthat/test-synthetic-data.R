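test_that("reference panel has block LD structure, bounded MAF and is deterministic", {
  cfg <- truth_config(seed = 8, n_blocks = 50, snps_per_block = 4,
                      within_block_ld = 0.9, n_panel = 5000,
                      n_concordant = 3, n_discordant = 2)
  panel <- simulate_reference_panel(cfg)
  eaf <- colMeans(panel$dosage) / 2
  expect_true(all(pmin(eaf, 1 - eaf) <= 0.5))
  # adjacent within-block dosage r2 concentrates near ld^2 = 0.81
  r2 <- sapply(seq_len(50), function(b) {
    i <- (b - 1) * 4 + 1
    cor(panel$dosage[, i], panel$dosage[, i + 1])^2
  })
  expect_lt(abs(mean(r2) - 0.81), 0.05)
  # across blocks: independent
  r2x <- sapply(seq_len(49), function(b) {
    cor(panel$dosage[, b * 4], panel$dosage[, b * 4 + 1])^2
  })
  expect_lt(mean(r2x), 0.01)
  # determinism
  panel2 <- simulate_reference_panel(cfg)
  expect_identical(panel$dosage, panel2$dosage)
  expect_identical(panel$snps, panel2$snps)

  # zero LD: off-diagonal r2 at the null level
  cfg0 <- truth_config(seed = 8, n_blocks = 20, snps_per_block = 4,
                       within_block_ld = 0, n_panel = 5000,
                       n_concordant = 3, n_discordant = 2)
  p0 <- simulate_reference_panel(cfg0)
  r20 <- sapply(seq_len(20), function(b) {
    i <- (b - 1) * 4 + 1
    cor(p0$dosage[, i], p0$dosage[, i + 1])^2
  })
  expect_lt(mean(r20), 0.01)
})

test_that("gwas pair is deterministic, null-calibrated, and SEs follow the MAF/n law", {
  cfg <- small_config(seed = 21)
  panel <- simulate_reference_panel(cfg)
  gw1 <- simulate_gwas_pair(cfg, panel)
  gw2 <- simulate_gwas_pair(cfg, panel)
  expect_identical(gw1, gw2)
  expect_equal(sum(gw1$truth$role == "concordant"), 12)
  expect_equal(sum(gw1$truth$role == "discordant"), 5)

  # generated SEs match the standardized-trait law within 2%
  maf <- pmin(gw1$bmi$eaf, 1 - gw1$bmi$eaf)
  z <- gw1$bmi$beta / gw1$bmi$se
  se_law <- 1 / sqrt(2 * maf * (1 - maf) * (gw1$bmi$n + z^2))
  expect_true(all(abs(gw1$bmi$se / se_law - 1) < 0.02))

  # null world: no genome-wide hits
  cfg0 <- small_config(seed = 3, effect_size_bmi = 0, effect_size_t2d = 0)
  p0 <- simulate_reference_panel(cfg0)
  gw0 <- simulate_gwas_pair(cfg0, p0)
  expect_equal(sum(gw0$bmi$p < 5e-8 & gw0$t2d$p < 5e-8), 0)
})

test_that("generated summary statistics round-trip through the io layer", {
  cfg <- small_config(seed = 5)
  panel <- simulate_reference_panel(cfg)
  gw <- simulate_gwas_pair(cfg, panel)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(gw$bmi, f)
  back <- read_sumstats(f)
  expect_equal(attr(back, "n_dropped"), 0)
  for (col in names(gw$bmi)) expect_equal(back[[col]], gw$bmi[[col]], info = col)
})

test_that("trait panel nulls pool to near-zero heterogeneity when tau = 0", {
  cfg <- small_config(seed = 9,
                      trait_panel = tibble::tibble(
                        trait_id = "flat", binary = FALSE,
                        mu_c = 0.02, mu_d = 0.02, tau = 0, n = 1e6))
  panel <- simulate_reference_panel(cfg)
  gw <- simulate_gwas_pair(cfg, panel)
  prof <- truth_profile_snps(panel, gw$truth)
  tp <- simulate_trait_panel(cfg, prof)
  scan <- harvest(prof, tp$tables)
  pm <- pm_meta(scan$beta_std, scan$se_std)
  # identical true effects at huge n: tau2 estimate collapses
  expect_lt(pm$tau2, 1e-6)
  expect_false(tp$truth$separating[1])
})

test_that("two-visit rule: single-visit individuals are controls, exclusions respected", {
  events <- tibble::tibble(
    individual_id = c("a", "a", "b", "c", "c"),
    phecode = "250.2",
    date = as.Date(c("2020-01-01", "2020-02-01",  # a: two days -> case
                     "2020-01-01",                # b: one day  -> control
                     "2020-03-01", "2020-03-01")) # c: same day twice -> control
  )
  st <- phecode_case_status(c("a", "b", "c", "d"), events)
  s <- setNames(st$status, st$individual_id)
  expect_equal(unname(s[c("a", "b", "c", "d")]),
               c("case", "control", "control", "control"))
  # without the rule, one code is enough
  st1 <- phecode_case_status(c("a", "b", "c", "d"), events, two_visit = FALSE)
  expect_equal(st1$status[st1$individual_id == "b"], "case")
  # exclusion removes controls but never cases
  ex <- tibble::tibble(phecode = "250.2", individual_id = c("a", "d"))
  st2 <- phecode_case_status(c("a", "b", "c", "d"), events, exclusions = ex)
  expect_equal(st2$status[st2$individual_id == "d"], "excluded")
  expect_equal(st2$status[st2$individual_id == "a"], "case")
})

test_that("eqtl scenarios plant the advertised structure", {
  cfg <- truth_config(seed = 31)
  eq <- simulate_eqtl_scenario("pleiotropy", cfg)
  expect_equal(dim(eq$ld), c(31, 31))
  lead <- top_cis_eqtl(eq$eqtl, "G1", bmi_ss = eq$bmi)
  expect_false(is.null(lead))
  # under pleiotropy the lead is (near) the planted causal SNP
  expect_lt(abs(match(lead$snp_id, eq$eqtl$snp_id) -
                  match(eq$truth$causal_expr, eq$eqtl$snp_id)), 3)
  # null scenario: expression signal only
  eq0 <- simulate_eqtl_scenario("null", cfg)
  expect_gt(min(eq0$eqtl$p), 0)
  expect_gt(min(eq0$bmi$p), 5e-8)
  # determinism given the same seed
  eqa <- simulate_eqtl_scenario("linkage", cfg, seed = 77)
  eqb <- simulate_eqtl_scenario("linkage", cfg, seed = 77)
  expect_identical(eqa, eqb)
})

test_that("expression atlas plants a dominant tissue with a promoter mark", {
  cfg <- truth_config(seed = 12)
  atlas <- simulate_expression_atlas(cfg)
  g <- atlas$truth$gene[1]
  tt <- atlas$truth$true_tissue[1]
  spec <- specificity(atlas$tpm, g)
  expect_equal(names(which.max(spec)), tt)
  expect_equal(sum(spec), 1)
  lead <- paste0("rs_lead_", 1)
  ev <- epi_evidence(lead, NULL, atlas$annotation, atlas$cellline_map)
  expect_equal(unname(ev[tt]), "promoter")
})
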