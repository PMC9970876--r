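# End-to-end orchestration over a synthetic world, with a run manifest.

#' Run the full discordance-decomposition pipeline on a synthetic world
#'
#' Simulates a reference panel and paired GWAS, selects and labels
#' instruments, simulates and harvests a secondary-trait panel, runs the
#' two-stage profile comparison, simulates a cohort and runs the
#' genetic-risk-score batteries, screens a cis-eQTL scenario with
#' SMR/HEIDI, and scores tissues of action. All tabular outputs are
#' written as TSV under `out_dir` together with a JSON manifest carrying
#' the configuration snapshot, seeds and per-file content digests.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [truth_config()].
#' @param out_dir Output directory (created if needed).
#' @param boruta_iters Shadow iterations for stage two (default 100).
#' @return The manifest (invisibly also written as `manifest.json`): a
#'   list with `config`, `outputs` (named file digests), and headline
#'   `summary` numbers.
#' @export
run_pipeline <- function(cfg, out_dir, boruta_iters = 100) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_reference_panel(cfg)
  gw <- simulate_gwas_pair(cfg, panel)
  profiles <- select_instruments(gw$bmi, gw$t2d, panel)

  tp <- simulate_trait_panel(cfg, profiles, panel)
  scan <- harvest(profiles, tp$tables, panel = panel)
  cmp <- compare_profiles(scan)

  zmat <- scan_z_matrix(scan)
  sel <- intersect(cmp$selected_traits, colnames(zmat))
  boruta <- NULL
  if (length(sel) >= 1 && length(unique(attr(zmat, "labels"))) == 2) {
    boruta <- boruta_select(zmat[, sel, drop = FALSE], attr(zmat, "labels"),
                            n_iter = boruta_iters,
                            seed = stage_seed(cfg$seed, "boruta"))
  }
  trees <- list()
  for (lab in c("concordant", "discordant")) {
    rows <- attr(zmat, "labels") == lab
    if (sum(rows) >= 2) {
      trees[[lab]] <- single_linkage_outliers(zmat[rows, , drop = FALSE])
    }
  }

  cohort <- simulate_cohort(cfg, panel, profiles)
  grs_c <- compute_grs(cohort, profiles$snp_id[profiles$label == "concordant"])
  grs_d <- compute_grs(cohort, profiles$snp_id[profiles$label == "discordant"])
  status <- phecode_case_status(rownames(cohort$genotypes),
                                cohort$phecode_events,
                                cohort$phecode_exclusions)
  phe_c <- phewas(grs_c, status, cohort$covariates)
  phe_d <- phewas(grs_d, status, cohort$covariates)
  lab_c <- labwas(grs_c, cohort$labs, cohort$covariates)
  lab_d <- labwas(grs_d, cohort$labs, cohort$covariates)
  cox_c <- cox_mortality(grs_c, cohort$survival, cohort$covariates)

  eq <- simulate_eqtl_scenario("pleiotropy", cfg)
  screen <- discordant_gene_screen(
    tibble::tibble(gene = "G1", tissue = "adipose", tss = eq$eqtl$tss[1]),
    eq$eqtl, eq$bmi, eq$t2d, eq$ld
  )

  atlas <- simulate_expression_atlas(cfg)
  toa <- tissue_of_action(
    specificity(atlas$tpm, atlas$truth$gene[1]),
    epi_evidence(paste0("rs_lead_1"), NULL, atlas$annotation,
                 atlas$cellline_map)
  )

  outputs <- list(
    profiles = profiles,
    truth = gw$truth,
    scan = scan,
    pooled_effects = cmp$pooled,
    delta_results = cmp$delta,
    phewas_concordant = phe_c,
    phewas_discordant = phe_d,
    labwas_concordant = lab_c,
    labwas_discordant = lab_d,
    smr_results = screen$results,
    tissue_scores = toa
  )
  if (!is.null(boruta)) outputs$boruta_decisions <- boruta
  digests <- character()
  for (nm in names(outputs)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(outputs[[nm]], f, progress = FALSE)
    digests[[paste0(nm, ".tsv")]] <- unname(tools::md5sum(f))
  }
  manifest <- list(
    config = cfg[setdiff(names(cfg), c("trait_panel", "phecode_panel",
                                       "lab_panel"))],
    seed = cfg$seed,
    outputs = as.list(digests),
    summary = list(
      n_instruments = nrow(profiles),
      n_concordant = sum(profiles$label == "concordant"),
      n_discordant = sum(profiles$label == "discordant"),
      selected_traits = cmp$selected_traits,
      cox_hr_concordant = cox_c$hr,
      discordant_genes = screen$discordant_genes,
      top_tissue = toa$tissue[1]
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
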