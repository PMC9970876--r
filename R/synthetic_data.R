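# Synthetic-world generators. Every input the pipeline consumes can be
# simulated with recorded ground truth, so each downstream stage is
# testable without external cohort or consortium data.

#' Ground-truth configuration for a synthetic world
#'
#' Bundles every parameter of the generators, with defaults emulating the
#' study conditions of the discordance analysis: 48 concordant and 19
#' discordant causal loci planted among null loci, a BMI GWAS of 500,000
#' and a T2D GWAS with effective sample size 150,000, common causal
#' variants, block-structured LD, a secondary-trait panel in which some
#' traits separate the profiles, and an individual-level cohort with
#' phecode, laboratory and survival outcomes.
#'
#' @param seed Global seed; per-stage seeds are derived via [stage_seed()].
#' @param n_blocks Number of independent LD blocks.
#' @param snps_per_block SNPs per block.
#' @param within_block_ld Dosage correlation between adjacent SNPs in a
#'   block (correlation decays as `within_block_ld^distance`).
#' @param maf_range Range of per-block minor allele frequencies.
#' @param causal_maf_range MAF range for causal blocks (planted loci are
#'   common variants, as the genome-wide significant loci the method
#'   selects are in practice).
#' @param n_concordant,n_discordant Planted causal SNP counts.
#' @param effect_size_bmi Per-allele causal effect on BMI (s.d. units).
#' @param effect_size_t2d Per-allele causal effect on T2D (log-OR;
#'   positive for concordant, negative for discordant loci).
#' @param n_gwas_bmi,n_gwas_t2d GWAS (effective) sample sizes.
#' @param n_panel Reference-panel individuals.
#' @param prop_palindromic Fraction of null SNPs assigned A/T or C/G
#'   allele pairs; causal SNPs are always non-palindromic so ground truth
#'   survives the ambiguity filter.
#' @param trait_panel Tibble describing the secondary-trait panel:
#'   `trait_id`, `binary`, `mu_c`, `mu_d` (profile-mean per-allele
#'   effects), `tau` (between-SNP s.d.), `n`.
#' @param trait_missing_rate Fraction of (SNP, trait) records reported
#'   for an adjacent block-mate instead of the index SNP, to exercise
#'   proxy search.
#' @param cohort_n Individual-level cohort size.
#' @param cohort_bmi_beta Per-allele effect of each profile SNP on BMI in
#'   the cohort (s.d. units).
#' @param phecode_panel Tibble `phecode`, `base_rate`, `logor_c`,
#'   `logor_d` describing planted phecode effects per allele.
#' @param single_visit_rate Fraction of affected individuals recorded on
#'   a single visit day only (controls under the two-visit rule).
#' @param lab_panel Tibble `lab_id`, `beta_c`, `beta_d` of planted
#'   per-allele laboratory effects (s.d. units).
#' @param cohort_hr_c,cohort_hr_d Per-allele hazard ratios of the
#'   concordant/discordant scores on cardiovascular death.
#' @param eqtl Named list of cis-region parameters used by
#'   [simulate_eqtl_scenario()]: `m_snps`, `rho`, `maf`, `n_eqtl`,
#'   `beta_eqtl`, `b_smr_bmi`, `b_smr_t2d`, `linkage_gap`.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(seed = 1,
                         n_blocks = 90,
                         snps_per_block = 8,
                         within_block_ld = 0.8,
                         maf_range = c(0.01, 0.5),
                         causal_maf_range = c(0.2, 0.5),
                         n_concordant = 48,
                         n_discordant = 19,
                         effect_size_bmi = 0.02,
                         effect_size_t2d = 0.04,
                         n_gwas_bmi = 5e5,
                         n_gwas_t2d = 1.5e5,
                         n_panel = 2000,
                         prop_palindromic = 0.3,
                         trait_panel = default_trait_panel(),
                         trait_missing_rate = 0,
                         cohort_n = 6000,
                         cohort_bmi_beta = 0.05,
                         phecode_panel = default_phecode_panel(),
                         single_visit_rate = 0.1,
                         lab_panel = default_lab_panel(),
                         cohort_hr_c = 1.01,
                         cohort_hr_d = 0.995,
                         cohort_base_cv = 0.004,
                         cohort_base_other = 0.006,
                         eqtl = list()) {
  stopifnot(n_blocks >= n_concordant + n_discordant,
            within_block_ld >= 0, within_block_ld < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            n_concordant > 0, n_discordant > 0,
            all(trait_panel$tau >= 0))
  eqtl_default <- list(m_snps = 31, rho = 0.89, maf = 0.3, n_eqtl = 2500,
                       beta_eqtl = 0.35, b_smr_bmi = 0.06, b_smr_t2d = -0.1,
                       linkage_gap = 3)
  eqtl <- utils::modifyList(eqtl_default, eqtl)
  cfg <- list(seed = seed, n_blocks = n_blocks,
              snps_per_block = snps_per_block,
              within_block_ld = within_block_ld, maf_range = maf_range,
              causal_maf_range = causal_maf_range,
              n_concordant = n_concordant, n_discordant = n_discordant,
              effect_size_bmi = effect_size_bmi,
              effect_size_t2d = effect_size_t2d,
              n_gwas_bmi = n_gwas_bmi, n_gwas_t2d = n_gwas_t2d,
              n_panel = n_panel, prop_palindromic = prop_palindromic,
              trait_panel = trait_panel,
              trait_missing_rate = trait_missing_rate,
              cohort_n = cohort_n, cohort_bmi_beta = cohort_bmi_beta,
              phecode_panel = phecode_panel,
              single_visit_rate = single_visit_rate,
              lab_panel = lab_panel,
              cohort_hr_c = cohort_hr_c, cohort_hr_d = cohort_hr_d,
              cohort_base_cv = cohort_base_cv,
              cohort_base_other = cohort_base_other,
              eqtl = eqtl)
  structure(cfg, class = "truth_config")
}

#' Default secondary-trait panel
#'
#' Three traits whose per-SNP effects separate the profiles (opposite
#' profile means, as blood pressure and lipid fractions do in the real
#' phenome scan) plus seven non-separating traits.
#' @return A tibble usable as `trait_panel` in [truth_config()].
#' @export
default_trait_panel <- function() {
  tibble::tibble(
    trait_id = c(paste0("sep_trait_", 1:3), paste0("null_trait_", 1:7)),
    binary = FALSE,
    mu_c = c(rep(0.01, 3), rep(0, 7)),
    mu_d = c(rep(-0.01, 3), rep(0, 7)),
    tau = 0.003,
    n = 2e5
  )
}

#' Default phecode panel for the synthetic cohort
#' @return A tibble usable as `phecode_panel` in [truth_config()].
#' @export
default_phecode_panel <- function() {
  tibble::tibble(
    phecode = c("250.2", "401.1", "585.3", "278.1",
                paste0("null_", sprintf("%03d", 1:6))),
    base_rate = c(0.10, 0.25, 0.06, 0.15, rep(0.08, 6)),
    logor_c = c(0.03, 0.014, 0.02, 0.03, rep(0, 6)),
    logor_d = c(-0.05, -0.01, -0.02, 0.02, rep(0, 6))
  )
}

#' Default laboratory panel for the synthetic cohort
#' @return A tibble usable as `lab_panel` in [truth_config()].
#' @export
default_lab_panel <- function() {
  tibble::tibble(
    lab_id = c("hba1c", "hdl", "null_lab"),
    beta_c = c(0.05, -0.01, 0),
    beta_d = c(-0.06, 0.01, 0)
  )
}

# non-palindromic effect/other pairs
NONPAL_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                      c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate an LD-block-structured genotype reference panel
#'
#' Haplotypes are generated by a copy chain within each block: each
#' SNP's allele copies its left neighbour with probability
#' `within_block_ld` and is otherwise drawn fresh at the block MAF, so
#' dosage correlation decays as `within_block_ld^distance` within blocks
#' and is zero across blocks. All SNPs in a block share one MAF drawn
#' from `maf_range`; blocks earmarked to carry planted causal loci draw
#' from `causal_maf_range` and their centre SNP is non-palindromic.
#' Blocks are placed 2 Mb apart so the clumping window never spans
#' blocks.
#'
#' @param cfg A [truth_config()].
#' @return A [reference_panel()] whose `snps` table carries `block`,
#'   `maf` and a `causal_block` attribute consumed by
#'   [simulate_gwas_pair()].
#' @export
simulate_reference_panel <- function(cfg) {
  with_seed_(stage_seed(cfg$seed, "reference_panel"), {
    nb <- cfg$n_blocks
    m <- cfg$snps_per_block
    n <- cfg$n_panel
    n_causal <- cfg$n_concordant + cfg$n_discordant
    causal_blocks <- sort(sample.int(nb, n_causal))
    maf <- stats::runif(nb, cfg$maf_range[1], cfg$maf_range[2])
    maf[causal_blocks] <- stats::runif(n_causal, cfg$causal_maf_range[1],
                                       cfg$causal_maf_range[2])
    dosage <- matrix(0, n, nb * m)
    for (b in seq_len(nb)) {
      h <- matrix(0L, n, m)
      g <- matrix(0L, n, m)
      for (hap in 1:2) {
        hmat <- matrix(0L, n, m)
        hmat[, 1] <- stats::rbinom(n, 1L, maf[b])
        if (m > 1) for (j in 2:m) {
          copy <- stats::runif(n) < cfg$within_block_ld
          fresh <- stats::rbinom(n, 1L, maf[b])
          hmat[, j] <- ifelse(copy, hmat[, j - 1], fresh)
        }
        g <- g + hmat
      }
      dosage[, (b - 1) * m + seq_len(m)] <- g
    }
    total <- nb * m
    block <- rep(seq_len(nb), each = m)
    within <- rep(seq_len(m), nb)
    pos <- (block - 1L) * 2000000L + within * 10000L
    pal <- stats::runif(total) < cfg$prop_palindromic
    centre <- within == ceiling(m / 2)
    pal[block %in% causal_blocks & centre] <- FALSE
    pair_idx_np <- sample.int(nrow(NONPAL_PAIRS), total, replace = TRUE)
    pair_idx_p <- sample.int(nrow(PAL_PAIRS), total, replace = TRUE)
    alt <- ifelse(pal, PAL_PAIRS[pair_idx_p, 1], NONPAL_PAIRS[pair_idx_np, 1])
    ref <- ifelse(pal, PAL_PAIRS[pair_idx_p, 2], NONPAL_PAIRS[pair_idx_np, 2])
    snps <- tibble::tibble(
      snp_id = sprintf("rs%05d", seq_len(total)),
      chrom = "1", pos = as.integer(pos),
      ref = ref, alt = alt,
      block = block, maf = maf[block]
    )
    panel <- reference_panel(snps, dosage)
    attr(panel, "causal_blocks") <- causal_blocks
    panel
  })
}

# theoretical within-block dosage correlation matrix for the copy chain
block_corr <- function(m, ld) {
  outer(seq_len(m), seq_len(m), function(i, j) ld^abs(i - j))
}

# draw observed betas: marginal truth + within-block correlated noise
draw_block_betas <- function(beta_true, R, se) {
  marg <- as.vector(R %*% beta_true)
  L <- chol(R)
  noise <- as.vector(t(L) %*% stats::rnorm(length(beta_true))) * se
  marg + noise
}

#' Simulate a paired BMI/T2D GWAS with planted profile ground truth
#'
#' Causal SNPs sit at the centre of the blocks earmarked by
#' [simulate_reference_panel()]. All carry a positive per-allele BMI
#' effect; concordant SNPs carry a positive and discordant SNPs a
#' negative T2D log-OR of equal magnitude. Marginal effects at non-causal
#' SNPs follow the block LD; observed effects add within-block correlated
#' noise with standard error `1 / sqrt(2 * MAF * (1 - MAF) * n)` (the
#' usual standardized-trait approximation; for T2D `n` is an effective
#' sample size on the log-OR scale).
#'
#' @param cfg A [truth_config()].
#' @param panel Panel from [simulate_reference_panel()] under the same
#'   config.
#' @return A list with `bmi` and `t2d` summary-statistics tibbles (effects
#'   reported on the panel `alt` allele) and `truth`, a tibble of
#'   `snp_id`, `block`, `role` in `{concordant, discordant, null}`.
#' @export
simulate_gwas_pair <- function(cfg, panel) {
  with_seed_(stage_seed(cfg$seed, "gwas_pair"), {
    snps <- panel$snps
    m <- cfg$snps_per_block
    causal_blocks <- attr(panel, "causal_blocks")
    stopifnot(!is.null(causal_blocks))
    roles <- sample(c(rep("concordant", cfg$n_concordant),
                      rep("discordant", cfg$n_discordant)))
    centre <- ceiling(m / 2)
    causal_idx <- (causal_blocks - 1L) * m + centre
    role_by_block <- stats::setNames(roles, causal_blocks)

    # SEs from the panel's realized allele frequencies, so that the
    # published MAF column reproduces the SE law exactly
    eaf <- unname(colMeans(panel$dosage)) / 2
    eaf <- pmin(pmax(eaf, 1e-4), 1 - 1e-4)
    maf <- pmin(eaf, 1 - eaf)
    se_bmi <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_gwas_bmi)
    se_t2d <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_gwas_t2d)

    beta_bmi_true <- numeric(nrow(snps))
    beta_t2d_true <- numeric(nrow(snps))
    beta_bmi_true[causal_idx] <- cfg$effect_size_bmi
    beta_t2d_true[causal_idx] <- ifelse(roles == "concordant",
                                        cfg$effect_size_t2d,
                                        -cfg$effect_size_t2d)

    R <- block_corr(m, cfg$within_block_ld)
    beta_bmi <- numeric(nrow(snps))
    beta_t2d <- numeric(nrow(snps))
    for (b in seq_len(cfg$n_blocks)) {
      ii <- (b - 1L) * m + seq_len(m)
      beta_bmi[ii] <- draw_block_betas(beta_bmi_true[ii], R, se_bmi[ii])
      beta_t2d[ii] <- draw_block_betas(beta_t2d_true[ii], R, se_t2d[ii])
    }
    mk <- function(beta, se, n, binary) {
      out <- tibble::tibble(
        snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
        ea = snps$alt, oa = snps$ref, eaf = eaf,
        beta = beta, se = se,
        p = 2 * stats::pnorm(-abs(beta / se)), n = n
      )
      if (binary) {
        out$n_cases <- n / 2
        out$n_controls <- n / 2
      }
      out
    }
    truth_role <- rep("null", nrow(snps))
    truth_role[causal_idx] <- roles
    list(
      bmi = mk(beta_bmi, se_bmi, cfg$n_gwas_bmi, FALSE),
      t2d = mk(beta_t2d, se_t2d, cfg$n_gwas_t2d, TRUE),
      truth = tibble::tibble(snp_id = snps$snp_id, block = snps$block,
                             role = truth_role)
    )
  })
}

#' Simulate a secondary-trait association panel
#'
#' For each trait in `cfg$trait_panel`, per-SNP true effects on the
#' BMI-increasing allele are drawn `N(mu_c, tau^2)` for concordant and
#' `N(mu_d, tau^2)` for discordant SNPs; non-separating traits use
#' `mu_c == mu_d`. Observed effects add independent noise at the standard
#' error implied by the trait sample size and SNP MAF. Each record is
#' emitted on a random allele orientation so downstream alignment is
#' exercised; with probability `cfg$trait_missing_rate` a record is
#' reported for an adjacent block-mate (a proxy) instead of the index
#' SNP.
#'
#' @param cfg A [truth_config()].
#' @param profile_snps Tibble with `snp_id`, `label`, `bmi_allele`,
#'   `other_allele`, `eaf` (e.g. output of [assign_profiles()] or built
#'   from the truth manifest), plus `chrom`/`pos`.
#' @param panel Optional panel, required when `trait_missing_rate > 0`.
#' @return A list: `tables`, a named list of per-trait
#'   summary-statistics tibbles; `truth`, a tibble of `trait_id`,
#'   `separating`, `mu_c`, `mu_d`.
#' @export
simulate_trait_panel <- function(cfg, profile_snps, panel = NULL) {
  with_seed_(stage_seed(cfg$seed, "trait_panel"), {
    tp <- cfg$trait_panel
    k <- nrow(profile_snps)
    maf <- maf_of(profile_snps$eaf)
    tables <- vector("list", nrow(tp))
    names(tables) <- tp$trait_id
    for (t in seq_len(nrow(tp))) {
      mu <- ifelse(profile_snps$label == "concordant", tp$mu_c[t], tp$mu_d[t])
      beta_true <- stats::rnorm(k, mu, tp$tau[t])
      se <- 1 / sqrt(2 * maf * (1 - maf) * tp$n[t])
      beta <- beta_true + stats::rnorm(k) * se

      snp_id <- profile_snps$snp_id
      chrom <- profile_snps$chrom
      pos <- profile_snps$pos
      ea <- profile_snps$bmi_allele
      oa <- profile_snps$other_allele
      eaf <- profile_snps$eaf

      if (cfg$trait_missing_rate > 0 && !is.null(panel)) {
        # report a block-mate instead of the index SNP for some records
        swap <- which(stats::runif(k) < cfg$trait_missing_rate)
        for (i in swap) {
          bi <- panel_index(panel, snp_id[i])
          blk <- panel$snps$block[bi]
          mates <- which(panel$snps$block == blk & seq_len(nrow(panel$snps)) != bi)
          if (!length(mates)) next
          mate <- sample(mates, 1)
          r <- stats::cor(panel$dosage[, bi], panel$dosage[, mate])
          snp_id[i] <- panel$snps$snp_id[mate]
          chrom[i] <- panel$snps$chrom[mate]
          pos[i] <- panel$snps$pos[mate]
          ea[i] <- panel$snps$alt[mate]
          oa[i] <- panel$snps$ref[mate]
          eaf[i] <- mean(panel$dosage[, mate]) / 2
          beta[i] <- sign(r) * beta[i] * abs(r)
        }
      }
      # random orientation: half the records reported on the other allele
      flip <- stats::runif(k) < 0.5
      ea_out <- ifelse(flip, oa, ea)
      oa_out <- ifelse(flip, ea, oa)
      tables[[t]] <- tibble::tibble(
        snp_id = snp_id, chrom = chrom, pos = pos,
        ea = ea_out, oa = oa_out,
        eaf = ifelse(flip, 1 - eaf, eaf),
        beta = ifelse(flip, -beta, beta), se = se,
        p = 2 * stats::pnorm(-abs(beta / se)), n = tp$n[t]
      )
    }
    list(tables = tables,
         truth = tibble::tibble(trait_id = tp$trait_id,
                                separating = tp$mu_c != tp$mu_d,
                                mu_c = tp$mu_c, mu_d = tp$mu_d))
  })
}

#' Simulate an individual-level cohort with genotypes, phenotypes,
#' phecode events, laboratory values and censored survival
#'
#' Genotypes at profile SNPs are drawn as independent binomial dosages at
#' the SNP MAF (profile SNPs live in distinct LD blocks). BMI is a linear
#' genetic score plus noise; phecode liabilities are logistic in the
#' centred concordant/discordant scores with planted per-allele log-ORs;
#' laboratory values are linear with repeated measurements;
#' cardiovascular death times are exponential with log-hazard linear in
#' the centred scores, with an independent other-cause death process and
#' uniform administrative censoring. Covariates (age, sex, ten genetic PC
#' surrogates) are independent of genotype. Affected individuals are
#' recorded on two or three distinct visit days except a
#' `single_visit_rate` fraction with one day only, which the two-visit
#' rule downgrades to controls.
#'
#' @param cfg A [truth_config()].
#' @param panel A [reference_panel()] (supplies MAFs for the profile
#'   SNPs when present; otherwise `profile_snps$eaf` is used).
#' @param profile_snps Tibble with `snp_id`, `label` and `eaf`.
#' @return A list of class `cohort_data` with elements `genotypes`
#'   (matrix), `score_c`, `score_d`, `covariates`, `phenotypes` (BMI,
#'   obesity flag, T1D flag), `phecode_events` (long table of individual,
#'   phecode, date), `phecode_exclusions`, `labs` (long table), and
#'   `survival` (time, event, cause), plus `truth` with the planted
#'   parameters.
#' @export
simulate_cohort <- function(cfg, panel, profile_snps) {
  with_seed_(stage_seed(cfg$seed, "cohort"), {
    n <- cfg$cohort_n
    k <- nrow(profile_snps)
    maf <- maf_of(profile_snps$eaf)
    G <- sapply(maf, function(p) stats::rbinom(n, 2L, p))
    colnames(G) <- profile_snps$snp_id
    id <- sprintf("ind%05d", seq_len(n))
    rownames(G) <- id
    conc <- profile_snps$label == "concordant"
    score_c <- rowSums(G[, conc, drop = FALSE])
    score_d <- rowSums(G[, !conc, drop = FALSE])
    sc <- score_c - mean(score_c)
    sd_ <- score_d - mean(score_d)

    covariates <- tibble::tibble(
      individual_id = id,
      age = stats::runif(n, 40, 70),
      sex = stats::rbinom(n, 1L, 0.5)
    )
    for (j in 1:10) covariates[[paste0("pc", j)]] <- stats::rnorm(n)

    bmi <- cfg$cohort_bmi_beta * (sc + sd_) + stats::rnorm(n)
    t1d <- stats::runif(n) < 0.01
    phenotypes <- tibble::tibble(
      individual_id = id, bmi = bmi,
      obesity = bmi >= stats::quantile(bmi, 0.75, type = 7),
      t1d = t1d
    )

    pp <- cfg$phecode_panel
    events <- list()
    for (t in seq_len(nrow(pp))) {
      eta <- stats::qlogis(pp$base_rate[t]) + pp$logor_c[t] * sc +
        pp$logor_d[t] * sd_
      affected <- stats::runif(n) < stats::plogis(eta)
      aff_id <- id[affected]
      if (!length(aff_id)) next
      n_days <- ifelse(stats::runif(length(aff_id)) < cfg$single_visit_rate,
                       1L, sample(2:3, length(aff_id), replace = TRUE))
      events[[t]] <- tibble::tibble(
        individual_id = rep(aff_id, n_days),
        phecode = pp$phecode[t],
        date = as.Date("2015-01-01") +
          unlist(lapply(n_days, function(d) sample.int(3000, d)))
      )
    }
    phecode_events <- dplyr::bind_rows(events)
    phecode_exclusions <- tibble::tibble(
      phecode = "250.2", individual_id = id[t1d]
    )

    lp <- cfg$lab_panel
    labs <- list()
    for (t in seq_len(nrow(lp))) {
      mu <- lp$beta_c[t] * sc + lp$beta_d[t] * sd_ + stats::rnorm(n, 0, 0.6)
      reps <- sample(1:3, n, replace = TRUE)
      labs[[t]] <- tibble::tibble(
        individual_id = rep(id, reps), lab_id = lp$lab_id[t],
        value = rep(mu, reps) + stats::rnorm(sum(reps), 0, 0.3)
      )
    }
    labs <- dplyr::bind_rows(labs)

    haz_cv <- cfg$cohort_base_cv * exp(log(cfg$cohort_hr_c) * sc +
                                         log(cfg$cohort_hr_d) * sd_)
    t_cv <- stats::rexp(n, haz_cv)
    t_other <- stats::rexp(n, cfg$cohort_base_other)
    censor <- stats::runif(n, 8, 14)
    time <- pmin(t_cv, t_other, censor)
    dead <- time < censor
    cause <- ifelse(!dead, NA_character_,
                    ifelse(t_cv <= t_other, "I21", "C50"))
    surv <- tibble::tibble(individual_id = id, time = time,
                           event = dead, cause = cause)

    structure(list(genotypes = G, score_c = score_c, score_d = score_d,
                   covariates = covariates, phenotypes = phenotypes,
                   phecode_events = phecode_events,
                   phecode_exclusions = phecode_exclusions,
                   labs = labs, survival = surv,
                   truth = list(phecode_panel = pp, lab_panel = lp,
                                hr_c = cfg$cohort_hr_c,
                                hr_d = cfg$cohort_hr_d,
                                bmi_beta = cfg$cohort_bmi_beta)),
              class = "cohort_data")
  })
}

#' Simulate a cis-eQTL region under a pleiotropy, linkage or null scenario
#'
#' A region of `m_snps` SNPs with AR(1) LD (`rho^distance`) and common
#' MAF. Under `pleiotropy` a single centre SNP drives expression and both
#' traits through expression, so Wald ratios are constant across the
#' region; under `linkage` a second SNP `linkage_gap` positions away
#' (r^2 about 0.5 at the default `rho`) drives the traits directly, so
#' ratios are heterogeneous; under `null` only expression carries signal.
#' Observed z-scores are drawn from the exact multivariate normal
#' sampling distribution given the LD matrix.
#'
#' @param kind One of `"pleiotropy"`, `"linkage"`, `"null"`.
#' @param cfg A [truth_config()]; region parameters come from `cfg$eqtl`.
#' @param seed Optional override of the stage seed (used when many
#'   replicate regions are needed).
#' @return A list: `eqtl`, `bmi`, `t2d` summary-statistics tibbles (the
#'   eQTL table carries `gene`, `tissue`, `tss` columns), `ld` (signed
#'   correlation matrix with SNP dimnames), and `truth`.
#' @export
simulate_eqtl_scenario <- function(kind = c("pleiotropy", "linkage", "null"),
                                   cfg, seed = NULL) {
  kind <- match.arg(kind)
  seed <- seed %||% stage_seed(cfg$seed, paste0("eqtl_", kind))
  with_seed_(seed, {
    e <- cfg$eqtl
    m <- e$m_snps
    R <- block_corr(m, e$rho)
    L <- chol(R)
    maf <- rep(e$maf, m)
    c1 <- ceiling(m / 2)
    c2 <- min(m, c1 + e$linkage_gap)

    z_eqtl_true <- numeric(m)
    z_bmi_true <- numeric(m)
    z_t2d_true <- numeric(m)
    z_eqtl_true[c1] <- e$beta_eqtl * sqrt(e$n_eqtl)
    if (kind == "pleiotropy") {
      z_bmi_true[c1] <- e$b_smr_bmi * e$beta_eqtl * sqrt(cfg$n_gwas_bmi)
      z_t2d_true[c1] <- e$b_smr_t2d * e$beta_eqtl * sqrt(cfg$n_gwas_t2d)
    } else if (kind == "linkage") {
      z_bmi_true[c2] <- 0.02 * sqrt(cfg$n_gwas_bmi)
      z_t2d_true[c2] <- -0.035 * sqrt(cfg$n_gwas_t2d)
    }
    draw_z <- function(z_true) {
      as.vector(R %*% z_true) + as.vector(t(L) %*% stats::rnorm(m))
    }
    pos <- 1000000L + seq_len(m) * 5000L
    ids <- sprintf("rs_cis_%03d", seq_len(m))
    pair <- NONPAL_PAIRS[sample.int(nrow(NONPAL_PAIRS), m, replace = TRUE), ,
                         drop = FALSE]
    mk <- function(z_true, n) {
      z <- draw_z(z_true)
      se <- 1 / sqrt(2 * maf * (1 - maf) * n)
      tibble::tibble(snp_id = ids, chrom = "2", pos = pos,
                     ea = pair[, 1], oa = pair[, 2], eaf = maf,
                     beta = z * se, se = se,
                     p = 2 * stats::pnorm(-abs(z)), n = n)
    }
    eqtl <- mk(z_eqtl_true, e$n_eqtl)
    eqtl$gene <- "G1"
    eqtl$tissue <- "adipose"
    eqtl$tss <- pos[c1]
    dimnames(R) <- list(ids, ids)
    list(eqtl = eqtl, bmi = mk(z_bmi_true, cfg$n_gwas_bmi),
         t2d = mk(z_t2d_true, cfg$n_gwas_t2d), ld = R,
         truth = list(kind = kind, causal_expr = ids[c1],
                      causal_trait = ids[if (kind == "linkage") c2 else c1],
                      b_smr_bmi = if (kind == "pleiotropy") e$b_smr_bmi else NA,
                      b_smr_t2d = if (kind == "pleiotropy") e$b_smr_t2d else NA))
  })
}

#' Profile-SNP table from the truth manifest
#'
#' Builds the table [assign_profiles()] would ideally produce, using the
#' planted roles instead of estimated labels (the generator plants
#' positive BMI effects on the panel's counted `alt` allele, so that
#' allele is the BMI-increasing one). Useful for testing downstream
#' stages in isolation from selection noise.
#'
#' @param panel A [reference_panel()] from [simulate_reference_panel()].
#' @param truth Truth tibble from [simulate_gwas_pair()].
#' @return A tibble with the [assign_profiles()] columns (effect sizes
#'   set to the planted values are not included; only identity, alleles,
#'   frequency and label).
#' @export
truth_profile_snps <- function(panel, truth) {
  causal <- truth[truth$role != "null", , drop = FALSE]
  idx <- match(causal$snp_id, panel$snps$snp_id)
  eaf <- unname(colMeans(panel$dosage[, idx, drop = FALSE])) / 2
  tibble::tibble(
    snp_id = causal$snp_id,
    chrom = panel$snps$chrom[idx],
    pos = panel$snps$pos[idx],
    bmi_allele = panel$snps$alt[idx],
    other_allele = panel$snps$ref[idx],
    eaf = pmin(pmax(eaf, 1e-4), 1 - 1e-4),
    label = causal$role
  )
}

#' Simulate a tissue expression atlas with epigenetic marks
#'
#' Each planted gene has one designated true tissue with strongly
#' elevated median expression and a promoter mark at its lead instrument
#' in a cell line mapped to that tissue; other tissues get background
#' expression and scattered enhancer marks in other cell lines.
#'
#' @param cfg A [truth_config()].
#' @param genes Tibble with `gene` and `lead_snp`; defaults to five
#'   planted genes.
#' @param n_tissues Number of tissues in the atlas.
#' @return A list: `tpm` (long tibble tissue, gene, median_tpm),
#'   `annotation` (snp_id, cell_line, mark), `cellline_map`
#'   (cell_line, tissue), `truth` (gene, true_tissue).
#' @export
simulate_expression_atlas <- function(cfg, genes = NULL, n_tissues = 20) {
  with_seed_(stage_seed(cfg$seed, "expression_atlas"), {
    if (is.null(genes)) {
      genes <- tibble::tibble(gene = paste0("GENE", 1:5),
                              lead_snp = paste0("rs_lead_", 1:5))
    }
    tissues <- paste0("tissue_", sprintf("%02d", seq_len(n_tissues)))
    true_tissue <- sample(tissues, nrow(genes), replace = TRUE)
    tpm <- tidyr::expand_grid(tissue = tissues, gene = genes$gene)
    tpm$median_tpm <- stats::runif(nrow(tpm), 0.5, 4)
    for (i in seq_len(nrow(genes))) {
      hit <- tpm$gene == genes$gene[i] & tpm$tissue == true_tissue[i]
      tpm$median_tpm[hit] <- stats::runif(1, 30, 50)
    }
    cellline_map <- tibble::tibble(
      cell_line = paste0("cell_", sprintf("%02d", seq_len(n_tissues))),
      tissue = tissues
    )
    ann <- tibble::tibble(
      snp_id = genes$lead_snp,
      cell_line = cellline_map$cell_line[match(true_tissue,
                                               cellline_map$tissue)],
      mark = "promoter"
    )
    # scattered background enhancer marks in random other cell lines
    noise <- tibble::tibble(
      snp_id = sample(genes$lead_snp, 5, replace = TRUE),
      cell_line = sample(cellline_map$cell_line, 5, replace = TRUE),
      mark = "enhancer"
    )
    list(tpm = tpm, annotation = dplyr::bind_rows(ann, noise),
         cellline_map = cellline_map,
         truth = tibble::tibble(gene = genes$gene, true_tissue = true_tissue))
  })
}
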