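# Unweighted profile genetic risk scores on individual-level data, and
# the association batteries: phecode logistic PheWAS, laboratory linear
# models, Cox cardiovascular mortality and extreme-decile subgroup tests.

#' Unweighted genetic risk score
#'
#' Exact sum of allele dosages over a SNP set, no weights. Missing
#' dosages are mean-imputed per SNP with a logged count.
#'
#' @param genotypes Matrix, individuals x SNPs (dosages in \[0, 2\]),
#'   or a `cohort_data` object.
#' @param snp_set Character vector of SNP ids (columns).
#' @return Named numeric vector of scores.
#' @export
compute_grs <- function(genotypes, snp_set) {
  if (inherits(genotypes, "cohort_data")) genotypes <- genotypes$genotypes
  if (!length(snp_set)) stop("empty SNP set")
  missing <- setdiff(snp_set, colnames(genotypes))
  if (length(missing)) stop("SNPs absent from genotypes: ",
                            paste(missing, collapse = ", "))
  G <- genotypes[, snp_set, drop = FALSE]
  n_na <- sum(is.na(G))
  if (n_na > 0) {
    log_count("missing dosages mean-imputed", n_na)
    for (j in seq_len(ncol(G))) {
      na <- is.na(G[, j])
      if (any(na)) G[na, j] <- mean(G[, j], na.rm = TRUE)
    }
  }
  rowSums(G)
}

#' Derive phecode case/control/excluded status from an event table
#'
#' A case requires at least two codes on different visit days when the
#' two-visit rule is enabled (one code otherwise). Individuals listed in
#' the exclusion table for a phecode are neither cases nor controls.
#'
#' @param individual_ids All cohort individuals.
#' @param events Long tibble `individual_id`, `phecode`, `date`.
#' @param exclusions Optional tibble `phecode`, `individual_id`.
#' @param two_visit Require two distinct visit days (default TRUE).
#' @return A tibble `individual_id` x `phecode` long: `status` in
#'   `{case, control, excluded}`.
#' @export
phecode_case_status <- function(individual_ids, events, exclusions = NULL,
                                two_visit = TRUE) {
  phecodes <- unique(events$phecode)
  days <- dplyr::summarise(
    dplyr::group_by(events, .data$individual_id, .data$phecode),
    n_days = dplyr::n_distinct(.data$date), .groups = "drop"
  )
  need <- if (two_visit) 2L else 1L
  out <- tidyr::expand_grid(individual_id = individual_ids,
                            phecode = phecodes)
  out <- dplyr::left_join(out, days, by = c("individual_id", "phecode"))
  out$status <- ifelse(!is.na(out$n_days) & out$n_days >= need,
                       "case", "control")
  if (!is.null(exclusions) && nrow(exclusions)) {
    key_ex <- paste(exclusions$individual_id, exclusions$phecode)
    excl <- paste(out$individual_id, out$phecode) %in% key_ex
    out$status[excl & out$status != "case"] <- "excluded"
  }
  out$n_days <- NULL
  out
}

fit_logistic <- function(y, grs, covariates) {
  dat <- data.frame(y = y, grs = grs, covariates)
  dat$individual_id <- NULL
  fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
  co <- summary(fit)$coefficients
  est <- co["grs", "Estimate"]
  se <- co["grs", "Std. Error"]
  flagged <- !fit$converged || abs(est) > 10 || se > 10
  list(beta = est, se = se, p = co["grs", "Pr(>|z|)"], flagged = flagged)
}

#' Phecode logistic PheWAS of a genetic risk score
#'
#' Per phecode: logistic regression of case status on the score plus
#' covariates, with excluded individuals removed. Phecodes with fewer
#' than `min_cases` cases are skipped. Degenerate fits (non-convergence
#' or runaway estimates, e.g. complete separation or a constant score)
#' are returned flagged.
#'
#' @param grs Named score vector (names = individual ids).
#' @param status Long status tibble from [phecode_case_status()].
#' @param covariates Tibble with `individual_id` plus covariate columns
#'   (age, sex, PCs ...).
#' @param min_cases Minimum case count (default 200).
#' @return A tibble: `outcome`, `beta` (log-OR per allele), `se`, `p`,
#'   `n`, `n_cases`, `flagged`.
#' @export
phewas <- function(grs, status, covariates, min_cases = 200) {
  rows <- list()
  for (ph in unique(status$phecode)) {
    sub <- status[status$phecode == ph & status$status != "excluded", ]
    ids <- sub$individual_id
    y <- as.integer(sub$status == "case")
    n_cases <- sum(y)
    if (n_cases < min_cases) next
    cv <- covariates[match(ids, covariates$individual_id), ]
    g <- grs[ids]
    if (stats::var(g) == 0) {
      rows[[ph]] <- tibble::tibble(outcome = ph, beta = NA_real_,
                                   se = NA_real_, p = NA_real_,
                                   n = length(y), n_cases = n_cases,
                                   flagged = TRUE)
      next
    }
    f <- fit_logistic(y, g, cv)
    rows[[ph]] <- tibble::tibble(outcome = ph, beta = f$beta, se = f$se,
                                 p = f$p, n = length(y), n_cases = n_cases,
                                 flagged = f$flagged)
  }
  dplyr::bind_rows(rows)
}

#' Rank-based inverse-normal transform
#' @param x Numeric vector.
#' @return Transformed vector with sample mean ~0 and variance ~1.
#' @export
inverse_normal <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Laboratory-value linear models against a genetic risk score
#'
#' The per-individual value is the median over all measurements; an
#' optional rank-based inverse-normal transform precedes the linear
#' model on score plus covariates.
#'
#' @param grs Named score vector.
#' @param labs Long tibble `individual_id`, `lab_id`, `value`.
#' @param covariates Covariate tibble with `individual_id`.
#' @param inverse_normalize Apply [inverse_normal()] (default TRUE).
#' @return A tibble: `outcome`, `beta` (per-allele, s.d. units when
#'   transformed), `se`, `p`, `n`.
#' @export
labwas <- function(grs, labs, covariates, inverse_normalize = TRUE) {
  med <- dplyr::summarise(dplyr::group_by(labs, .data$individual_id,
                                          .data$lab_id),
                          value = stats::median(.data$value),
                          .groups = "drop")
  rows <- list()
  for (lab in unique(med$lab_id)) {
    sub <- med[med$lab_id == lab, ]
    y <- sub$value
    if (inverse_normalize) y <- inverse_normal(y)
    cv <- covariates[match(sub$individual_id, covariates$individual_id), ]
    cv$individual_id <- NULL
    dat <- data.frame(y = y, grs = grs[sub$individual_id], cv)
    fit <- stats::lm(y ~ ., data = dat)
    co <- summary(fit)$coefficients
    rows[[lab]] <- tibble::tibble(outcome = lab, beta = co["grs", "Estimate"],
                                  se = co["grs", "Std. Error"],
                                  p = co["grs", "Pr(>|t|)"], n = nrow(dat))
  }
  dplyr::bind_rows(rows)
}

#' Cox regression of cause-specific mortality on a genetic risk score
#'
#' Right-censored proportional-hazards fit by partial likelihood. Events
#' are deaths whose primary cause is in `cause_codes`; deaths from other
#' causes are censored at the death time.
#'
#' @param grs Named score vector.
#' @param surv Tibble `individual_id`, `time`, `event` (logical death
#'   indicator), `cause`.
#' @param covariates Covariate tibble with `individual_id`.
#' @param cause_codes Character vector of qualifying cause codes.
#' @return A list: `log_hr` per allele, `se`, `p`, `hr`, `lo`, `hi`
#'   (95% CI), `n`, `n_events`.
#' @export
cox_mortality <- function(grs, surv, covariates, cause_codes = "I21") {
  ev <- surv$event & !is.na(surv$cause) & surv$cause %in% cause_codes
  if (!any(ev)) stop("no qualifying events")
  cv <- covariates[match(surv$individual_id, covariates$individual_id), ]
  cv$individual_id <- NULL
  dat <- data.frame(time = surv$time, ev = ev,
                    grs = grs[surv$individual_id], cv)
  fit <- survival::coxph(survival::Surv(time, ev) ~ ., data = dat)
  co <- summary(fit)$coefficients
  est <- co["grs", "coef"]
  se <- co["grs", "se(coef)"]
  list(log_hr = est, se = se, p = co["grs", "Pr(>|z|)"],
       hr = exp(est), lo = exp(est - 1.96 * se), hi = exp(est + 1.96 * se),
       n = nrow(dat), n_events = sum(ev))
}

#' Delta test between two per-allele association estimates
#'
#' Applies the same difference test used in the summary-level comparison
#' to a pair of individual-level estimates (log scale for OR/HR).
#'
#' @param est_c,est_d Lists or one-row tibbles with `beta` and `se`.
#' @return As [delta_test()].
#' @export
compare_estimates <- function(est_c, est_d) {
  delta_test(list(beta_hat = est_c$beta, se = est_c$se),
             list(beta_hat = est_d$beta, se = est_d$se))
}

#' Extreme-decile subgroup comparison within individuals with obesity
#'
#' Within the obesity subgroup, the extreme-concordant group is the top
#' decile of the concordant score and the extreme-discordant group the
#' top decile of the discordant score. The decile is an exact top-10%
#' membership: individuals are sorted by score with ties broken by their
#' stable input order, so discrete (allele-count) scores still yield
#' 10% groups. Each trait is compared between each extreme
#' group and all other individuals with obesity by the Kruskal-Wallis
#' test, optionally within sex strata. The union-membership fraction
#' (individuals in either extreme) is reported; for independent
#' continuous scores its expectation is `1 - 0.9^2 = 0.19`.
#'
#' @param score_c,score_d Named score vectors.
#' @param obesity_mask Logical vector (same order) flagging obesity.
#' @param traits Tibble `individual_id` plus one column per trait.
#' @param sex Optional vector for stratified analysis.
#' @return A list: `union_fraction`, `groups` (per-individual membership
#'   tibble), `tests` (tibble trait, group, stratum, p, n_extreme).
#' @export
extreme_decile_analysis <- function(score_c, score_d, obesity_mask, traits,
                                    sex = NULL) {
  ids <- names(score_c)
  ob <- which(obesity_mask)
  n_ob <- length(ob)
  n_top <- floor(n_ob / 10)
  top_decile <- function(s) {
    memb <- logical(n_ob)
    memb[order(-s)[seq_len(n_top)]] <- TRUE  # order() is stable on ties
    memb
  }
  in_c <- top_decile(score_c[ob])
  in_d <- top_decile(score_d[ob])
  union_fraction <- mean(in_c | in_d)
  groups <- tibble::tibble(individual_id = ids[ob],
                           extreme_c = in_c, extreme_d = in_d)
  trait_cols <- setdiff(names(traits), "individual_id")
  tmat <- traits[match(ids[ob], traits$individual_id), , drop = FALSE]
  strata <- if (is.null(sex)) list(all = rep(TRUE, length(ob)))
            else {
              sx <- sex[ob]
              out <- lapply(unique(sx), function(s) sx == s)
              names(out) <- paste0("sex_", unique(sx))
              c(list(all = rep(TRUE, length(ob))), out)
            }
  rows <- list()
  for (tc in trait_cols) {
    for (st in names(strata)) {
      sel <- strata[[st]]
      for (grp in c("extreme_c", "extreme_d")) {
        memb <- if (grp == "extreme_c") in_c else in_d
        x <- tmat[[tc]][sel]
        g <- memb[sel]
        if (length(unique(g)) < 2) next
        kw <- stats::kruskal.test(x, factor(g))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          trait = tc, group = grp, stratum = st,
          p = kw$p.value, n_extreme = sum(g)
        )
      }
    }
  }
  list(union_fraction = union_fraction, groups = groups,
       tests = dplyr::bind_rows(rows))
}
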