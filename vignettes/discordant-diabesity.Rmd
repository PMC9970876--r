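---
title: "Decomposing obesity genetics into diabetes-concordant and discordant profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing obesity genetics into diabetes-concordant and discordant profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabesity)
```

## The scientific problem

Obesity and type 2 diabetes (T2D) usually travel together, yet a
substantial minority of people with obesity stay metabolically healthy
while many normal-weight individuals develop T2D. One way to dissect
this "discordant diabesity" is genetic: take variants that raise body
mass index (BMI) and are also strongly associated with T2D, align every
variant to its BMI-increasing allele, and split them by the sign of the
T2D effect. Variants whose BMI-raising allele also raises T2D risk form
the **concordant** profile; variants whose BMI-raising allele *lowers*
T2D risk form the **discordant** profile. The two SNP sets can then be
compared across hundreds of traits, in individual-level cohorts, and at
the level of gene expression, to characterize the mechanisms that
uncouple adiposity from its diabetogenic consequences.

This package implements that comparison pipeline end to end:

1. **Instrument selection** (`cross_reference()`, `clump()`,
   `assign_profiles()`, `replicate_signs()`) — harmonize a BMI and a
   T2D GWAS, keep common (MAF > 1%) biallelic SNPs genome-wide
   significant (p < 5×10⁻⁸) in both, clump to near-independence
   (r² < 0.01 within 500 kb), align to the BMI-increasing allele and
   label by the T2D sign, then sign-check against a replication GWAS.
2. **Phenome scan** (`harvest()`, `standardize_effect()`,
   `qc_filter()`) — collect each instrument's effect on a panel of
   secondary traits, with LD-proxy fallback (r² ≥ 0.5 within 500 kb)
   and standardization of heterogeneous study effects.
3. **Profile comparison** (`pm_meta()`, `delta_test()`, `bh_fdr()`,
   `boruta_select()`, `single_linkage_outliers()`) — pool effects per
   profile, test the between-profile difference with FDR control, and
   confirm relevance with a shadow-feature random-forest stage.
4. **Individual-level risk scores** (`compute_grs()`, `phewas()`,
   `labwas()`, `cox_mortality()`, `extreme_decile_analysis()`).
5. **Expression screening** (`smr_test()`, `heidi_test()`,
   `discordant_gene_screen()`) and **tissue scoring**
   (`specificity()`, `epi_evidence()`, `tissue_of_action()`).
6. **Directional decomposition** (`select_trait_instruments()`,
   `split_by_sign()`, `summary_grs_effect()`, `cis_instrument()`) —
   instrumental estimates of how candidate mediators offset T2D risk.

`run_pipeline()` orchestrates all stages over a synthetic world and
writes TSV outputs plus a JSON manifest with content digests.

## Models and statistics

### Harmonization and alignment

Records from two studies are matched by SNP id and expressed per copy of
a shared effect allele; a record reported on the opposite allele has its
beta negated and its allele frequency complemented. Strand inference is
never attempted: allele sets that do not match are dropped, as are
potentially ambiguous palindromic SNPs (A/T, C/G) with MAF > 30%, where
MAF is taken from the first study and falls back to the second when
missing (missing in both drops the SNP — the standardization formulas
need a frequency). Indels are excluded at parse time by restricting
alleles to single bases.

### Effect standardization

Study effects arrive in heterogeneous units. We convert each to a
z-score, z = β/SE, and place it on a common per-s.d. scale through

$$\mathrm{SE}_{std} = \frac{1}{\sqrt{2\,\mathrm{MAF}\,(1-\mathrm{MAF})\,(n+z^2)}},
\qquad \beta_{std} = z \cdot \mathrm{SE}_{std}.$$

For a quantitative trait this approximates the per-allele effect in
phenotype-s.d. units, which the test suite verifies against direct
least squares on simulated individual-level data. Binary-trait z-scores
come from the log-OR and its SE and are standardized identically, with
no extra liability transformation. Studies with n ≤ 500, and binary
traits with fewer than 25 expected minor alleles in the smaller group
(2·MAF·n_smallest), are dropped before pooling.

### Paule–Mandel pooling and the profile difference test

Per trait and profile, standardized effects are pooled by a
random-effects meta-analysis whose between-SNP variance τ² solves the
generalized Q equation

$$\sum_i w_i(\tau^2)\,(\beta_i - \hat\beta(\tau^2))^2 = k - 1,
\qquad w_i = \frac{1}{\mathrm{SE}_i^2 + \tau^2},$$

the Paule–Mandel moment condition. Q is monotone decreasing in τ², so
the root is found by bisection to relative tolerance 1e-10; when
Q(0) ≤ k−1 the estimate is τ² = 0 and pooling reduces exactly to
fixed-effect inverse-variance weighting. The profiles are compared by

$$\delta = |\beta_C - \beta_D|, \qquad
\mathrm{SE}_\delta^2 = \mathrm{SE}_C^2 + \mathrm{SE}_D^2,$$

with a two-sided normal p-value, and two Benjamini–Hochberg families at
the 5% level — one over the per-profile p-values, one over the δ
p-values, optionally within phenotypic domains. A trait advances to
stage two when some pooled estimate *and* the difference are both
significant. Reported odds/hazard-ratio comparisons are performed on
the log scale, with SEs reconstructed from 95% CIs as width/(2·1.96).

### Shadow-feature relevance selection

Stage two asks which traits can actually discriminate concordant from
discordant SNPs. Each iteration appends column-permuted *shadow* copies
of every trait to the SNP × trait z-matrix, fits a random-forest
classifier of the labels, and counts a "hit" for every real trait whose
importance exceeds the maximum shadow importance; decisions come from
two-sided binomial tests of the hit counts against 0.5 with Holm
correction at α = 0.01. Two deliberate implementation choices:

* importance is the **Z-score of out-of-bag permutation importance**
  (`ranger`, scaled). Impurity importance lets a trait with a chance
  in-sample correlation with the labels beat the re-randomized shadows
  almost every iteration, producing false confirmations on pure noise;
* **two shadow copies per trait** (configurable). With p traits, the
  strongest spurious real-trait correlation is itself the maximum of p
  draws, so a single re-randomized shadow set of size p sits at the
  median of the same order-statistic distribution and is beaten half
  the time by chance. Doubling the shadow pool lifts the per-iteration
  reference above that order statistic; the sensitivity to genuinely
  separating traits (class means a few s.d. apart) is unaffected.

Missing z-matrix cells are imputed to 0 for the forest only; the
meta-analytic stage simply pools over the SNPs available.

### Within-profile outliers

Single-linkage clustering over the SNP rows of the z-matrix
(`stats::hclust`, Euclidean by default, correlation distance by option)
reports the full merge sequence; the SNP whose first merge happens at
the greatest height is the profile's most distal member — the candidate
outlier. Merge heights are checked against a brute-force O(n³)
agglomeration in the tests.

### Risk scores and cohort batteries

Individual scores are exact unweighted allele-count sums
$\mathrm{GRS}_{Pi} = \sum_{j \in P} G_{ij}$ over each profile's SNP set
(mean imputation for missing dosages, logged). Phecode case status
requires two codes on different visit days (configurable); excluded
individuals are removed per phecode. Associations are logistic (phecode,
≥ 200 cases required), linear on per-individual medians with optional
rank-based inverse-normal transform (labs), and Cox partial likelihood
for cause-specific cardiovascular mortality (deaths from other causes
censored at death), all adjusted for age, sex and ten genetic-PC
surrogates. The extreme-decile analysis takes, within the obesity
subgroup, the exact top 10% of each score — individuals sorted by score
with ties broken by stable input order, which keeps allele-count ties
from shrinking the groups — and compares traits between each extreme
group and all other individuals with obesity by Kruskal–Wallis tests,
optionally within sex strata. For independent continuous scores the
expected union membership is 1 − 0.9² = 0.19.

### SMR and HEIDI

For a gene, the lead cis-eQTL instrument is the strongest eQTL within
±500 kb of the transcription start site that is genome-wide significant
for both expression and BMI. (The cis window is a parameter; its
default is 500 kb.) The Wald ratio b = β_outcome/β_eQTL carries the
combined statistic

$$T_{SMR} = \frac{z_{out}^2\, z_{eQTL}^2}{z_{out}^2 + z_{eQTL}^2} \sim \chi^2_1 .$$

HEIDI distinguishes single-variant pleiotropy from linkage: secondary
SNPs with r² to the lead in [0.05, 0.9] and eQTL p < 1.57×10⁻³ (χ²₁ >
10; the cited method's convention, up to 20 SNPs, strongest first) give
differences dᵢ = bᵢ − b_lead whose delta-method covariance follows from
the LD correlations; the statistic Σ(dᵢ/sd(dᵢ))² is referred to its
eigenvalue-weighted χ² mixture. Small p_HEIDI indicates linkage; the
screen requires p_HEIDI > 0.01 for both outcomes, FDR-significant SMR
effects for both outcomes, and opposite signs on BMI and T2D to call a
gene discordant.

The mixture tail probability is computed by Imhof's numerical inversion
(adaptive quadrature of the oscillatory integrand on (0, ∞)); with two
or more eigenvalues the quadrature is accurate to ~1e-9, with a single
eigenvalue the slowly decaying tail limits it to ~1e-4, ample for a
0.01 decision threshold. If the quadrature fails or returns an
out-of-range value, a fixed-seed Monte-Carlo fallback with 10⁶ draws is
used.

### Tissue-of-action score

Per gene, tissue specificity is the fraction of summed median TPM
contributed by each tissue; epigenetic evidence is the strongest
promoter/enhancer mark overlapping the lead instrument or any proxy
with r² ≥ 0.8 in a cell line mapped to the tissue. The published
procedure sorts tissues by the two criteria without printing a formula,
so the combined score here is an explicit package construction —
specificity × weight with weights none = 1, enhancer = 2, promoter = 3,
both = 4 — config-exposed, and both raw criteria are always emitted
alongside it.

### Directional decomposition

For a candidate mediator, instruments are SNPs genome-wide significant
for both the mediator and BMI (the mediator threshold is a parameter;
genome-wide is the default), clumped, aligned to the BMI-increasing
allele, and split by the sign of the mediator effect. Each group's T2D
effect is the fixed-effect inverse-variance pool of the members'
per-allele log-ORs (a Paule–Mandel variant is available by flag); a
one-SNP group reduces to the Wald estimate, which also covers the
cis-instrument protein analyses. The union of the two groups pools to
the all-instrument estimate, an identity the tests assert.

## The synthetic world

All inputs can be generated with recorded ground truth by
`truth_config()` and the `simulate_*()` generators; every generator is
deterministic given (seed, config), with per-stage seeds derived by a
fixed hash of the stage name (`stage_seed()`).

**What it emulates.** LD blocks use a haplotype copy chain: within a
block each allele copies its left neighbour with probability equal to
the configured adjacent correlation (default 0.8), giving dosage
correlation decaying as ρ^distance and exact zero across blocks; block
MAFs are uniform on [0.01, 0.5]. The default world plants 48 concordant
and 19 discordant causal loci (the published profile sizes) among 90
blocks of 8 SNPs, with per-allele effects of 0.02 s.d. on BMI
(n = 500,000) and ±0.04 log-OR on T2D (effective n = 150,000) — the
magnitudes of real BMI/T2D loci at those consortium sample sizes, large
enough that a genome-wide dual-significance filter recovers the loci.
Causal loci are drawn common (MAF 0.2–0.5) and non-palindromic, since
genome-wide significant dual associations at biobank scale are
overwhelmingly common variants and the selection filters would
otherwise discard planted truth by construction; null SNPs include
palindromic allele pairs at a realistic rate (~30%). Observed marginal
effects are the LD-propagated causal effects plus within-block
correlated noise at the SE implied by MAF and sample size, so the
published SE column obeys the standardization law exactly. Secondary
traits draw per-SNP effects N(μ_C, τ²)/N(μ_D, τ²) per profile (default
separating traits ±0.01 with τ = 0.003 at n = 200,000; null traits
μ = 0); records are emitted in random allele orientation, and a
configurable fraction is reported at an LD neighbour to exercise proxy
search. The cohort generator produces binomial dosages at the profile
SNPs, BMI as a genetic score plus noise, logistic phecode events with
two-or-three visit days (10% single-visit, downgraded by the two-visit
rule), repeated-measure labs, and exponential cause-specific survival.
cis-eQTL regions are 31 SNPs with AR(1) LD (ρ = 0.89 so the
linkage-scenario causal pair sits near r² = 0.5), drawn from the exact
multivariate normal sampling distribution of marginal z-scores.

**What it does not emulate** — and hence what passing tests do not
show about real data: realistic human LD maps and allele-frequency
spectra, population stratification and relatedness, imputation
uncertainty, genuine phecode hierarchies, selection bias in cohort
ascertainment, or between-study heterogeneity beyond the planted τ².
Calibration statements (δ-test size, SMR null uniformity, HEIDI
operating characteristics) hold under the generator's assumptions.

## Numerical choices and degenerate inputs

* Windows are symmetric and inclusive (|Δpos| ≤ window), 1-based
  coordinates.
* Clumping ranks by the sum of −log₁₀ p across the two GWAS (min-p and
  single-study ranking available); ties break lexicographically by id,
  making selection fully deterministic.
* Proxy effects are re-signed by the sign of the proxy–index dosage
  correlation in the reference panel; proxy ties break by distance then
  id.
* β_T2D = 0 cannot be sign-labelled and is excluded; zero-variance
  dosages, empty instrument groups, single-class label vectors and
  zero-event survival tables raise immediate errors; complete
  separation in logistic fits is returned flagged rather than hidden.
* The Paule–Mandel bisection brackets [0, expanding upper] and stops at
  relative width 1e-10; the test suite checks agreement with a dense
  grid search to 1e-6 and with `metafor::rma(method = "PM")`.
* p-values from the weighted-χ² inversion are clipped to [1e-300, 1].

## Problem sizes used by the test and acceptance suites

The suites run on deliberately desk-scale worlds: full-size selection
worlds of 720 SNPs × 2,000 panel individuals (20 seeds), a 1,000-trait
null panel for δ calibration, 60-iteration shadow-feature runs at
67 SNPs × 30 traits (20 seeds each for noise and planted cases), 1,000
SMR null regions and 200 HEIDI regions per scenario, and 50 cohorts of
4,000 individuals for the risk-score coverage checks. These sizes give
Monte-Carlo error comfortably inside the asserted margins while keeping
the whole suite in minutes.

## Known limitations

* The tissue-of-action combination rule is a transparent stand-in for a
  procedure whose exact formula is not public; rankings should be read
  together with the raw specificity and evidence columns it emits.
* HEIDI here uses the single-layer delta-method covariance; multi-SNP
  SMR extensions and conditional analyses are out of scope.
* The phenome scan assumes a single ancestry; no trans-ancestry
  harmonization is attempted.
* T2D-family traits must be excluded from the scan by the caller's
  pattern list (`exclude_patterns`) to avoid circularity; the package
  ships the mechanism, not a trait ontology.
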