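# diabesity

Obesity and type 2 diabetes (T2D) usually co-occur, but not always:
some genetic variants raise body-mass index while *lowering* T2D risk.
`diabesity` decomposes BMI-raising genetic variation into a
diabetes-**concordant** and a diabetes-**discordant** profile from
paired GWAS summary statistics, and provides the full battery for
comparing the two profiles: a phenome-wide scan with random-effects
pooling and a profile-difference test, shadow-feature random-forest
relevance selection, individual-level genetic risk scores (phecode
PheWAS, laboratory models, Cox cardiovascular mortality, extreme-decile
subgroups), summary-based Mendelian randomization with the HEIDI
heterogeneity test for discordant gene screening, tissue-of-action
scoring, and directional instrument decomposition. A synthetic-data
generator with recorded ground truth makes every stage testable without
access to cohort or consortium data.

It is aimed at statistical geneticists and epidemiologists working with
GWAS summary statistics who want a reproducible, tested implementation
of the discordance-decomposition analysis.

## The core statistics

Instruments are SNPs genome-wide significant (p < 5×10⁻⁸) for both BMI
and T2D, common (MAF > 1%), non-ambiguous, and clumped to
near-independence (r² < 0.01 within 500 kb). After alignment to the
BMI-increasing allele each SNP is labelled by the sign of its T2D
log-OR. Per trait, each profile's standardized effects
(β_std = z·SE_std with SE_std = 1/√(2·MAF·(1−MAF)·(n+z²))) are pooled
by a Paule–Mandel random-effects meta-analysis, and the profiles are
compared with

    δ = |β_C − β_D|,   SE_δ² = SE_C² + SE_D²,

a two-sided z-test with Benjamini–Hochberg control at 5% FDR. Genetic
risk scores are unweighted allele-count sums per profile. The gene
screen uses the SMR Wald ratio T = z_out²·z_eQTL²/(z_out²+z_eQTL²) with
the HEIDI heterogeneity test (p_HEIDI > 0.01 required for pleiotropy)
and opposite BMI/T2D effect signs. See the methods vignette
(`vignettes/discordant-diabesity.Rmd`) for the complete model account.

## Worked example

```r
library(diabesity)

cfg      <- truth_config(seed = 42)           # synthetic study conditions
panel    <- simulate_reference_panel(cfg)     # LD-block genotypes
gw       <- simulate_gwas_pair(cfg, panel)    # paired BMI/T2D GWAS + truth
profiles <- select_instruments(gw$bmi, gw$t2d, panel)
table(profiles$label)
#> concordant discordant
#>         48         19

tp   <- simulate_trait_panel(cfg, profiles, panel)
scan <- harvest(profiles, tp$tables, panel = panel)
cmp  <- compare_profiles(scan)
dplyr::arrange(cmp$delta, p)[1:4, c("trait_id","delta","se_delta","p","q","selected")]
#>   trait_id       delta se_delta      p     q selected
#> 1 sep_trait_1  0.0212   0.00144 0      0     TRUE
#> 2 sep_trait_2  0.0174   0.00106 0      0     TRUE
#> 3 sep_trait_3  0.0204   0.00119 0      0     TRUE
#> 4 null_trait_2 0.00226  0.00126 0.0730 0.145 FALSE
```

The generator plants 48 concordant and 19 discordant causal loci; the
selection stage recovers exactly those counts, and the three traits
planted with opposite profile means (±0.01 s.d. per allele) are the
three selected by the two-stage comparison, with the seven null traits
left behind. The same difference test reproduces published worked
examples from reported estimates, e.g. for systolic blood pressure:

```r
delta_test_ci(0.002, -0.001, 0.004, -0.008, -0.012, -0.004)
#> δ = 0.010, z = 4.16, p = 3.25e-05
```

`run_pipeline(cfg, out_dir)` executes every stage — selection, scan,
comparison, risk-score batteries, SMR/HEIDI screen, tissue scoring —
and writes TSV outputs plus a JSON manifest with content digests;
reruns with the same config are digest-identical.

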