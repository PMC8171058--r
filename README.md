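# mrflow

Two-sample Mendelian randomization (MR) for scanning many brain-imaging
exposures against binary neuropsychiatric outcomes, using GWAS summary
statistics only.

Observational neuroimaging associations cannot separate cause from
consequence: a smaller tract volume in patients may drive disease or follow
from it. Two-sample MR uses genetic variants as instruments — SNPs strongly
associated with an imaging phenotype (the exposure) whose effects on a
disorder (the outcome) are read from an independent case-control GWAS. Under
the instrumental-variable assumptions, the ratio of outcome to exposure
effects estimates the causal effect of the imaging phenotype on disease
risk (log-odds per 1-SD of exposure).

`mrflow` covers the whole scan:

- **Ingestion & instruments** — delimited summary-statistic tables with a
  column map, odds ratios log-transformed on the way in; instrument
  selection at p < 5×10⁻⁸ with greedy LD clumping (r² ≥ 0.001 pruned);
  allele harmonization with strand-complement handling, palindromic SNPs
  kept under a forward-strand assumption.
- **Estimation** — `mr_fit()` returns a classed model object with
  `print`/`summary`/`coef`/`confint`/`plot`/`residuals`/`predict` methods.
  For k instruments, the per-SNP Wald ratio (k = 1, with the SMR test and
  HEIDI colocalization check), inverse-variance-weighted meta-analysis
  (k ≥ 2, multiplicative random effects), MR-Egger slope and intercept,
  weighted median and weighted mode (k ≥ 3, bootstrap standard errors):

  beta_IVW = Σ w_j (Γ̂_j/γ̂_j) / Σ w_j,  w_j = γ̂_j²/σ²_Yj

- **Sensitivity** — modified Cochran's Q and Rucker's Q, Egger-intercept
  pleiotropy test, MR-PRESSO global test with outlier detection and
  outlier-corrected re-estimation, leave-one-out, funnel tables, reverse MR
  as a directionality check.
- **Power** — per-instrument R² = β²/(β² + Nσ²) (the 2·EAF(1−EAF) factor
  cancels; both forms implemented), F = R²(N−2)/(1−R²), and binary-outcome
  study power at an assumed OR (default 1.3, α = 0.05).
- **Pooled inflation analysis** — per-pair p-values pooled per exposure
  class and disorder; genomic inflation factor λ by chi-square regression
  through the origin, KS uniformity test, within-pair permutation null,
  stratified reruns after removing heterogeneous pairs or outlier SNPs,
  Bonferroni significance tiers and a rank-rank overlap table.
- **Synthetic GWAS generator** — seeded, with known causal structure
  (instrument-count control, pleiotropy modes, outliers, block LD), so the
  whole pipeline is testable end to end without any download.

## Worked example

Simulate one exposure–disorder pair with a true protective effect
(β = −0.3 log-odds per SD, 8 expected instruments, outcome GWAS of 46,350
with 35% cases), then run the full per-pair analysis:

```r
library(mrflow)
sim <- simulate_pair(sim_config(n_snps = 200, n_exp = 17706, n_out = 46350,
                                causal_beta = -0.3, n_instruments = 8,
                                outcome_type = "binary", case_fraction = 0.35,
                                seed = 2026))
instruments <- select_instruments(sim$exposure)   # p < 5e-8, LD-clumped
pair <- harmonize_pair(sim$exposure, sim$outcome, instruments)
fit <- mr_fit(pair, seed = 1)
summary(fit)
```

```
Two-sample MR fit: exposure -> outcome (8 instrument SNPs)
          method     beta      se   ci_low  ci_high   pvalue n_snp
             ivw -0.31620 0.04414 -0.40270 -0.22970 7.89e-13     8
     egger_slope -0.41110 0.11720 -0.69790 -0.12430 1.27e-02     8
 egger_intercept  0.01571 0.01791 -0.02812  0.05954 4.14e-01     8
 weighted_median -0.36600 0.04976 -0.46350 -0.26840 1.93e-13     8
Cochran Q (modified) = 9.685 on 7 df, p = 0.207
Rucker Q' = 9.096 on 6 df, p = 0.168
Odds ratios per 1-SD exposure:
          method odds_ratio or_ci_low or_ci_high percent_change
             ivw       0.73      0.67       0.79          -27.1
     egger_slope       0.66      0.50       0.88          -33.7
 weighted_median       0.69      0.63       0.76          -30.6
```

The IVW estimate recovers the simulated effect (−0.32 vs the true −0.3;
OR 0.73 means each 1-SD increase in the exposure lowers disease odds by
27%), the Egger intercept shows no directional pleiotropy (p = 0.41), and
Cochran's Q shows no heterogeneity (p = 0.21). The sensitivity battery and
power columns follow the same pattern:

```r
mr_sensitivity(pair, n_sim = 2500, seed = 1)
#> Sensitivity report: exposure -> outcome (8 SNPs)
#>   Cochran Q = 9.685 (df 7, p = 0.207)
#>   Rucker Q' = 9.096 (p = 0.168)
#>   Egger intercept = 0.0157 (p = 0.414)
#>   MR-PRESSO global p = 0.225; 0 outlier(s)

mr_power(pair, n_exposure = 17706, n_outcome = 46350, case_fraction = 0.35,
         eaf = sim$exposure$records$eaf[match(pair$snps$snp_id,
                                              sim$exposure$records$snp_id)])
#> MR power report: R2_total = 0.07052, F_min = 47.6, power = 1.000 (OR = 1.30, alpha = 0.05)
```

A whole scan — every exposure × disorder pair, exclusions tracked, pooled
λ/KS per disorder, tiers, TSV outputs — is one call chain:

```r
coll  <- simulate_study_collection(110, 101, 12, fraction_causal = 0.05, seed = 1)
study <- run_study(coll, seed = 1)
write_study_tables(study, "study_out")
```

## Vignette

`vignettes/mr-brain-imaging.Rmd` documents the models and their assumptions,
every tunable parameter with its default and rationale, what the synthetic
generator does and does not emulate, and the package's numerical choices.
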