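---
title: "Two-sample MR for brain-imaging exposures: models, diagnostics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR for brain-imaging exposures: models, diagnostics, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
```

## The problem

Case-control neuroimaging studies reliably find brain differences in
psychiatric and neurodegenerative disorders, but cannot say whether a
structural difference causes the disorder or follows from it (medication,
metabolic change, neurotoxicity). Two-sample Mendelian randomization (MR)
addresses the direction-of-causality question with summary statistics alone:
genetic variants associated with an imaging phenotype (the exposure) are used
as instruments, their effects on a disorder (the outcome) are read from an
independent case-control GWAS, and under the instrumental-variable
assumptions the ratio of outcome to exposure effects estimates the causal
effect of the imaging phenotype on disease risk, on the log-odds scale per
1-SD of exposure.

`mrflow` implements the full scan that this design implies when there are
many exposures (e.g. 110 white-matter diffusion measures, five parameters
for each of 22 tracts, plus ~101 regional volumes) and a panel of binary
disorder outcomes: instrument selection, harmonization, estimation,
sensitivity analysis, power bookkeeping, and a pooled analysis that asks
whether the whole family of exposures shifts the p-value distribution away
from uniform.

## Models and estimators

For instrument $j$, let $\hat\gamma_j \pm \sigma_{Xj}$ be its exposure
association and $\hat\Gamma_j \pm \sigma_{Yj}$ its (allele-aligned) outcome
association. The per-SNP Wald ratio is
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard error
$\sigma_{Yj}/|\hat\gamma_j|$.

* **IVW** combines ratios with weights
  $w_j = \hat\gamma_j^2/\sigma_{Yj}^2$ — algebraically the zero-intercept
  weighted regression of $\hat\Gamma$ on $\hat\gamma$. The default standard
  error uses multiplicative random effects: it is inflated by
  $\sqrt{Q/(k-1)}$ when Cochran's $Q$ exceeds its degrees of freedom, and
  never deflated.
* **MR-Egger** frees the intercept after orienting every SNP to
  $\hat\gamma_j \ge 0$. The slope is robust to directional pleiotropy under
  the InSIDE assumption; the intercept is the pleiotropy test. Standard
  errors scale with the weighted residual standard deviation, exactly as
  `lm()` does, with a $t_{k-2}$ reference. We deliberately do not floor the
  residual scale at 1 here: with the floor the intercept test is
  conservative (empirical size ~0.02 at the nominal 0.05 with ten
  instruments), whereas the unfloored form is exactly calibrated under
  homogeneity. A `se_floor = TRUE` switch restores the floored behaviour for
  comparability with tools that use it.
* **Weighted median**: the ratio at which the normalized cumulative weight
  crosses one half (linear interpolation between order statistics);
  consistent while valid instruments hold a majority of the weight.
* **Weighted mode**: argmax of a normal-kernel density over the ratios with
  bandwidth `phi` times a modified Silverman rule (`phi = 1` by default);
  consistent when the largest group of agreeing instruments is valid. Named
  in the methods battery but excluded from the default report profile, since
  headline tables in this design report IVW/Egger/median.
* **Single-instrument pairs** fall back to the Wald ratio, confirmed by the
  **SMR** chi-square test
  $T = z_X^2 z_Y^2/(z_X^2+z_Y^2)$, with the **HEIDI** companion-SNP test to
  distinguish one shared causal variant from linkage of distinct variants.
  HEIDI here forms ratio deviations $d_i = \hat\beta_i - \hat\beta_{top}$
  over companions (exposure $p < 1.6\times10^{-3}$, $r^2$ to the top SNP in
  $[0.05, 0.9]$, at most 20) and refers the delta-method quadratic form to
  $\chi^2_m$; the original tool's saddlepoint refinement is not reproduced.

Median and mode standard errors come from a seeded parametric bootstrap
(redraw both effect vectors from their sampling normals, re-estimate,
take the SD; 1000 draws by default). This is the construction their source
publications use; note it is conservative — measured against the true
sampling SD of the estimators under our generator it overestimates by
roughly 20% (median) and 30% (mode), so their confidence intervals
over-cover (~0.97–0.99 at nominal 0.95). IVW coverage sits at ~0.955–0.96.

## Instrument selection and harmonization

Instruments are SNPs with exposure $p < 5\times10^{-8}$, pruned by greedy LD
clumping at $r^2 \ge 0.001$ (best p kept, tagged SNPs removed) within a
10 Mb window when positions are available; the window is a clumping
convention, not a published choice, and is configurable. Exposures with no
surviving instrument are excluded with a reason code rather than dropped
silently. Harmonization aligns outcome records to the exposure's effect
allele, flipping signs for swapped alleles and applying strand complements
where needed; palindromic (A/T, C/G) SNPs are kept under a forward-strand
assumption — the appropriate choice when most outcome GWAS publish no allele
frequencies to check against — and counted. Duplicate SNP rows keep the
smallest p; input p-values of exactly zero are floored to the smallest
positive double before any quantile transform.

## Sensitivity battery

* **Modified Cochran's Q** (default): second-order weights
  $w_j(b) = \hat\gamma_j^2 / (\sigma_{Yj}^2 + b^2\sigma_{Xj}^2)$ evaluated at
  the pooled estimate, itself re-solved under those weights to convergence;
  the plain first-order Q is available (`method = "first_order"`) and is the
  form that nests Rucker's Q ($Q' \le Q$, the difference being the
  intercept's squared unscaled t statistic).
* **MR-PRESSO**: the observed residual sum of squares around leave-one-out
  IVW predictions is compared with `n_sim` simulated datasets from the
  no-pleiotropy model (2500 by default, as in the study design this package
  follows; reducible in configuration). P-values use the add-one rule, so
  the floor is $1/(n_{sim}+1)$, never zero. Flagged outliers are removed and
  IVW re-estimated; a distortion test compares the shift against random
  same-size removals. SNPs are processed in a canonical order internally so
  results are invariant to input row order.
* **Leave-one-out**, **funnel tables** (ratio vs precision, with IVW and
  Egger reference lines and a precision-weighted skew statistic), and
  **reverse MR** (roles swapped; reverse IVW $p > 0.05$ is the
  directionality check) complete the battery.

## Power

Per instrument, variance explained is
$R^2 = 2f(1-f)\beta^2 / \{2f(1-f)\beta^2 + 2f(1-f)N\sigma^2\}$ — the
$2f(1-f)$ factor cancels, and the package exploits that: when the effect
allele frequency is missing (common in consortium GWAS) it evaluates the
simplified form $\beta^2/(\beta^2+N\sigma^2)$ and flags the provenance.
$F = R^2(N-2)/(1-R^2)$. Study power for a binary outcome uses the normal
approximation with non-centrality
$|\log OR|\sqrt{N\,K(1-K)\,R^2}$ (assumed OR 1.3, two-sided
$\alpha = 0.05$ by default), pinned by a simulation oracle in the test
suite. At $R^2 = 0$ the power equals $\alpha$.

## Pooled "general contribution" analysis

Per-pair primary p-values (IVW with $\ge 2$ instruments, Wald ratio with 1;
an `ivw_only` pooling switch exists) are pooled per exposure class and per
disorder. Inflation is measured by $\lambda$: each p-value becomes a 1-df
chi-square quantile, sorted observed statistics are regressed through the
origin on expected order statistics, and the slope (with its normal CI) is
$\lambda$; all order statistics are used (a trim fraction is exposed).
Uniformity is tested by the two-sided KS test. Because $\lambda$ is
overestimated easily at small counts, a permutation null is provided: within
every pair the outcome associations are shuffled across instrument SNPs —
breaking the instrument-outcome linkage, preserving both marginals — and
$\lambda$/KS recomputed; permutation p-values use the add-one rule with
$B = 1000$ by default. A global across-pair shuffle was considered and
rejected as the default because it also destroys per-pair weighting
structure; the within-pair interpretation is a documented choice. Stratified
reruns drop heterogeneous pairs (Cochran $p < 0.05$) or PRESSO-flagged SNPs
and re-pool. Significance tiers are nominal ($0.05$), single-disease
($0.05/n_{exposures}$) and study-wide ($0.05/n_{pairs}$); the study-wide
denominator defaults to the enumerated pair count (e.g. 1320) with the
tested count (e.g. 1253) selectable, since both conventions appear in
practice.

## The synthetic generator

`simulate_pair()` draws, per SNP: MAF uniform in `maf_range`; exposure
standard error $1/\sqrt{2f(1-f)N_{exp}}$ (standardized trait); outcome
standard error additionally divided by $\sqrt{K(1-K)}$ for binary outcomes.
True exposure effects follow a two-component mixture: most SNPs are null,
and $\lceil 1.5\,n \rceil$ large-effect SNPs draw
$\gamma \sim N(0, \sigma^2)$ with $\sigma$ solved in closed form so each
reaches $p < 5\times10^{-8}$ with probability $2/3$ — the expected
significant count is then the requested $n$, and the significant set shows a
realistic spectrum of instrument strengths ($|z|$ from 5.45 upward) rather
than a pile-up at the threshold. Outcome effects are
$\Gamma_j = \beta\,\gamma_j + \alpha_j$ with pleiotropy $\alpha_j$ zero,
balanced ($N(0, s^2)$), directional ($N(s, s^2)$), or correlated with
$\gamma$ (InSIDE violation); designated outliers (placed on the strongest
instruments so they survive selection) add a shift. Exposure and outcome
noise are independent (no sample overlap). Optional block LD correlates both
the marginal effects ($R\gamma$) and the noise. The (beta, se, p) triple is
exactly consistent with the two-sided normal.

`simulate_study_collection()` assembles the full scan: DTI exposures at
sample size 17,706 and ROI exposures at 19,629; disorder outcomes with
log-uniform sample sizes between 9,725 and 1,331,010 and case fractions in
(0.2, 0.5); a stated fraction of pairs causal at effect 0.15 (random sign)
by default; 5% of DTI and 20% of ROI exposures carry no designated
instrument, so the no-strong-instrument exclusion path is exercised at
roughly the rates such scans see in practice. Default SNP panels are 60
SNPs per exposure with 1–8 requested instruments — scaled for desk use; the
statistical structure downstream code consumes (effect/se/p consistency,
instrument strength, exclusion rates) is what matters, not genome-scale row
counts.

What the generator does **not** emulate: realistic genome maps and LD beyond
block-constant correlation, population stratification, sample overlap
between cohorts, winner's-curse-corrected discovery (selection at
$5\times10^{-8}$ is applied, so the mild curse present in real studies is
present here too), non-normal effect distributions, and case-control
ascertainment subtleties beyond the $K(1-K)$ variance scaling. Tests passing
on this generator show the machinery is correct and calibrated under the
stated model — not that real-data results are confirmed.

## Numerical and design choices

* Wald-ratio standard errors are first-order delta method by default
  (second-order via `second_order = TRUE`); p-values are two-sided normal
  for ratio-based methods and $t_{k-2}$ for Egger.
* IVW is multiplicative random effects with the scale floored at 1
  (fixed-effect via `random_effects = FALSE`); Egger is unfloored (above).
* Bootstrap seeds are mandatory and derived per stage from the global seed
  by a multiplicative-congruential hash (`derive_seed()`), so any stage
  reruns identically in isolation; everything downstream is byte-identical
  under a fixed seed.
* HEIDI adds a $10^{-10}$-scaled ridge before solving the deviation
  covariance; fewer than 3 usable companions returns a distinct
  not-evaluable status, never a p-value.
* Degenerate inputs: $\hat\gamma = 0$ is an undefined-ratio error; equal
  ratios give $Q = 0, p = 1$; a pair whose instruments all fail
  harmonization is excluded downstream with a reason code.
* MR-PRESSO needs $\ge 4$ instruments, Egger/median/mode $\ge 3$, IVW
  $\ge 2$; below each threshold the report says not-evaluable rather than
  guessing.

## Problem sizes used by the tests and acceptance script

Monte-Carlo checks run at sizes chosen to give stable estimates on one CPU:
calibration of Egger-intercept/Cochran/PRESSO at 2000 null pairs (PRESSO at
500 simulations there); estimator recovery at 400 seeds per causal effect in
the test suite and 200 in the acceptance script, with 30-instrument panels
at $N = 5\times10^4$; CI coverage is pooled across the three causal-effect
settings (1200 draws) because per-setting binomial noise at a few hundred
seeds is comparable to the width of the acceptance band. The
weighted-median robustness scenario uses 40% invalid instruments with
moderate one-sided pleiotropic effects ($|N(0.02, 0.008)|$, i.e. ratio
shifts of roughly 0.1–0.3 against a true effect of 0.3): large enough to
pull IVW visibly off target, within the regime where the median's
majority-weight consistency applies. The weighted mode's bootstrap
over-coverage noted above is a property of the prescribed interval
construction, and the corresponding coverage check in the acceptance suite
documents it by failing on the conservative side.

## Limitations

Wald-ratio/IVW inference is first-order: very weak instruments (|z| near
the selection threshold) carry the usual ratio-estimator skew. HEIDI is a
delta-method approximation of the original statistic. The permutation null
interprets "shuffling SNP labels" within pairs; the original operational
definition is not public. Real GWAS ingestion assumes well-formed delimited
tables; VCF parsing, liftover and remote LD reference panels are out of
scope, with LD supplied by the user as a matrix or long table.
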