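Package: mrflow
Title: Two-Sample Mendelian Randomization for Brain-Imaging Exposures and
    Neuropsychiatric Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    scanning many imaging-derived exposures (white-matter diffusion
    parameters, regional volumes) against binary neuropsychiatric outcomes
    using GWAS summary statistics. Covers instrument selection with
    p-value thresholding and greedy LD clumping, allele harmonization,
    inverse-variance-weighted, MR-Egger, weighted-median, weighted-mode,
    Wald-ratio and SMR estimators, a full sensitivity battery (modified
    Cochran's Q, Rucker's Q, Egger intercept, MR-PRESSO outlier detection,
    HEIDI, leave-one-out, reverse MR), instrument-strength and power
    formulas, and a pooled p-value inflation analysis (genomic inflation
    factor lambda, Kolmogorov-Smirnov uniformity test, permutation nulls).
    Includes a seeded synthetic GWAS summary-statistic generator with known
    causal structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
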