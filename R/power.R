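#' Variance in the exposure explained by one instrument
#'
#' For an instrument with effect-allele frequency `EAF`, per-allele effect
#' `beta`, standard error `se` and sample size `n`, the variance explained is
#'
#' `R2 = 2*EAF*(1-EAF)*beta^2 / (2*EAF*(1-EAF)*beta^2 + 2*EAF*(1-EAF)*n*se^2)`
#'
#' The `2*EAF*(1-EAF)` factor cancels algebraically, leaving
#' `beta^2 / (beta^2 + n*se^2)`; the full form is evaluated when EAF is
#' available (and validates it), and the simplified se-based form — the same
#' number — is the fallback when EAF is missing, with `provenance = "se_only"`.
#'
#' @param beta,se Instrument effect and standard error (`se > 0`).
#' @param eaf Effect-allele frequency in `(0, 1)`, or `NA`.
#' @param n Exposure-GWAS sample size.
#' @return List with `r2` and `provenance` (`"eaf"` or `"se_only"`); `r2` is
#'   `NA` with `provenance = "not_evaluable"` when `n` is missing.
#' @export
instrument_r2 <- function(beta, se, eaf = NA_real_, n = NA_real_) {
  stopifnot(se > 0)
  if (is.na(n) || n <= 0) {
    return(list(r2 = NA_real_, provenance = "not_evaluable"))
  }
  if (!is.na(eaf)) {
    if (eaf <= 0 || eaf >= 1) stop("eaf must be in (0, 1)", call. = FALSE)
    v <- 2 * eaf * (1 - eaf)
    r2 <- (v * beta^2) / (v * beta^2 + v * n * se^2)
    return(list(r2 = r2, provenance = "eaf"))
  }
  list(r2 = beta^2 / (beta^2 + n * se^2), provenance = "se_only")
}

#' Instrument F statistic
#'
#' `F = R2 * (N - 2) / (1 - R2)`; values above ~10 are the conventional bar
#' for a non-weak instrument.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n Sample size (> 2).
#' @return The F statistic.
#' @export
f_statistic <- function(r2, n) {
  stopifnot(r2 >= 0, r2 < 1)
  if (n <= 2) stop("F statistic requires n > 2", call. = FALSE)
  r2 * (n - 2) / (1 - r2)
}

#' Power of a two-sample MR test with a binary outcome
#'
#' Normal-approximation power of the two-sided Wald test of the causal
#' log-odds ratio. The non-centrality is
#' `log(assumed_or) * sqrt(n_outcome * r2_total * case_fraction * (1 - case_fraction))`,
#' i.e. the asymptotic standard error of the IV estimate on the log-odds
#' scale is `1 / sqrt(N * K * (1-K) * R2)`:
#' `power = P(|Z + ncp| > z_{1-alpha/2})`. At `r2_total = 0` power equals
#' `alpha` (the test keeps its size when the instrument carries no
#' information).
#'
#' @param r2_total Total exposure variance explained by the instruments.
#' @param n_outcome Outcome-GWAS sample size.
#' @param case_fraction Proportion of cases in the outcome GWAS, in `(0, 1)`.
#' @param assumed_or Assumed causal odds ratio per 1-SD exposure
#'   (default 1.3).
#' @param alpha Two-sided type-I error (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
binary_outcome_power <- function(r2_total, n_outcome, case_fraction,
                                 assumed_or = 1.3, alpha = 0.05) {
  stopifnot(r2_total >= 0, r2_total < 1, n_outcome > 0,
            case_fraction > 0, case_fraction < 1, assumed_or > 0,
            alpha > 0, alpha < 1)
  ncp <- abs(log(assumed_or)) *
    sqrt(n_outcome * r2_total * case_fraction * (1 - case_fraction))
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Instrument-strength and power report for a pair
#'
#' Computes per-instrument R-squared and F statistics from the exposure GWAS
#' and the overall MR power at an assumed odds ratio, mirroring the standard
#' per-pair power columns (R2_total, F_min, power).
#'
#' @param pair A `harmonized_pair`.
#' @param n_exposure Exposure-GWAS sample size (used for R2/F when per-SNP n
#'   is unavailable).
#' @param n_outcome Outcome-GWAS sample size.
#' @param case_fraction Case fraction of the outcome GWAS.
#' @param eaf Optional vector of effect-allele frequencies per instrument.
#' @param assumed_or,alpha Power assumptions (defaults 1.3 and 0.05).
#' @return Object of class `mr_power`: list with `r2_per_snp`, `r2_total`,
#'   `f_per_snp`, `f_min`, `power`, `provenance`, and the assumptions.
#' @export
mr_power <- function(pair, n_exposure, n_outcome, case_fraction,
                     eaf = NULL, assumed_or = 1.3, alpha = 0.05) {
  d <- pair_snps(pair)
  k <- nrow(d)
  if (is.null(eaf)) eaf <- rep(NA_real_, k)
  rr <- lapply(seq_len(k), function(i) {
    instrument_r2(d$beta_exp[i], d$se_exp[i], eaf[i], n_exposure)
  })
  r2 <- vapply(rr, `[[`, numeric(1), "r2")
  prov <- vapply(rr, `[[`, character(1), "provenance")
  r2_total <- sum(r2)
  f <- vapply(r2, function(x) {
    if (is.na(x)) NA_real_ else f_statistic(x, n_exposure)
  }, numeric(1))
  pw <- if (is.na(r2_total)) NA_real_ else {
    binary_outcome_power(min(r2_total, 1 - 1e-12), n_outcome, case_fraction,
                         assumed_or, alpha)
  }
  structure(
    list(r2_per_snp = r2, r2_total = r2_total, f_per_snp = f,
         f_min = if (all(is.na(f))) NA_real_ else min(f, na.rm = TRUE),
         power = pw, provenance = prov, assumed_or = assumed_or,
         alpha = alpha, n_outcome = n_outcome,
         case_fraction = case_fraction),
    class = "mr_power"
  )
}

#' @export
print.mr_power <- function(x, ...) {
  cat(sprintf("MR power report: R2_total = %.4g, F_min = %.3g, power = %.3f (OR = %.2f, alpha = %.2f)\n",
              x$r2_total, x$f_min, x$power, x$assumed_or, x$alpha))
  invisible(x)
}
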