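## One-row estimate record shared by every method. `df` selects the reference
## distribution: NULL -> normal, otherwise Student t with that df.
new_estimate <- function(method, beta, se, n_snp, df = NULL) {
  if (is.null(df)) {
    p <- p_normal(beta, se)
    crit <- stats::qnorm(0.975)
  } else {
    p <- 2 * stats::pt(-abs(beta / se), df = df)
    crit <- stats::qt(0.975, df = df)
  }
  data.frame(method = method, beta = beta, se = se,
             ci_low = beta - crit * se, ci_high = beta + crit * se,
             pvalue = max(p, P_FLOOR), n_snp = n_snp,
             stringsAsFactors = FALSE)
}

pair_snps <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  pair$snps
}

#' Wald-ratio causal estimate from a single instrument
#'
#' The per-SNP causal estimate `beta_out / beta_exp`, with first-order
#' delta-method standard error `se_out / |beta_exp|` (the second-order form
#' adds the exposure-error term and is available via `second_order = TRUE`).
#'
#' @param pair A `harmonized_pair`; the first row is used unless `i` is given.
#' @param i Row index of the instrument to use.
#' @param second_order Logical; include the exposure sampling-error term in
#'   the delta-method variance.
#' @return One-row estimate data frame (`method`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, `n_snp`).
#' @export
wald_ratio <- function(pair, i = 1L, second_order = FALSE) {
  d <- pair_snps(pair)[i, , drop = FALSE]
  if (nrow(d) != 1L) stop("wald_ratio needs exactly one instrument", call. = FALSE)
  if (d$beta_exp == 0) stop("undefined ratio: exposure beta is 0", call. = FALSE)
  beta <- d$beta_out / d$beta_exp
  se <- if (second_order) {
    sqrt(d$se_out^2 / d$beta_exp^2 + d$beta_out^2 * d$se_exp^2 / d$beta_exp^4)
  } else {
    d$se_out / abs(d$beta_exp)
  }
  new_estimate("wald_ratio", beta, se, 1L)
}

## Core IVW arithmetic, usable at k = 1 (then identical to the Wald ratio).
## Ratio estimates combined with first-order weights beta_exp^2 / se_out^2 —
## algebraically the zero-intercept WLS slope of beta_out on beta_exp with
## weights 1/se_out^2. Multiplicative random effects: se scaled by
## max(1, sqrt(Q / (k - 1))).
ivw_core <- function(bx, sx, by, sy, random_effects = TRUE) {
  w <- bx^2 / sy^2
  r <- by / bx
  beta <- sum(w * r) / sum(w)
  se <- sqrt(1 / sum(w))
  k <- length(bx)
  q <- sum(w * (r - beta)^2)
  scale <- 1
  if (random_effects && k >= 2L) scale <- max(1, sqrt(q / (k - 1)))
  list(beta = beta, se = se * scale, q = q, k = k)
}

#' Inverse-variance-weighted (IVW) causal estimate
#'
#' Meta-analysis of per-SNP Wald ratios with first-order inverse-variance
#' weights; equivalently the slope of a zero-intercept weighted regression of
#' outcome on exposure effects with weights `1/se_out^2`. By default the
#' standard error uses multiplicative random effects: it is inflated by
#' `sqrt(Q/(k-1))` when Cochran's Q exceeds its degrees of freedom, never
#' deflated.
#'
#' @param pair A `harmonized_pair` with at least two instruments.
#' @param random_effects Logical; `FALSE` gives the fixed-effect standard
#'   error.
#' @return One-row estimate data frame; see [wald_ratio()].
#' @export
mr_ivw <- function(pair, random_effects = TRUE) {
  d <- pair_snps(pair)
  if (nrow(d) < 2L) stop("IVW needs at least two instruments", call. = FALSE)
  fit <- ivw_core(d$beta_exp, d$se_exp, d$beta_out, d$se_out, random_effects)
  new_estimate("ivw", fit$beta, fit$se, fit$k)
}

## Egger arithmetic on oriented effects; closed-form WLS with intercept.
## se_floor = TRUE floors the residual scale at 1 (never deflates); the
## default scales by the residual sigma exactly as weighted lm() does, which
## keeps the intercept t-test exactly calibrated under homogeneity.
egger_core <- function(bx, sx, by, sy, se_floor = FALSE) {
  flip <- sign(bx); flip[flip == 0] <- 1
  bx <- bx * flip; by <- by * flip
  w <- 1 / sy^2
  W <- sum(w); Sx <- sum(w * bx); Sy <- sum(w * by)
  Sxx <- sum(w * bx^2); Sxy <- sum(w * bx * by)
  D <- W * Sxx - Sx^2
  slope <- (W * Sxy - Sx * Sy) / D
  intercept <- (Sy - slope * Sx) / W
  k <- length(bx)
  q <- sum(w * (by - intercept - slope * bx)^2)
  scale <- if (k > 2L) sqrt(q / (k - 2)) else 1
  if (se_floor) scale <- max(1, scale)
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(W / D) * scale, se_intercept = sqrt(Sxx / D) * scale,
       q = q, k = k)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept, after orienting every instrument to a non-negative exposure
#' effect. The slope is a pleiotropy-robust causal estimate under the InSIDE
#' assumption; the intercept estimates directional pleiotropy and its p-value
#' is the standard pleiotropy test. Standard errors scale with the weighted
#' residual standard deviation (exactly as weighted least squares does) and
#' use a t reference with `k - 2` df, which keeps the intercept test
#' calibrated under homogeneity; `se_floor = TRUE` floors the residual scale
#' at 1 so standard errors are never deflated below the fixed-effect value.
#'
#' @param pair A `harmonized_pair` with at least three instruments.
#' @param se_floor Logical; floor the residual scale at 1 (default FALSE).
#' @return List with one-row estimate data frames `slope` and `intercept`.
#' @export
mr_egger <- function(pair, se_floor = FALSE) {
  d <- pair_snps(pair)
  if (nrow(d) < 3L) stop("MR-Egger needs at least three instruments", call. = FALSE)
  fit <- egger_core(d$beta_exp, d$se_exp, d$beta_out, d$se_out,
                    se_floor = se_floor)
  list(slope = new_estimate("egger_slope", fit$slope, fit$se_slope,
                            fit$k, df = fit$k - 2),
       intercept = new_estimate("egger_intercept", fit$intercept,
                                fit$se_intercept, fit$k, df = fit$k - 2))
}

weighted_median_core <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]; w <- weights[o] / sum(weights)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  j <- max(which(cw < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - cw[j]) / (cw[j + 1] - cw[j])
}

## Parametric bootstrap se for median/mode estimators: resample per-SNP betas
## from their normal sampling distributions, re-estimate, take the sd.
boot_se <- function(d, estimator, n_boot, seed) {
  set.seed(seed)
  k <- nrow(d)
  est <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, d$beta_exp, d$se_exp)
    by <- stats::rnorm(k, d$beta_out, d$se_out)
    estimator(bx, by)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted-median causal estimate
#'
#' The ratio estimate at which the normalized cumulative inverse-variance
#' weight of the ordered per-SNP Wald ratios crosses one half, with linear
#' interpolation between adjacent ratios. Consistent when instruments holding
#' at least half the weight are valid, so it tolerates up to 50% invalid
#' instruments. Standard error by seeded parametric bootstrap.
#'
#' @param pair A `harmonized_pair` with at least three instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row estimate data frame; see [wald_ratio()].
#' @export
mr_weighted_median <- function(pair, n_boot = 1000, seed = 1L) {
  d <- pair_snps(pair)
  if (nrow(d) < 3L) stop("weighted median needs at least three instruments", call. = FALSE)
  wm <- function(bx, by) {
    weighted_median_core(by / bx, bx^2 / d$se_out^2)
  }
  beta <- wm(d$beta_exp, d$beta_out)
  se <- boot_se(d, wm, n_boot, seed)
  new_estimate("weighted_median", beta, se, nrow(d))
}

## Mode bandwidth: phi times a modified Silverman rule on the ratio scale.
mode_bandwidth <- function(ratios, phi) {
  s <- stats::sd(ratios)
  m <- stats::mad(ratios)
  disp <- if (m > 0) min(s, m) else s
  if (disp == 0) disp <- max(abs(ratios[1]), 1e-8) * 1e-6
  phi * 0.9 * disp * length(ratios)^(-1 / 5)
}

weighted_mode_core <- function(ratios, weights, bandwidth) {
  if (stats::sd(ratios) == 0) return(ratios[1])
  dens <- stats::density(ratios, weights = weights / sum(weights),
                         bw = bandwidth, n = 2048)
  dens$x[which.max(dens$y)]
}

#' Weighted-mode causal estimate
#'
#' Kernel-density (normal kernel) estimate of the mode of the per-SNP Wald
#' ratios, weighted by first-order inverse ratio variances; the causal
#' estimate is the density argmax. Consistent when the largest group of
#' instruments sharing a ratio is valid (ZEMPA). Bandwidth is `phi` times a
#' modified Silverman rule; standard error by seeded parametric bootstrap.
#'
#' @param pair A `harmonized_pair` with at least three instruments.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row estimate data frame; see [wald_ratio()].
#' @export
mr_weighted_mode <- function(pair, phi = 1, n_boot = 1000, seed = 1L) {
  d <- pair_snps(pair)
  if (nrow(d) < 3L) stop("weighted mode needs at least three instruments", call. = FALSE)
  wmode <- function(bx, by) {
    r <- by / bx
    w <- bx^2 / d$se_out^2
    weighted_mode_core(r, w, mode_bandwidth(r, phi))
  }
  beta <- wmode(d$beta_exp, d$beta_out)
  se <- boot_se(d, wmode, n_boot, seed)
  new_estimate("weighted_mode", beta, se, nrow(d))
}

#' Summary-data-based MR (SMR) test for a single instrument
#'
#' Tests the null of no mediated effect using
#' `T = z_exp^2 * z_out^2 / (z_exp^2 + z_out^2)` against chi-square with 1 df;
#' the point estimate is the Wald ratio. With a very strong instrument
#' (`|z_exp| -> Inf`) T tends to `z_out^2` and the p-value to the outcome GWAS
#' p-value.
#'
#' @param pair A `harmonized_pair`; row `i` (default the smallest exposure
#'   p-value) is the top instrument.
#' @param i Row index of the instrument to test; default picks the top SNP.
#' @return One-row estimate data frame with `method = "smr"`; the p-value is
#'   the SMR chi-square p, the beta/se/CI are the Wald ratio's.
#' @export
smr_test <- function(pair, i = NULL) {
  d <- pair_snps(pair)
  if (nrow(d) < 1L) stop("smr_test needs an instrument", call. = FALSE)
  if (is.null(i)) i <- which.min(d$p_exp)
  w <- wald_ratio(pair, i = i)
  zx <- d$beta_exp[i] / d$se_exp[i]
  zy <- d$beta_out[i] / d$se_out[i]
  t_smr <- zx^2 * zy^2 / (zx^2 + zy^2)
  out <- new_estimate("smr", w$beta, w$se, 1L)
  out$pvalue <- max(stats::pchisq(t_smr, df = 1, lower.tail = FALSE), P_FLOOR)
  attr(out, "t_smr") <- t_smr
  out
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Distinguishes a single shared causal variant (top SNP and its LD companions
#' all imply the same Wald ratio) from linkage of distinct causal variants
#' (ratios differ). For each companion SNP i the deviation
#' `d_i = ratio_i - ratio_top` is formed; its covariance follows from the LD
#' correlation between SNPs and the first-order delta method, and the
#' quadratic form `d' V^{-1} d` is referred to chi-square with m df. Small p
#' indicates heterogeneity, i.e. the association is driven by linkage; p >=
#' 0.05 is reported as no evidence of colocalization pleiotropy.
#'
#' Companions default to SNPs with exposure p below `p_companion` and LD
#' r-squared to the top SNP within `r2_range`, capped at `max_companions`
#' (strongest exposure signals first).
#'
#' @param pair A `harmonized_pair` holding the top SNP and candidate
#'   companions (all harmonized to the exposure's effect alleles).
#' @param ld LD source for [ld_lookup()]; must be a signed correlation matrix
#'   covering the SNPs (r, not r-squared).
#' @param p_companion Companion exposure p-value ceiling (default 1.6e-3).
#' @param r2_range Allowed r-squared between companion and top SNP (default
#'   `c(0.05, 0.9)`).
#' @param max_companions Maximum companions used (default 20).
#' @return List with `status` (`"ok"` or `"not_evaluable"`), `p`,
#'   `n_companions`, `top_snp`.
#' @export
heidi_test <- function(pair, ld, p_companion = 1.6e-3,
                       r2_range = c(0.05, 0.9), max_companions = 20L) {
  d <- pair_snps(pair)
  if (!is.matrix(ld)) stop("HEIDI needs an LD correlation matrix", call. = FALSE)
  i_top <- which.min(d$p_exp)
  ids <- d$snp_id
  if (!all(ids %in% rownames(ld))) {
    stop("LD matrix does not cover all SNPs in the pair", call. = FALSE)
  }
  r_top <- ld[ids, ids[i_top]]
  r2 <- r_top^2
  cand <- which(seq_len(nrow(d)) != i_top &
                  d$p_exp < p_companion &
                  r2 >= r2_range[1] & r2 <= r2_range[2])
  if (length(cand) > max_companions) {
    cand <- cand[order(d$p_exp[cand])][seq_len(max_companions)]
  }
  m <- length(cand)
  if (m < 3L) {
    return(list(status = "not_evaluable", p = NA_real_, n_companions = m,
                top_snp = ids[i_top]))
  }
  b <- d$beta_out / d$beta_exp
  dev <- b[cand] - b[i_top]
  ## First-order variance of each ratio and LD-driven covariance between
  ## ratios: cov(b_i, b_j) ~ r_ij * (se_out_i se_out_j)/(bx_i bx_j); the
  ## exposure term is second order and dropped consistently.
  R <- ld[ids, ids]
  var_b <- d$se_out^2 / d$beta_exp^2
  cov_b <- outer(d$se_out / d$beta_exp, d$se_out / d$beta_exp) * R
  idx <- c(cand, i_top)
  Cb <- cov_b[idx, idx, drop = FALSE]
  mm <- length(cand)
  ## cov(d_i, d_j) = cov(b_i,b_j) - cov(b_i,b_top) - cov(b_j,b_top) + var(b_top)
  V <- Cb[seq_len(mm), seq_len(mm), drop = FALSE] -
    outer(Cb[seq_len(mm), mm + 1], rep(1, mm)) -
    outer(rep(1, mm), Cb[seq_len(mm), mm + 1]) +
    Cb[mm + 1, mm + 1]
  ridge <- 1e-10 * mean(diag(V))
  stat <- drop(crossprod(dev, solve(V + diag(ridge, mm), dev)))
  p <- stats::pchisq(stat, df = mm, lower.tail = FALSE)
  list(status = "ok", p = max(p, P_FLOOR), n_companions = mm,
       top_snp = ids[i_top], statistic = stat)
}

#' Convert a log-odds estimate to an odds ratio
#'
#' Exponentiates the causal estimate and its confidence bounds and reports the
#' signed percent change `100 * (OR - 1)`.
#'
#' @param est A one-row estimate data frame (e.g. from [mr_ivw()]).
#' @param outcome_type Scale check: must be `"binary"` (log-odds scale).
#' @return List with `odds_ratio`, `or_ci_low`, `or_ci_high`,
#'   `percent_change`.
#' @export
to_odds_ratio <- function(est, outcome_type = "binary") {
  if (!identical(outcome_type, "binary")) {
    stop("odds-ratio conversion requires a binary outcome (log-odds beta)",
         call. = FALSE)
  }
  or <- exp(est$beta)
  list(odds_ratio = or, or_ci_low = exp(est$ci_low),
       or_ci_high = exp(est$ci_high), percent_change = 100 * (or - 1))
}
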