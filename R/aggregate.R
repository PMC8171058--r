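#' Kolmogorov-Smirnov test of p-value uniformity
#'
#' Two-sided KS test of a set of per-pair p-values against Uniform(0,1); a
#' small p-value indicates departure from the null expectation (inflation
#' when paired with lambda > 1).
#'
#' @param pvalues Numeric vector of p-values in `(0, 1]` (at least 5).
#' @return List with `statistic` (D) and `p`.
#' @export
ks_uniform <- function(pvalues) {
  pvalues <- floor_p(as.numeric(pvalues))
  if (length(pvalues) < 5L) {
    return(list(statistic = NA_real_, p = NA_real_, status = "not_evaluable"))
  }
  kt <- suppressWarnings(stats::ks.test(pvalues, "punif"))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value), status = "ok")
}

#' Genomic inflation factor by chi-square regression
#'
#' Converts each p-value to its 1-df chi-square quantile and regresses the
#' sorted observed statistics on the expected 1-df chi-square order
#' statistics through the origin; the slope is the inflation factor lambda
#' (1 under the uniform null, > 1 for systematic enrichment of small
#' p-values), with a 95% confidence interval from the slope standard error.
#' All order statistics enter the regression (no trimming by default).
#'
#' @param pvalues Numeric vector of p-values (at least 5); zeros are floored.
#' @param trim Fraction of the largest statistics to drop before regression
#'   (default 0, i.e. none).
#' @return List with `lambda`, `ci` (length-2), `se`, `n`.
#' @export
inflation_lambda <- function(pvalues, trim = 0) {
  pvalues <- floor_p(as.numeric(pvalues))
  n <- length(pvalues)
  if (n < 5L) {
    return(list(lambda = NA_real_, ci = c(NA_real_, NA_real_),
                se = NA_real_, n = n, status = "not_evaluable"))
  }
  obs <- sort(stats::qchisq(pvalues, df = 1, lower.tail = FALSE))
  expd <- sort(stats::qchisq(stats::ppoints(n), df = 1, lower.tail = FALSE))
  if (trim > 0) {
    keep <- seq_len(floor(n * (1 - trim)))
    obs <- obs[keep]; expd <- expd[keep]
  }
  fit <- stats::lm.fit(x = matrix(expd, ncol = 1), y = obs)
  lambda <- unname(fit$coefficients)
  dfres <- length(obs) - 1L
  s2 <- sum(fit$residuals^2) / dfres
  se <- sqrt(s2 / sum(expd^2))
  z <- stats::qnorm(0.975)
  list(lambda = lambda, ci = c(lambda - z * se, lambda + z * se),
       se = se, n = n, status = "ok")
}

#' Pool per-pair p-values into an inflation summary
#'
#' Combines [inflation_lambda()] and [ks_uniform()] for one stratum of
#' exposure-outcome pairs. Duplicate pair labels are rejected.
#'
#' @param pvalues P-values (at least 5).
#' @param stratum Label (e.g. `"all"`, a disease, `"heterogeneity-removed"`).
#' @param pair_ids Optional pair labels used only to reject duplicates.
#' @return Object of class `mr_pooled`: `lambda_hat`, `lambda_ci`, `ks_p`,
#'   `ks_d`, `n_pvalues`, `stratum`, and optional permutation p-values (NA
#'   until [permutation_null()] supplies them).
#' @export
pool_pvalues <- function(pvalues, stratum = "all", pair_ids = NULL) {
  if (!is.null(pair_ids) && anyDuplicated(pair_ids)) {
    stop("duplicate pair ids in pooled set", call. = FALSE)
  }
  lam <- inflation_lambda(pvalues)
  ks <- ks_uniform(pvalues)
  structure(
    list(lambda_hat = lam$lambda, lambda_ci = lam$ci, lambda_se = lam$se,
         ks_p = ks$p, ks_d = ks$statistic, n_pvalues = length(pvalues),
         permutation_p_lambda = NA_real_, permutation_p_ks = NA_real_,
         stratum = stratum),
    class = "mr_pooled"
  )
}

#' @export
print.mr_pooled <- function(x, ...) {
  cat(sprintf("Pooled p-value inflation [%s]: lambda = %.2f (%.2f~%.2f), KS p = %.3g, n = %d\n",
              x$stratum, x$lambda_hat, x$lambda_ci[1], x$lambda_ci[2],
              x$ks_p, x$n_pvalues))
  if (!is.na(x$permutation_p_lambda)) {
    cat(sprintf("  permutation p: lambda %.3g, KS %.3g\n",
                x$permutation_p_lambda, x$permutation_p_ks))
  }
  invisible(x)
}

pair_primary_p <- function(pair) {
  k <- nrow(pair$snps)
  if (k >= 2L) mr_ivw(pair)$pvalue
  else if (k == 1L) wald_ratio(pair)$pvalue
  else NA_real_
}

#' Permutation null for pooled inflation statistics
#'
#' Shuffles, within every pair, the assignment of outcome associations to
#' instrument SNPs — breaking the instrument-outcome linkage while
#' preserving both marginal distributions — recomputes every IVW p-value,
#' and from `B` such shuffles derives add-one permutation p-values for the
#' observed lambda and KS statistics: `p = (1 + #{perm >= obs}) / (B + 1)`,
#' so the smallest attainable p is `1/(B+1)`.
#'
#' @param pairs List of `harmonized_pair` objects, each with at least two
#'   instruments.
#' @param B Number of permutations (at least 100; the conventional choice is
#'   1000).
#' @param seed Integer seed.
#' @return An `mr_pooled` object for the observed p-values with
#'   `permutation_p_lambda` and `permutation_p_ks` filled in.
#' @export
permutation_null <- function(pairs, B = 1000L, seed = 1L) {
  stopifnot(B >= 100L)
  ks <- vapply(pairs, function(p) nrow(p$snps), integer(1))
  if (any(ks < 2L)) {
    stop("every pair must have at least two instruments", call. = FALSE)
  }
  obs_p <- vapply(pairs, pair_primary_p, numeric(1))
  pooled <- pool_pvalues(obs_p, stratum = "permutation-tested")
  set.seed(seed)
  lam_perm <- numeric(B)
  ks_perm <- numeric(B)
  snp_data <- lapply(pairs, `[[`, "snps")
  for (b in seq_len(B)) {
    pb <- vapply(snp_data, function(d) {
      idx <- sample.int(nrow(d))
      fit <- ivw_core(d$beta_exp, d$se_exp, d$beta_out[idx], d$se_out[idx])
      p_normal(fit$beta, fit$se)
    }, numeric(1))
    lam_perm[b] <- inflation_lambda(pb)$lambda
    ks_perm[b] <- ks_uniform(pb)$statistic
  }
  pooled$permutation_p_lambda <-
    (1 + sum(lam_perm >= pooled$lambda_hat)) / (B + 1)
  pooled$permutation_p_ks <- (1 + sum(ks_perm >= pooled$ks_d)) / (B + 1)
  pooled
}

#' Re-pool p-values after removing heterogeneity or outliers
#'
#' `remove_heterogeneous` drops whole pairs whose Cochran p is below 0.05;
#' `remove_outlier_snps` drops each pair's MR-PRESSO-flagged SNPs and
#' recomputes the pair's primary p-value before pooling.
#'
#' @param pairs List of `harmonized_pair` objects.
#' @param sensitivities List of [mr_sensitivity()] reports, parallel to
#'   `pairs`.
#' @param mode `"remove_heterogeneous"` or `"remove_outlier_snps"`.
#' @param stratum Label for the result (default the mode).
#' @return An `mr_pooled` object, or status `not_evaluable` when fewer than
#'   5 p-values survive.
#' @export
stratified_rerun <- function(pairs, sensitivities,
                             mode = c("remove_heterogeneous",
                                      "remove_outlier_snps"),
                             stratum = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(pairs) == length(sensitivities))
  pvals <- numeric(0)
  for (i in seq_along(pairs)) {
    pair <- pairs[[i]]
    sens <- sensitivities[[i]]
    if (mode == "remove_heterogeneous") {
      if (isTRUE(sens$cochran_p < 0.05)) next
      pvals <- c(pvals, pair_primary_p(pair))
    } else {
      drop_ids <- sens$presso_outliers
      if (length(drop_ids)) {
        keep <- !(pair$snps$snp_id %in% drop_ids)
        if (sum(keep) < 1L) next
        pair$snps <- pair$snps[keep, , drop = FALSE]
      }
      pvals <- c(pvals, pair_primary_p(pair))
    }
  }
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) < 5L) {
    out <- pool_pvalues(rep(0.5, 5), stratum = stratum %||% mode)
    out$lambda_hat <- NA_real_; out$lambda_ci <- c(NA_real_, NA_real_)
    out$ks_p <- NA_real_; out$ks_d <- NA_real_
    out$n_pvalues <- length(pvals); out$status <- "not_evaluable"
    return(out)
  }
  pool_pvalues(pvals, stratum = stratum %||% mode)
}

TIER_LEVELS <- c("NS", "nominal", "single_disease", "study_wide")

#' Significance tiers and rank-rank overlap
#'
#' Assigns each pair's p-value to nested significance tiers — `NS`,
#' `nominal` (p < 0.05), `single_disease` (p < 0.05 / number of exposures),
#' `study_wide` (p < 0.05 / number of pairs) — and, when heterogeneity
#' p-values are supplied, cross-tabulates MR tier against heterogeneity tier
#' with row-normalized proportions (each row sums to 1).
#'
#' @param pvalues Per-pair MR p-values.
#' @param n_exposures Single-disease Bonferroni denominator (e.g. 110).
#' @param n_pairs_total Study-wide Bonferroni denominator — the enumerated
#'   pair count (e.g. 1320) by default; pass the tested count (e.g. 1253) to
#'   use that convention instead.
#' @param het_pvalues Optional heterogeneity p-values, same length.
#' @return List with `tiers` (ordered factor), `thresholds`, and (when
#'   `het_pvalues` given) `overlap_counts` and `overlap_prop`.
#' @export
classify_tiers <- function(pvalues, n_exposures, n_pairs_total,
                           het_pvalues = NULL) {
  th <- c(nominal = 0.05, single_disease = 0.05 / n_exposures,
          study_wide = 0.05 / n_pairs_total)
  tier_of <- function(p) {
    ifelse(is.na(p), NA_character_,
           ifelse(p < th["study_wide"], "study_wide",
                  ifelse(p < th["single_disease"], "single_disease",
                         ifelse(p < th["nominal"], "nominal", "NS"))))
  }
  tiers <- factor(tier_of(pvalues), levels = TIER_LEVELS, ordered = TRUE)
  out <- list(tiers = tiers, thresholds = th)
  if (!is.null(het_pvalues)) {
    stopifnot(length(het_pvalues) == length(pvalues))
    het <- factor(tier_of(het_pvalues), levels = TIER_LEVELS, ordered = TRUE)
    counts <- table(mr = tiers, heterogeneity = het)
    rs <- rowSums(counts)
    prop <- counts / ifelse(rs == 0, 1, rs)
    out$overlap_counts <- counts
    out$overlap_prop <- prop
  }
  out
}

#' QQ-plot-ready table of pooled p-values
#'
#' Expected versus observed -log10 p for each stratum, sorted ascending.
#'
#' @param pvalues P-values.
#' @param stratum Stratum label attached as a column.
#' @return Data frame with `stratum`, `expected`, `observed` (-log10 scale).
#' @export
qq_table <- function(pvalues, stratum = "all") {
  p <- sort(floor_p(as.numeric(pvalues)))
  n <- length(p)
  data.frame(stratum = stratum,
             expected = -log10(stats::ppoints(n)),
             observed = -log10(p),
             stringsAsFactors = FALSE)
}
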