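#' Cochran's Q heterogeneity test around the IVW estimate
#'
#' Default is the modified form: ratio variances use second-order weights
#' `w_i(b) = beta_exp_i^2 / (se_out_i^2 + b^2 * se_exp_i^2)` evaluated at the
#' pooled estimate, which is itself re-solved under those weights until
#' convergence. `method = "first_order"` gives the plain Q with weights
#' `beta_exp^2 / se_out^2` about the first-order IVW estimate; that form
#' nests within Rucker's Q (see [rucker_q()]).
#'
#' @param pair A `harmonized_pair` with at least two instruments.
#' @param method `"modified"` (default) or `"first_order"`.
#' @param max_iter,tol Convergence controls for the modified weights.
#' @return List with `Q`, `df` (`k - 1`), `p`, `beta` (the pooled estimate the
#'   weights were evaluated at) and `method`.
#' @export
cochran_q <- function(pair, method = c("modified", "first_order"),
                      max_iter = 50L, tol = 1e-10) {
  method <- match.arg(method)
  d <- pair_snps(pair)
  k <- nrow(d)
  if (k < 2L) {
    return(list(Q = NA_real_, df = NA_integer_, p = NA_real_,
                beta = NA_real_, method = method, status = "not_evaluable"))
  }
  r <- d$beta_out / d$beta_exp
  if (method == "first_order") {
    w <- d$beta_exp^2 / d$se_out^2
    beta <- sum(w * r) / sum(w)
  } else {
    beta <- {
      w0 <- d$beta_exp^2 / d$se_out^2
      sum(w0 * r) / sum(w0)
    }
    for (it in seq_len(max_iter)) {
      w <- d$beta_exp^2 / (d$se_out^2 + beta^2 * d$se_exp^2)
      beta_new <- sum(w * r) / sum(w)
      if (abs(beta_new - beta) < tol) { beta <- beta_new; break }
      beta <- beta_new
    }
    w <- d$beta_exp^2 / (d$se_out^2 + beta^2 * d$se_exp^2)
  }
  Q <- sum(w * (r - beta)^2)
  list(Q = Q, df = k - 1L,
       p = stats::pchisq(Q, df = k - 1, lower.tail = FALSE),
       beta = beta, method = method, status = "ok")
}

#' Rucker's Q: heterogeneity around the Egger line
#'
#' Residual weighted sum of squares about the Egger regression (first-order
#' weights `1/se_out^2` on the effect scale), referred to chi-square with
#' `k - 2` df. Always satisfies `Q' <= Q` for the first-order Cochran Q, since
#' the Egger model nests the zero-intercept IVW model.
#'
#' @param pair A `harmonized_pair` with at least three instruments.
#' @return List with `Q`, `df` (`k - 2`), `p`.
#' @export
rucker_q <- function(pair) {
  d <- pair_snps(pair)
  k <- nrow(d)
  if (k < 3L) {
    return(list(Q = NA_real_, df = NA_integer_, p = NA_real_,
                status = "not_evaluable"))
  }
  fit <- egger_core(d$beta_exp, d$se_exp, d$beta_out, d$se_out)
  list(Q = fit$q, df = k - 2L,
       p = stats::pchisq(fit$q, df = k - 2, lower.tail = FALSE),
       status = "ok")
}

#' Leave-one-out IVW estimates
#'
#' Recomputes the IVW estimate omitting each instrument in turn; a single SNP
#' whose omission moves the estimate far more than any other flags a dominant
#' or outlying instrument.
#'
#' @param pair A `harmonized_pair` with at least three instruments.
#' @return Data frame with one row per omitted SNP: `snp_id`, `beta`, `se`,
#'   `pvalue`.
#' @export
leave_one_out <- function(pair) {
  d <- pair_snps(pair)
  k <- nrow(d)
  if (k < 3L) stop("leave-one-out needs at least three instruments", call. = FALSE)
  res <- lapply(seq_len(k), function(i) {
    fit <- ivw_core(d$beta_exp[-i], d$se_exp[-i], d$beta_out[-i], d$se_out[-i])
    data.frame(snp_id = d$snp_id[i], beta = fit$beta, se = fit$se,
               pvalue = p_normal(fit$beta, fit$se), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' MR-PRESSO: global pleiotropy test, outlier detection and correction
#'
#' Simulation-based residual-sum-of-squares test. The observed RSS sums, over
#' instruments, the weighted squared difference between each observed outcome
#' effect and its prediction from the leave-one-out IVW slope. The null
#' distribution is built by redrawing exposure and outcome effects from the
#' no-pleiotropy model (outcome mean = leave-one-out slope times exposure
#' effect) `n_sim` times under a fixed seed; the global p-value is the
#' add-one exceedance fraction, so it is never 0 (minimum `1/(n_sim+1)`).
#' Per-SNP outlier p-values compare each observed contribution to its
#' simulated distribution, Bonferroni-corrected over k; flagged SNPs are
#' removed and the IVW estimate recomputed (`corrected_ivw`). When outliers
#' exist, a distortion test compares the original and corrected estimates
#' against re-estimates with random instrument subsets of the same size
#' removed.
#'
#' @param pair A `harmonized_pair` with at least four instruments.
#' @param n_sim Simulated datasets (default 2500, reducible for speed).
#' @param signif Outlier significance level after Bonferroni (default 0.05).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return List with `status`, `global_p`, `outliers` (SNP ids),
#'   `outlier_p` (per SNP, Bonferroni-corrected), `distortion_p` (NA when no
#'   outlier), `corrected_ivw` (one-row estimate or NULL).
#' @export
mr_presso <- function(pair, n_sim = 2500, signif = 0.05, seed = 1L) {
  d <- pair_snps(pair)
  k <- nrow(d)
  if (k < 4L) {
    return(list(status = "not_evaluable", global_p = NA_real_,
                outliers = character(0), outlier_p = rep(NA_real_, k),
                distortion_p = NA_real_, corrected_ivw = NULL))
  }
  ## canonical SNP order so results are invariant to input row order
  ord <- order(d$snp_id)
  d <- d[ord, , drop = FALSE]
  bx <- d$beta_exp; sx <- d$se_exp; by <- d$beta_out; sy <- d$se_out
  w <- 1 / sy^2

  loo_slopes <- function(BX, BY) {
    ## column-wise leave-one-out zero-intercept WLS slopes, weights fixed 1/sy^2
    num <- colSums(w * BX * BY)
    den <- colSums(w * BX^2)
    (rep(num, each = k) - w * BX * BY) / (rep(den, each = k) - w * BX^2)
  }
  contrib <- function(BX, BY) {
    sl <- loo_slopes(BX, BY)
    w * (BY - sl * BX)^2
  }

  obs_c <- contrib(matrix(bx), matrix(by))
  rss_obs <- sum(obs_c)
  mu <- loo_slopes(matrix(bx), matrix(by)) * bx  # no-pleiotropy outcome means

  set.seed(seed)
  BX <- matrix(stats::rnorm(k * n_sim, bx, sx), nrow = k)
  BY <- matrix(stats::rnorm(k * n_sim, mu, sy), nrow = k)
  sim_c <- contrib(BX, BY)
  rss_sim <- colSums(sim_c)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  p_snp <- (1 + rowSums(sim_c >= as.vector(obs_c))) / (n_sim + 1)
  p_snp_adj <- pmin(1, p_snp * k)
  out_idx <- which(p_snp_adj < signif)
  outliers <- d$snp_id[out_idx]

  corrected <- NULL
  distortion_p <- NA_real_
  if (length(out_idx) && k - length(out_idx) >= 2L) {
    fit <- ivw_core(bx[-out_idx], sx[-out_idx], by[-out_idx], sy[-out_idx])
    corrected <- new_estimate("ivw_corrected", fit$beta, fit$se,
                              k - length(out_idx))
    full <- ivw_core(bx, sx, by, sy)
    d_obs <- (full$beta - fit$beta) / abs(fit$beta)
    keep_pool <- setdiff(seq_len(k), out_idx)
    n_draw <- min(n_sim, 1000L)
    d_null <- vapply(seq_len(n_draw), function(s) {
      drop_s <- sample(keep_pool, length(out_idx), replace = TRUE)
      idx <- setdiff(seq_len(k), drop_s)
      f <- ivw_core(bx[idx], sx[idx], by[idx], sy[idx])
      (full$beta - f$beta) / abs(f$beta)
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_draw + 1)
  }
  list(status = "ok", global_p = global_p, outliers = outliers,
       outlier_p = p_snp_adj[order(ord)], distortion_p = distortion_p,
       corrected_ivw = corrected)
}

#' Reverse-direction MR: outcome as exposure
#'
#' Applies the full forward machinery with the roles swapped (disorder GWAS
#' as exposure, imaging GWAS as outcome): instrument selection at
#' `p_threshold`, LD clumping, harmonization, then IVW (or the Wald ratio
#' with a single instrument). Absence of a reverse effect (IVW p > 0.05) is
#' evidence that the forward direction is valid.
#'
#' @param outcome_gwas The forward-analysis outcome [gwas_table()] (now the
#'   exposure).
#' @param exposure_gwas The forward-analysis exposure [gwas_table()] (now the
#'   outcome).
#' @param p_threshold Instrument threshold (default 5e-8).
#' @param ld Optional LD source for clumping.
#' @param r2_threshold Clumping threshold (default 0.001).
#' @return List with `status` (`"ok"` or `"not_testable"`), `estimate`
#'   (one-row estimate data frame or NULL), `p`, and `directionality_valid`
#'   (`TRUE` when reverse p > 0.05).
#' @export
reverse_mr <- function(outcome_gwas, exposure_gwas, p_threshold = 5e-8,
                       ld = NULL, r2_threshold = 0.001) {
  inst <- select_instruments(outcome_gwas, p_threshold = p_threshold,
                             ld = ld, r2_threshold = r2_threshold)
  if (length(inst) < 1L) {
    return(list(status = "not_testable", estimate = NULL, p = NA_real_,
                directionality_valid = NA))
  }
  rev_pair <- harmonize_pair(outcome_gwas, exposure_gwas, inst)
  k <- nrow(rev_pair$snps)
  if (k < 1L) {
    return(list(status = "not_testable", estimate = NULL, p = NA_real_,
                directionality_valid = NA))
  }
  est <- if (k >= 2L) mr_ivw(rev_pair) else wald_ratio(rev_pair)
  list(status = "ok", estimate = est, p = est$pvalue,
       directionality_valid = est$pvalue > 0.05)
}

#' Funnel-plot-ready table for a pair
#'
#' One row per instrument with its Wald ratio and precision (inverse
#' first-order ratio standard error), plus vertical reference values at the
#' IVW and (when estimable) Egger slopes, and a precision-weighted asymmetry
#' statistic (weighted third moment of ratios about the IVW estimate).
#'
#' @param pair A `harmonized_pair` with at least one instrument.
#' @return List with `data` (data frame `snp_id`, `ratio`, `precision`),
#'   `ivw_beta`, `egger_beta` (NA if k < 3), `asymmetry`.
#' @export
funnel_data <- function(pair) {
  d <- pair_snps(pair)
  if (nrow(d) < 1L) stop("funnel_data needs at least one instrument", call. = FALSE)
  ratio <- d$beta_out / d$beta_exp
  se_ratio <- d$se_out / abs(d$beta_exp)
  ivw_beta <- if (nrow(d) >= 2L) mr_ivw(pair)$beta else ratio[1]
  egger_beta <- if (nrow(d) >= 3L) mr_egger(pair)$slope$beta else NA_real_
  w <- 1 / se_ratio^2
  dev <- ratio - ivw_beta
  asym <- sum(w * dev^3) / sum(w) / (sum(w * dev^2) / sum(w))^1.5
  if (!is.finite(asym)) asym <- 0
  list(data = data.frame(snp_id = d$snp_id, ratio = ratio,
                         precision = 1 / se_ratio, stringsAsFactors = FALSE),
       ivw_beta = ivw_beta, egger_beta = egger_beta, asymmetry = asym)
}

#' Full sensitivity battery for one harmonized pair
#'
#' Bundles the modified Cochran Q, Rucker Q, Egger intercept, MR-PRESSO,
#' leave-one-out estimates, and (optionally) reverse MR into one report with
#' derived flags: `heterogeneous` (Cochran p < 0.05), `pleiotropic` (Egger
#' intercept p < 0.05), `bidirectional` (reverse MR p < 0.05).
#'
#' @param pair A `harmonized_pair`.
#' @param n_sim MR-PRESSO simulations (default 2500).
#' @param seed Integer seed for MR-PRESSO.
#' @param signif Outlier significance (default 0.05).
#' @param reverse Optional precomputed [reverse_mr()] result.
#' @return Object of class `mr_sensitivity`.
#' @export
mr_sensitivity <- function(pair, n_sim = 2500, seed = 1L, signif = 0.05,
                           reverse = NULL) {
  k <- nrow(pair$snps)
  cq <- cochran_q(pair)
  rq <- rucker_q(pair)
  egger_int <- if (k >= 3L) mr_egger(pair)$intercept else NULL
  presso <- mr_presso(pair, n_sim = n_sim, signif = signif, seed = seed)
  loo <- if (k >= 3L) leave_one_out(pair) else NULL
  rev_p <- if (!is.null(reverse)) reverse$p else NA_real_
  structure(
    list(pair = c(pair$exposure_id, pair$outcome_id), n_snp = k,
         cochran_q = cq$Q, cochran_df = cq$df, cochran_p = cq$p,
         rucker_q = rq$Q, rucker_p = rq$p,
         egger_intercept = if (!is.null(egger_int)) egger_int$beta else NA_real_,
         egger_intercept_p = if (!is.null(egger_int)) egger_int$pvalue else NA_real_,
         presso_global_p = presso$global_p, presso_outliers = presso$outliers,
         presso_distortion_p = presso$distortion_p,
         corrected_ivw = presso$corrected_ivw,
         loo_estimates = loo, reverse_mr_p = rev_p,
         flags = list(
           heterogeneous = isTRUE(cq$p < 0.05),
           pleiotropic = isTRUE(!is.null(egger_int) && egger_int$pvalue < 0.05),
           bidirectional = isTRUE(!is.na(rev_p) && rev_p < 0.05))),
    class = "mr_sensitivity"
  )
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity report: %s -> %s (%d SNPs)\n",
              x$pair[1], x$pair[2], x$n_snp))
  cat(sprintf("  Cochran Q = %.3f (df %s, p = %.3g)%s\n", x$cochran_q,
              format(x$cochran_df), x$cochran_p,
              if (isTRUE(x$flags$heterogeneous)) " [heterogeneous]" else ""))
  if (!is.na(x$rucker_p)) {
    cat(sprintf("  Rucker Q' = %.3f (p = %.3g)\n", x$rucker_q, x$rucker_p))
  }
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4f (p = %.3g)%s\n", x$egger_intercept,
                x$egger_intercept_p,
                if (isTRUE(x$flags$pleiotropic)) " [pleiotropic]" else ""))
  }
  if (!is.na(x$presso_global_p)) {
    cat(sprintf("  MR-PRESSO global p = %.3g; %d outlier(s)\n",
                x$presso_global_p, length(x$presso_outliers)))
  }
  if (!is.na(x$reverse_mr_p)) {
    cat(sprintf("  Reverse MR p = %.3g%s\n", x$reverse_mr_p,
                if (isTRUE(x$flags$bidirectional)) " [bidirectional]" else ""))
  }
  invisible(x)
}
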