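#' Fit two-sample Mendelian randomization models to a harmonized pair
#'
#' The central fitting function: given allele-harmonized per-SNP exposure and
#' outcome effects, estimates the causal effect by every applicable method
#' and returns a classed model object. With a single instrument the Wald
#' ratio (plus the SMR test) is the primary estimate; with two or more the
#' inverse-variance-weighted (IVW) estimate is primary; with three or more
#' the MR-Egger slope/intercept and the weighted median are added. The
#' weighted mode is available via `methods` but excluded from the default
#' profile.
#'
#' @param pair A `harmonized_pair` (see [harmonize_pair()],
#'   [new_harmonized_pair()]).
#' @param methods Character vector among `"ivw"`, `"egger"`,
#'   `"weighted_median"`, `"weighted_mode"`, `"wald_ratio"`, `"smr"`; the
#'   default picks all methods the instrument count admits (mode excluded).
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Integer seed for the bootstraps.
#' @param phi Weighted-mode bandwidth multiplier.
#' @param random_effects Logical; multiplicative random-effects IVW standard
#'   error (default) or fixed-effect.
#' @return Object of class `mr_fit`: list with `estimates` (one row per
#'   method: `method`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`,
#'   `n_snp`), `primary_method`, `pair`, and the call. Effects are on the
#'   outcome scale (log-odds for binary outcomes) per 1-SD exposure.
#' @examples
#' pair <- new_harmonized_pair(
#'   snp_id = paste0("rs", 1:5),
#'   beta_exp = c(0.08, 0.10, 0.12, 0.09, 0.11), se_exp = rep(0.01, 5),
#'   beta_out = c(0.04, 0.05, 0.06, 0.05, 0.05), se_out = rep(0.01, 5))
#' fit <- mr_fit(pair, seed = 1)
#' coef(fit)
#' @export
mr_fit <- function(pair, methods = NULL, n_boot = 1000, seed = 1L, phi = 1,
                   random_effects = TRUE) {
  stopifnot(inherits(pair, "harmonized_pair"))
  k <- nrow(pair$snps)
  if (k < 1L) stop("pair has no instruments", call. = FALSE)
  if (is.null(methods)) {
    methods <- if (k == 1L) c("wald_ratio", "smr")
    else if (k == 2L) "ivw"
    else c("ivw", "egger", "weighted_median")
  }
  rows <- list()
  for (m in methods) {
    rows[[m]] <- switch(
      m,
      wald_ratio = wald_ratio(pair),
      smr = smr_test(pair),
      ivw = mr_ivw(pair, random_effects = random_effects),
      egger = {
        e <- mr_egger(pair)
        rbind(e$slope, e$intercept)
      },
      weighted_median = mr_weighted_median(pair, n_boot = n_boot,
                                           seed = derive_seed(seed, 1L)),
      weighted_mode = mr_weighted_mode(pair, phi = phi, n_boot = n_boot,
                                       seed = derive_seed(seed, 2L)),
      stop("unknown method: ", m, call. = FALSE))
  }
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  structure(
    list(estimates = estimates,
         primary_method = if (k >= 2L) "ivw" else "wald_ratio",
         pair = pair, n_boot = n_boot, seed = seed,
         call = match.call()),
    class = "mr_fit"
  )
}

est_row <- function(fit, method) {
  e <- fit$estimates
  e[e$method == method, , drop = FALSE]
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %s -> %s (%d instrument SNPs)\n",
              x$pair$exposure_id, x$pair$outcome_id, nrow(x$pair$snps)))
  e <- x$estimates
  e$beta <- signif(e$beta, digits); e$se <- signif(e$se, digits)
  e$ci_low <- signif(e$ci_low, digits); e$ci_high <- signif(e$ci_high, digits)
  e$pvalue <- signif(e$pvalue, 3)
  print(e, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  e <- object$estimates
  if (!missing(parm)) e <- e[e$method %in% parm, , drop = FALSE]
  z <- stats::qnorm(1 - (1 - level) / 2) / stats::qnorm(0.975)
  ## rescale the stored 95% half-width for other levels
  half <- (e$ci_high - e$beta) * z
  out <- cbind(e$beta - half, e$beta + half)
  dimnames(out) <- list(e$method,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  out
}

#' Residuals of an MR fit
#'
#' Standardized residuals of the outcome effects about the fitted line of the
#' chosen method (through the origin for IVW and ratio methods, with
#' intercept for Egger), scaled by the outcome standard errors.
#'
#' @param object An `mr_fit`.
#' @param method Method whose fitted line to use; default the primary.
#' @param ... Unused.
#' @return Named numeric vector, one residual per instrument.
#' @export
residuals.mr_fit <- function(object, method = object$primary_method, ...) {
  d <- object$pair$snps
  f <- fitted_line(object, method)
  r <- (d$beta_out - (f$intercept + f$slope * d$beta_exp)) / d$se_out
  stats::setNames(r, d$snp_id)
}

fitted_line <- function(fit, method) {
  if (method == "egger") {
    list(slope = est_row(fit, "egger_slope")$beta,
         intercept = est_row(fit, "egger_intercept")$beta)
  } else {
    m <- if (method %in% fit$estimates$method) method else fit$primary_method
    list(slope = est_row(fit, m)$beta[1], intercept = 0)
  }
}

#' Predicted outcome effects from an MR fit
#'
#' @param object An `mr_fit`.
#' @param newdata Optional data frame with a `beta_exp` column; default the
#'   fitted pair.
#' @param method Method whose fitted line to use; default the primary.
#' @param ... Unused.
#' @return Numeric vector of predicted outcome effects.
#' @export
predict.mr_fit <- function(object, newdata = NULL,
                           method = object$primary_method, ...) {
  bx <- if (is.null(newdata)) object$pair$snps$beta_exp else newdata$beta_exp
  f <- fitted_line(object, method)
  f$intercept + f$slope * bx
}

#' Summary of an MR fit
#'
#' Adds the sensitivity headline numbers (modified Cochran Q, Rucker Q, Egger
#' intercept) and, for binary outcomes, odds-ratio conversions of every
#' causal estimate.
#'
#' @param object An `mr_fit`.
#' @param ... Unused.
#' @return Object of class `summary.mr_fit`.
#' @export
summary.mr_fit <- function(object, ...) {
  pair <- object$pair
  k <- nrow(pair$snps)
  cq <- if (k >= 2L) cochran_q(pair) else NULL
  rq <- if (k >= 3L) rucker_q(pair) else NULL
  e <- object$estimates
  or <- NULL
  if (identical(pair$outcome_type, "binary")) {
    causal <- e$method %in% c("ivw", "wald_ratio", "egger_slope",
                              "weighted_median", "weighted_mode", "smr")
    or_list <- lapply(which(causal), function(i) {
      o <- to_odds_ratio(e[i, , drop = FALSE])
      data.frame(method = e$method[i], odds_ratio = o$odds_ratio,
                 or_ci_low = o$or_ci_low, or_ci_high = o$or_ci_high,
                 percent_change = o$percent_change, stringsAsFactors = FALSE)
    })
    or <- do.call(rbind, or_list)
  }
  structure(list(fit = object, cochran = cq, rucker = rq, odds_ratios = or),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$cochran) && !is.na(x$cochran$Q)) {
    cat(sprintf("Cochran Q (modified) = %.3f on %d df, p = %.3g\n",
                x$cochran$Q, x$cochran$df, x$cochran$p))
  }
  if (!is.null(x$rucker) && !is.na(x$rucker$Q)) {
    cat(sprintf("Rucker Q' = %.3f on %d df, p = %.3g\n",
                x$rucker$Q, x$rucker$df, x$rucker$p))
  }
  if (!is.null(x$odds_ratios)) {
    cat("Odds ratios per 1-SD exposure:\n")
    o <- x$odds_ratios
    o$odds_ratio <- round(o$odds_ratio, 2)
    o$or_ci_low <- round(o$or_ci_low, 2)
    o$or_ci_high <- round(o$or_ci_high, 2)
    o$percent_change <- round(o$percent_change, 1)
    print(o, row.names = FALSE)
  }
  invisible(x)
}

#' Scatter plot of an MR fit
#'
#' Instrument outcome effects against exposure effects with one-standard-
#' error bars, the IVW line through the origin, and (when fitted) the Egger
#' line.
#'
#' @param x An `mr_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$pair$snps
  plot(d$beta_exp, d$beta_out,
       xlab = "SNP effect on exposure", ylab = "SNP effect on outcome",
       pch = 19, ...)
  graphics::segments(d$beta_exp, d$beta_out - d$se_out,
                     d$beta_exp, d$beta_out + d$se_out)
  graphics::segments(d$beta_exp - d$se_exp, d$beta_out,
                     d$beta_exp + d$se_exp, d$beta_out)
  if ("ivw" %in% x$estimates$method || x$primary_method == "wald_ratio") {
    graphics::abline(0, est_row(x, x$primary_method)$beta[1], col = "steelblue")
  }
  if ("egger_slope" %in% x$estimates$method) {
    graphics::abline(est_row(x, "egger_intercept")$beta,
                     est_row(x, "egger_slope")$beta,
                     col = "firebrick", lty = 2)
  }
  invisible(x)
}
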