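test_that("wald ratio arithmetic and degenerate cases", {
  p <- new_harmonized_pair("rs1", beta_exp = 0.1, se_exp = 0.02,
                           beta_out = 0.05, se_out = 0.01)
  w <- wald_ratio(p)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.1)
  p0 <- new_harmonized_pair("rs1", 0.1, 0.02, 0, 0.01)
  w0 <- wald_ratio(p0)
  expect_equal(w0$beta, 0)
  expect_equal(w0$pvalue, 1)
  pz <- new_harmonized_pair("rs1", 0, 0.02, 0.1, 0.01)
  expect_error(wald_ratio(pz), "undefined ratio")
})

test_that("single-SNP IVW degenerates to the Wald ratio", {
  for (s in 1:5) {
    pr <- random_pair(s, k = 1)
    w <- wald_ratio(pr)
    d <- pr$snps
    core <- mrflow:::ivw_core(d$beta_exp, d$se_exp, d$beta_out, d$se_out)
    expect_equal(core$beta, w$beta, tolerance = 1e-12)
    expect_equal(core$se, w$se, tolerance = 1e-12)
  }
})

test_that("IVW with identical ratios and equal weights returns the ratio", {
  p <- new_harmonized_pair(c("a", "b"), beta_exp = c(0.1, 0.1),
                           se_exp = c(0.01, 0.01),
                           beta_out = c(0.05, 0.05), se_out = c(0.01, 0.01))
  fit <- mr_ivw(p)
  expect_equal(fit$beta, 0.5)
  core <- mrflow:::ivw_core(p$snps$beta_exp, p$snps$se_exp,
                            p$snps$beta_out, p$snps$se_out)
  expect_equal(core$q, 0)
  ## no random-effects inflation when Q = 0
  expect_equal(fit$se, mr_ivw(p, random_effects = FALSE)$se)
})

test_that("IVW and Egger match the generic weighted-least-squares oracle", {
  for (s in 1:25) {
    pr <- random_pair(s, k = sample(4:12, 1))
    d <- pr$snps
    w <- 1 / d$se_out^2
    wls0 <- wls_oracle(d$beta_exp, d$beta_out, w, intercept = FALSE)
    expect_equal(mr_ivw(pr, random_effects = FALSE)$beta,
                 unname(coef(wls0)), tolerance = 1e-10)
    eg <- mr_egger(pr)
    bx_or <- abs(d$beta_exp)
    by_or <- d$beta_out * sign(d$beta_exp)
    wls1 <- wls_oracle(bx_or, by_or, w, intercept = TRUE)
    expect_equal(eg$slope$beta, unname(coef(wls1)[2]), tolerance = 1e-10)
    expect_equal(eg$intercept$beta, unname(coef(wls1)[1]), tolerance = 1e-10)
  }
})

test_that("exact linear data are recovered by Egger without error", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  a <- 0.01; b <- 0.4
  p <- new_harmonized_pair(paste0("s", 1:4), bx, rep(0.01, 4),
                           a + b * bx, rep(0.01, 4))
  eg <- mr_egger(p)
  expect_equal(eg$slope$beta, b, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, a, tolerance = 1e-10)
})

test_that("weighted median interpolates the 0.5 weight crossing", {
  p <- new_harmonized_pair(paste0("s", 1:3), rep(0.1, 3), rep(0.01, 3),
                           c(0.01, 0.05, 0.09), rep(0.01, 3))
  ## equal weights, ratios {0.1, 0.5, 0.9} -> middle element
  fit <- mr_weighted_median(p, n_boot = 100, seed = 1)
  expect_equal(fit$beta, 0.5)
  ## all ratios equal: estimate equals the common ratio, bootstrap se small
  pe <- new_harmonized_pair(paste0("s", 1:4), rep(0.1, 4), rep(1e-6, 4),
                            rep(0.03, 4), rep(1e-6, 4))
  fe <- mr_weighted_median(pe, n_boot = 200, seed = 1)
  expect_equal(fe$beta, 0.3, tolerance = 1e-3)
  expect_lt(fe$se, 1e-3)
})

test_that("weighted mode finds the dominant ratio cluster", {
  set.seed(4)
  bx <- rep(0.1, 10)
  ratios <- c(0.3 + stats::rnorm(7, 0, 0.01), 1.0 + stats::rnorm(3, 0, 0.01))
  p <- new_harmonized_pair(paste0("s", 1:10), bx, rep(0.005, 10),
                           ratios * bx, rep(0.005, 10))
  fit <- mr_weighted_mode(p, n_boot = 100, seed = 2)
  ## independent density-argmax oracle on a fine grid
  r <- p$snps$beta_out / p$snps$beta_exp
  w <- p$snps$beta_exp^2 / p$snps$se_out^2
  bw <- mrflow:::mode_bandwidth(r, 1)
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 20000)
  dens <- vapply(grid, function(g) {
    sum(w / sum(w) * stats::dnorm((g - r) / bw))
  }, numeric(1))
  expect_equal(fit$beta, grid[which.max(dens)], tolerance = 1e-3)
  expect_lt(abs(fit$beta - 0.3), 0.05)
  ## large-bandwidth limit approaches the weighted mean of ratios
  wmean <- sum(w * r) / sum(w)
  fit_wide <- mr_weighted_mode(p, phi = 1000, n_boot = 10, seed = 2)
  expect_lt(abs(fit_wide$beta - wmean), 0.05)
  expect_lt(abs(fit_wide$beta - wmean), abs(fit$beta - wmean))
})

test_that("SMR statistic follows its closed form and limits", {
  ## z_exp = z_out = 2 -> T = 16/8 = 2
  p <- new_harmonized_pair("rs1", beta_exp = 0.02, se_exp = 0.01,
                           beta_out = 0.02, se_out = 0.01)
  s <- smr_test(p)
  expect_equal(attr(s, "t_smr"), 2)
  ## very strong instrument: p tends to the outcome GWAS p
  p2 <- new_harmonized_pair("rs1", beta_exp = 1, se_exp = 1e-6,
                            beta_out = 0.03, se_out = 0.01)
  s2 <- smr_test(p2)
  expect_equal(s2$pvalue, p2$snps$p_out, tolerance = 1e-6)
})

test_that("HEIDI separates shared-signal from linkage alternatives", {
  ## perfect single causal signal: all companions share the top ratio
  k <- 8
  R <- simulate_ld(k, k, 0.5)
  bx <- seq(0.2, 0.34, length.out = k)
  p_same <- new_harmonized_pair(rownames(R), bx, rep(0.01, k),
                                0.4 * bx, rep(0.01, k))
  h <- heidi_test(p_same, R)
  expect_identical(h$status, "ok")
  expect_gt(h$p, 0.5)

  ## two distinct causal variants in LD: ratios disagree -> small p often
  rej <- vapply(1:10, function(s) {
    set.seed(s)
    bx2 <- stats::runif(k, 0.1, 0.3)
    by2 <- 0.4 * bx2
    by2[seq(2, k, by = 2)] <- -0.4 * bx2[seq(2, k, by = 2)]
    pr <- new_harmonized_pair(rownames(R), bx2 + stats::rnorm(k, 0, 0.005),
                              rep(0.005, k), by2 + stats::rnorm(k, 0, 0.005),
                              rep(0.005, k))
    heidi_test(pr, R)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.5)

  ## too few usable companions -> not evaluable, no p-value
  p_small <- new_harmonized_pair(rownames(R)[1:3], bx[1:3], rep(0.01, 3),
                                 0.4 * bx[1:3], rep(0.01, 3))
  h_small <- heidi_test(p_small, R[1:3, 1:3])
  expect_identical(h_small$status, "not_evaluable")
  expect_true(is.na(h_small$p))
})

test_that("odds-ratio conversion matches the headline transforms", {
  an <- new_estimate_or(-0.48, log(0.50), log(0.76))
  expect_equal(round(an$odds_ratio, 2), 0.62)
  expect_equal(round(an$or_ci_low, 2), 0.50)
  expect_equal(round(an$or_ci_high, 2), 0.76)
  ad <- new_estimate_or(0.07)
  expect_equal(round(ad$odds_ratio, 2), 1.07)
  scz <- new_estimate_or(log(0.48))
  expect_equal(round(scz$percent_change), -52)
  null <- new_estimate_or(0)
  expect_equal(null$odds_ratio, 1)
  expect_equal(null$percent_change, 0)
  est <- data.frame(beta = 0.1, ci_low = 0, ci_high = 0.2)
  expect_error(to_odds_ratio(est, outcome_type = "continuous"), "binary")
})

test_that("estimators are scale-equivariant and orientation-invariant", {
  for (s in 1:5) {
    pr <- random_pair(100 + s, k = 10)
    d <- pr$snps
    ## scale: multiply exposure betas and ses by c -> estimates divide by c
    cc <- 2.5
    pr_sc <- new_harmonized_pair(d$snp_id, d$beta_exp * cc, d$se_exp * cc,
                                 d$beta_out, d$se_out)
    expect_equal(mr_ivw(pr_sc)$beta, mr_ivw(pr)$beta / cc, tolerance = 1e-10)
    expect_equal(mr_egger(pr_sc)$slope$beta, mr_egger(pr)$slope$beta / cc,
                 tolerance = 1e-10)
    expect_equal(mr_weighted_median(pr_sc, 50, seed = 1)$beta,
                 mr_weighted_median(pr, 50, seed = 1)$beta / cc,
                 tolerance = 1e-10)
    ## orientation: flip a subset of SNPs' both betas
    set.seed(s)
    flip <- sample(c(-1, 1), 10, replace = TRUE)
    pr_fl <- new_harmonized_pair(d$snp_id, d$beta_exp * flip, d$se_exp,
                                 d$beta_out * flip, d$se_out)
    expect_equal(mr_ivw(pr_fl)$beta, mr_ivw(pr)$beta, tolerance = 1e-10)
    expect_equal(mr_egger(pr_fl)$slope$beta, mr_egger(pr)$slope$beta,
                 tolerance = 1e-10)
    expect_equal(mr_weighted_median(pr_fl, 50, seed = 1)$beta,
                 mr_weighted_median(pr, 50, seed = 1)$beta, tolerance = 1e-10)
  }
})

test_that("mr_fit assembles the right method profile and accessors work", {
  pr1 <- random_pair(11, k = 1)
  f1 <- mr_fit(pr1)
  expect_setequal(f1$estimates$method, c("wald_ratio", "smr"))
  expect_identical(f1$primary_method, "wald_ratio")

  pr <- quick_pair(21, k = 8, causal_beta = 0.2)
  expect_gte(nrow(pr$snps), 3)
  f <- mr_fit(pr, seed = 3)
  expect_setequal(f$estimates$method,
                  c("ivw", "egger_slope", "egger_intercept",
                    "weighted_median"))
  expect_identical(f$primary_method, "ivw")
  expect_named(coef(f))
  ci <- confint(f)
  expect_true(all(ci[, 1] <= coef(f) & coef(f) <= ci[, 2]))
  expect_length(residuals(f), nrow(pr$snps))
  expect_equal(predict(f), f$estimates$beta[1] * pr$snps$beta_exp)
  s <- summary(f)
  expect_s3_class(s, "summary.mr_fit")
  expect_true("odds_ratio" %in% names(s$odds_ratios))
  ## estimate invariants
  e <- f$estimates
  expect_true(all(e$ci_low <= e$beta & e$beta <= e$ci_high))
  expect_true(all(e$pvalue > 0 & e$pvalue <= 1))
})
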