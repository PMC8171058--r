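test_that("Cochran Q is zero for identical ratios", {
  p <- new_harmonized_pair(paste0("s", 1:4), rep(0.1, 4), rep(0.01, 4),
                           rep(0.05, 4), rep(0.01, 4))
  for (m in c("modified", "first_order")) {
    cq <- cochran_q(p, method = m)
    expect_equal(cq$Q, 0)
    expect_identical(cq$df, 3L)
    expect_equal(cq$p, 1)
  }
  single <- new_harmonized_pair("s1", 0.1, 0.01, 0.05, 0.01)
  expect_identical(cochran_q(single)$status, "not_evaluable")
})

test_that("Rucker Q vanishes on exact-line data and matches the WLS RSS", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  p_line <- new_harmonized_pair(paste0("s", 1:4), bx, rep(0.01, 4),
                                0.01 + 0.4 * bx, rep(0.01, 4))
  expect_equal(rucker_q(p_line)$Q, 0, tolerance = 1e-20)
  for (s in 1:10) {
    pr <- random_pair(200 + s, k = 7)
    d <- pr$snps
    w <- 1 / d$se_out^2
    wls <- wls_oracle(abs(d$beta_exp), d$beta_out * sign(d$beta_exp), w,
                      intercept = TRUE)
    rss <- sum(w * stats::residuals(wls)^2)
    expect_equal(rucker_q(pr)$Q, rss, tolerance = 1e-10)
  }
})

test_that("Q nests: Rucker Q' <= first-order Cochran Q, difference is the intercept term", {
  for (s in 1:10) {
    pr <- random_pair(300 + s, k = 9)
    q1 <- cochran_q(pr, method = "first_order")$Q
    q2 <- rucker_q(pr)$Q
    expect_lte(q2, q1 + 1e-10)
    ## Q - Q' equals the squared unscaled intercept t-statistic
    d <- pr$snps
    fit <- mrflow:::egger_core(d$beta_exp, d$se_exp, d$beta_out, d$se_out)
    se_a_unscaled <- fit$se_intercept /
      (if (fit$k > 2) sqrt(fit$q / (fit$k - 2)) else 1)
    expect_equal(q1 - q2, (fit$intercept / se_a_unscaled)^2,
                 tolerance = 1e-8)
  }
})

test_that("leave-one-out estimates behave like k-1 IVW fits", {
  p_id <- new_harmonized_pair(paste0("s", 1:5), rep(0.1, 5), rep(0.01, 5),
                              rep(0.05, 5), rep(0.01, 5))
  loo <- leave_one_out(p_id)
  expect_equal(loo$beta, rep(0.5, 5))
  pr <- random_pair(41, k = 3)
  loo3 <- leave_one_out(pr)
  for (i in 1:3) {
    d <- pr$snps[-i, ]
    two <- new_harmonized_pair(d$snp_id, d$beta_exp, d$se_exp, d$beta_out,
                               d$se_out)
    expect_equal(loo3$beta[i], mr_ivw(two)$beta, tolerance = 1e-12)
  }
})

test_that("MR-PRESSO flags an injected outlier and corrects the estimate", {
  flagged <- vapply(1:10, function(s) {
    pair <- quick_pair(seed = 700 + s, k = 10, causal_beta = 0.2)
    if (nrow(pair$snps) < 4) return(NA)
    d <- pair$snps
    ## shift one SNP's outcome effect by 10 ratio-se
    shift <- 10 * d$se_out[3] / abs(d$beta_exp[3]) * d$beta_exp[3]
    pair$snps$beta_out[3] <- pair$snps$beta_out[3] + shift
    pres <- mr_presso(pair, n_sim = 600, seed = 1)
    d$snp_id[3] %in% pres$outliers
  }, logical(1))
  expect_gte(mean(flagged, na.rm = TRUE), 0.9)

  ## clean data: corrected estimate absent (no outliers), global p not tiny
  pair <- quick_pair(seed = 55, k = 8, causal_beta = 0.2)
  pres <- mr_presso(pair, n_sim = 600, seed = 2)
  expect_identical(pres$status, "ok")
  expect_length(pres$outliers, 0)
  expect_null(pres$corrected_ivw)
  expect_gte(pres$global_p, 1 / 601)

  ## too few instruments -> not evaluable
  small <- random_pair(1, k = 3)
  expect_identical(mr_presso(small, 100, seed = 1)$status, "not_evaluable")
})

test_that("sensitivity diagnostics are invariant to SNP input order", {
  pair <- quick_pair(seed = 66, k = 8, causal_beta = 0.1)
  set.seed(9)
  perm <- sample(nrow(pair$snps))
  pair_perm <- pair
  pair_perm$snps <- pair$snps[perm, ]
  expect_equal(cochran_q(pair_perm)$Q, cochran_q(pair)$Q, tolerance = 1e-12)
  expect_equal(rucker_q(pair_perm)$Q, rucker_q(pair)$Q, tolerance = 1e-12)
  a <- mr_presso(pair, n_sim = 400, seed = 5)
  b <- mr_presso(pair_perm, n_sim = 400, seed = 5)
  expect_identical(a$global_p, b$global_p)
  expect_identical(a$outliers, b$outliers)
})

test_that("reverse MR is an involution and handles missing instruments", {
  sim <- simulate_pair(sim_config(n_snps = 40, n_instruments = 6,
                                  causal_beta = 0.3, seed = 12))
  ## swapping roles twice reproduces the forward IVW estimate
  fwd_inst <- select_instruments(sim$exposure)
  fwd <- mr_ivw(harmonize_pair(sim$exposure, sim$outcome, fwd_inst))
  double_swap <- reverse_mr(sim$exposure, sim$outcome)  # roles swapped twice
  expect_equal(double_swap$estimate$beta, fwd$beta, tolerance = 1e-12)
  ## a null outcome GWAS carries no strong instruments: not testable
  sim0 <- simulate_pair(sim_config(n_snps = 40, n_instruments = 6,
                                   causal_beta = 0, seed = 12))
  rev <- reverse_mr(sim0$outcome, sim0$exposure)
  expect_identical(rev$status, "not_testable")
  expect_true(is.na(rev$p))
})

test_that("funnel table is consistent with the IVW estimate", {
  pair <- quick_pair(seed = 91, k = 10, causal_beta = 0.2)
  f <- funnel_data(pair)
  w <- f$data$precision^2
  expect_equal(sum(w * f$data$ratio) / sum(w), f$ivw_beta, tolerance = 1e-10)
  expect_identical(nrow(f$data), nrow(pair$snps))
  single <- new_harmonized_pair("s1", 0.1, 0.01, 0.05, 0.01)
  expect_identical(nrow(funnel_data(single)$data), 1L)
  ## one-sided pleiotropy on uniformly oriented instruments skews the
  ## low-precision tail of the funnel upward
  asym <- vapply(1:10, function(s) {
    set.seed(850 + s)
    bx <- stats::runif(12, 0.05, 0.2)
    alpha <- abs(stats::rnorm(12, 0.03, 0.01))
    pp <- new_harmonized_pair(paste0("s", 1:12), bx, rep(0.005, 12),
                              alpha + stats::rnorm(12, 0, 0.002),
                              rep(0.005, 12))
    funnel_data(pp)$asymmetry
  }, numeric(1))
  expect_gt(mean(asym), 0.1)
})

test_that("the sensitivity wrapper assembles a coherent report", {
  pair <- quick_pair(seed = 14, k = 8, causal_beta = 0.2)
  k <- nrow(pair$snps)
  expect_gte(k, 4)
  rep <- mr_sensitivity(pair, n_sim = 400, seed = 4)
  expect_s3_class(rep, "mr_sensitivity")
  expect_identical(rep$cochran_df, k - 1L)
  expect_true(rep$presso_global_p > 0 && rep$presso_global_p <= 1)
  expect_identical(nrow(rep$loo_estimates), k)
  expect_type(rep$flags$heterogeneous, "logical")
})
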