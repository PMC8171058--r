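test_that("KS uniformity statistic behaves at the extremes", {
  allhalf <- ks_uniform(rep(0.5, 20))
  expect_equal(allhalf$statistic, 0.5)
  grid <- (1:1000) / 1001
  near_uniform <- ks_uniform(grid)
  expect_gt(near_uniform$p, 0.99)
  expect_identical(ks_uniform(c(0.1, 0.2))$status, "not_evaluable")
})

test_that("inflation lambda recovers its construction values", {
  grid <- (1:1000) / 1001
  lam <- inflation_lambda(grid)
  expect_equal(lam$lambda, 1, tolerance = 0.02)
  expect_true(lam$ci[1] <= lam$lambda && lam$lambda <= lam$ci[2])
  set.seed(11)
  x2 <- stats::rchisq(1000, df = 1) * 2
  lam2 <- inflation_lambda(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  expect_equal(lam2$lambda, 2, tolerance = 0.1)
  expect_identical(inflation_lambda(c(0.1, 0.5))$status, "not_evaluable")
})

test_that("lambda and KS agree on strong inflation constructions", {
  set.seed(21)
  x2 <- stats::rchisq(200, df = 1) * 2
  p <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  expect_lt(ks_uniform(p)$p, 0.05)
  expect_gt(inflation_lambda(p)$lambda, 1.5)
})

test_that("pooling rejects duplicate pairs and is order-invariant", {
  set.seed(3)
  p <- stats::runif(50)
  a <- pool_pvalues(p)
  b <- pool_pvalues(sample(p))
  expect_equal(a$lambda_hat, b$lambda_hat, tolerance = 1e-12)
  expect_equal(a$ks_p, b$ks_p, tolerance = 1e-12)
  expect_error(pool_pvalues(p, pair_ids = rep("x", 50)), "duplicate")
})

test_that("permutation p-values obey the add-one rule and detect signal", {
  ## strong causal signal in a batch of pairs: permutation lambda p at floor
  pairs <- lapply(1:20, function(s) {
    quick_pair(seed = 1200 + s, k = 6,
               causal_beta = if (s <= 6) 0.5 else 0)
  })
  res <- permutation_null(pairs, B = 200, seed = 7)
  expect_gte(res$permutation_p_lambda, 1 / 201)
  expect_lte(res$permutation_p_lambda, 5 / 201)
  ## pairs must have >= 2 instruments
  bad <- c(pairs[1:3], list(new_harmonized_pair("s", 0.1, 0.01, 0, 0.01)))
  expect_error(permutation_null(bad, B = 100, seed = 1), "at least two")
})

test_that("stratified reruns are no-ops when nothing is removed", {
  pairs <- lapply(1:8, function(s) quick_pair(seed = 1300 + s, k = 6))
  sens <- lapply(seq_along(pairs), function(i) {
    mr_sensitivity(pairs[[i]], n_sim = 300, seed = i)
  })
  base <- pool_pvalues(vapply(pairs, mrflow:::pair_primary_p, numeric(1)))
  het <- stratified_rerun(pairs, sens, "remove_heterogeneous")
  out <- stratified_rerun(pairs, sens, "remove_outlier_snps")
  n_het <- sum(vapply(sens, function(s) isTRUE(s$cochran_p < 0.05),
                      logical(1)))
  if (n_het == 0) expect_equal(het$lambda_hat, base$lambda_hat)
  n_out <- sum(vapply(sens, function(s) length(s$presso_outliers) > 0,
                      logical(1)))
  if (n_out == 0) expect_equal(out$lambda_hat, base$lambda_hat)
  ## removing heterogeneous null pairs moves lambda toward the causal value
  noisy <- lapply(1:6, function(s) {
    quick_pair(seed = 1400 + s, k = 6, causal_beta = 0,
               pleiotropy_mode = "balanced", pleiotropy_sd = 0.08)
  })
  strong <- lapply(1:6, function(s) {
    quick_pair(seed = 1450 + s, k = 6, causal_beta = 0.3)
  })
  mix <- c(noisy, strong)
  sens_mix <- lapply(seq_along(mix), function(i) {
    mr_sensitivity(mix[[i]], n_sim = 300, seed = i)
  })
  kept <- stratified_rerun(mix, sens_mix, "remove_heterogeneous")
  expect_lte(kept$n_pvalues, length(mix))
})

test_that("significance tiers and the rank-rank overlap table", {
  tiers <- classify_tiers(c(0.04, 6.4e-6, 0.2, 4e-4), n_exposures = 110,
                          n_pairs_total = 1320)
  expect_identical(as.character(tiers$tiers),
                   c("nominal", "study_wide", "NS", "single_disease"))
  expect_equal(unname(tiers$thresholds["study_wide"]), 0.05 / 1320)
  ## alternative tested-pair denominator is selectable
  alt <- classify_tiers(3.9e-5, n_exposures = 110, n_pairs_total = 1253)
  expect_identical(as.character(alt$tiers), "study_wide")
  set.seed(5)
  p_mr <- stats::runif(200)
  p_het <- stats::runif(200)
  ov <- classify_tiers(p_mr, 110, 1320, het_pvalues = p_het)
  rs <- rowSums(ov$overlap_prop)
  expect_true(all(abs(rs[rowSums(ov$overlap_counts) > 0] - 1) < 1e-12))
})

test_that("qq tables align observed and expected quantiles", {
  set.seed(2)
  p <- stats::runif(100)
  qt <- qq_table(p)
  expect_identical(nrow(qt), 100L)
  expect_equal(qt$observed, sort(-log10(p), decreasing = TRUE))
  expect_true(all(diff(qt$expected) <= 0))
})
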