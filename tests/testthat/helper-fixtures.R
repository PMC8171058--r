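## Harmonized pair through the study's own selection path: simulate a panel
## with an expected k significant instruments, select at p < 5e-8, harmonize.
quick_pair <- function(seed, k = 10, n_exp = 5e4, n_out = 5e4,
                       causal_beta = 0, n_snps = max(3 * k, 20), ...) {
  sim <- simulate_pair(sim_config(n_snps = n_snps, n_exp = n_exp,
                                  n_out = n_out, causal_beta = causal_beta,
                                  n_instruments = k, seed = seed, ...))
  harmonize_pair(sim$exposure, sim$outcome,
                 select_instruments(sim$exposure))
}

## Arbitrary random instance for oracle-equivalence checks (not tied to the
## generator's effect-size structure).
random_pair <- function(seed, k = 8) {
  set.seed(seed)
  new_harmonized_pair(
    snp_id = paste0("s", seq_len(k)),
    beta_exp = stats::runif(k, -0.2, 0.2),
    se_exp = stats::runif(k, 0.005, 0.05),
    beta_out = stats::rnorm(k, 0, 0.1),
    se_out = stats::runif(k, 0.005, 0.05))
}

## Weighted least squares via lm(): the independent oracle for IVW/Egger.
wls_oracle <- function(bx, by, w, intercept = FALSE) {
  df <- data.frame(bx = bx, by = by)
  fit <- if (intercept) stats::lm(by ~ bx, data = df, weights = w)
  else stats::lm(by ~ 0 + bx, data = df, weights = w)
  fit
}

## odds-ratio conversion of a bare (beta, ci) triple
new_estimate_or <- function(beta, ci_low = beta - 0.1, ci_high = beta + 0.1) {
  to_odds_ratio(data.frame(beta = beta, ci_low = ci_low, ci_high = ci_high))
}

make_tmp_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
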