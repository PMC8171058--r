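GW_THRESHOLD <- 5e-8

## Genome-wide significance z threshold.
gw_z <- function(p_threshold = GW_THRESHOLD) stats::qnorm(1 - p_threshold / 2)

## Scale of the large-effect mixture component, solved in closed form so a
## large-effect SNP reaches p < p_threshold with probability hit_prob:
## observed beta ~ N(0, sigma^2 + se^2), so P(|beta| > z_thr*se) = hit_prob
## gives sqrt(sigma^2 + se^2) = z_thr*se / qnorm(1 - hit_prob/2).
mixture_scale <- function(se, p_threshold = GW_THRESHOLD, hit_prob = 2 / 3) {
  ratio <- gw_z(p_threshold) / stats::qnorm(1 - hit_prob / 2)
  se * sqrt(ratio^2 - 1)
}

## Per-SNP hit probability and number of large-effect SNPs used so the
## expected count of genome-wide-significant SNPs equals the request.
MIX_HIT_PROB <- 2 / 3

#' Configuration for the synthetic GWAS generator
#'
#' Describes one exposure-outcome pair's generative model: per SNP j a minor
#' allele frequency is drawn uniformly in `maf_range`; true exposure effects
#' come from a two-component mixture — most SNPs are null, while a
#' large-effect component of `ceiling(1.5 * n_instruments)` SNPs draws
#' `gamma ~ N(0, sigma^2)` with `sigma` solved in closed form so each
#' large-effect SNP reaches genome-wide significance (p < 5e-8) with
#' probability 2/3, making the expected significant count equal
#' `n_instruments` and giving the significant set a realistic spectrum of
#' instrument strengths; the true outcome effect is
#' `causal_beta * gamma_j + alpha_j` plus optional outlier shifts, where the
#' pleiotropic effect `alpha_j` is zero (`none`), symmetric zero-mean normal
#' (`balanced`), mean-shifted normal (`directional`), or correlated with
#' `gamma_j` (`inside_violated`, violating the InSIDE assumption). Observed
#' effects add sampling noise with standard errors
#' `1/sqrt(2*MAF*(1-MAF)*N)` for a standardized continuous trait; binary
#' outcomes (log-odds scale) divide additionally by
#' `sqrt(case_fraction*(1-case_fraction))`. P-values are two-sided normal, so
#' the (beta, se, p) triple is internally consistent. The seed fully
#' determines the output.
#'
#' @param n_snps Number of SNPs.
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes.
#' @param causal_beta True causal effect of the exposure on the outcome.
#' @param n_instruments Requested (expected) number of genome-wide-
#'   significant instrument SNPs; `ceiling(1.5 * n_instruments)` SNPs carry
#'   large effects and must fit within `n_snps`.
#' @param pleiotropy_mode One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violated"`.
#' @param pleiotropy_sd Scale of the pleiotropic effects.
#' @param n_outliers Number of instrument SNPs given an extra outcome shift.
#' @param outlier_shift Shift added to those SNPs' true outcome effects.
#' @param maf_range Minor-allele-frequency range, within `(0, 0.5]`.
#' @param outcome_type `"binary"` (default) or `"continuous"`.
#' @param case_fraction Case proportion for binary outcomes.
#' @param ld_blocks Optional list `list(block_size =, within_r =)` giving a
#'   block-diagonal LD structure; marginal effects and sampling noise are
#'   correlated accordingly.
#' @param seed Mandatory integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 200L, n_exp = 17706L, n_out = 50000L,
                       causal_beta = 0, n_instruments = 10L,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violated"),
                       pleiotropy_sd = 0, n_outliers = 0L, outlier_shift = 0,
                       maf_range = c(0.05, 0.5),
                       outcome_type = c("binary", "continuous"),
                       case_fraction = 0.5, ld_blocks = NULL, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_snps >= 1, n_exp > 0, n_out > 0, n_instruments >= 0,
            ceiling(1.5 * n_instruments) <= n_snps,
            pleiotropy_sd >= 0, n_outliers >= 0,
            n_outliers <= n_instruments, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            case_fraction > 0, case_fraction < 1)
  structure(
    list(n_snps = as.integer(n_snps), n_exp = n_exp, n_out = n_out,
         causal_beta = causal_beta, n_instruments = as.integer(n_instruments),
         pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
         n_outliers = as.integer(n_outliers), outlier_shift = outlier_shift,
         maf_range = maf_range, outcome_type = outcome_type,
         case_fraction = case_fraction, ld_blocks = ld_blocks,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Block-diagonal LD correlation matrix
#'
#' Constant correlation `within_r` inside consecutive blocks of
#' `block_size` SNPs, zero between blocks. Positive semi-definite for
#' `|within_r| < 1` (equicorrelation blocks have smallest eigenvalue
#' `1 - within_r`).
#'
#' @param n_snps Number of SNPs (ids `rs1 ... rsN` as dimnames).
#' @param block_size SNPs per block.
#' @param within_r Within-block correlation, `|within_r| < 1`.
#' @return A correlation matrix with SNP-id dimnames.
#' @export
simulate_ld <- function(n_snps, block_size, within_r) {
  stopifnot(n_snps >= 1, block_size >= 1, abs(within_r) < 1)
  R <- diag(1, n_snps)
  start <- 1L
  while (start <= n_snps) {
    end <- min(start + block_size - 1L, n_snps)
    idx <- start:end
    R[idx, idx] <- within_r
    diag(R)[idx] <- 1
    start <- end + 1L
  }
  ids <- paste0("rs", seq_len(n_snps))
  dimnames(R) <- list(ids, ids)
  R
}

random_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), character(1))
  list(ea = ea, oa = unname(oa))
}

#' Simulate one exposure-outcome pair of GWAS summary tables
#'
#' Draws two-sample GWAS summary statistics under the generative model
#' described in [sim_config()], with known ground truth. The exposure and
#' outcome noise draws are independent (no sample overlap).
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` ([gwas_table()] objects) and
#'   `truth`: `causal_beta`, `gamma` (true exposure effects),
#'   `per_snp_pleiotropy`, `instrument_ids` (the designated large-effect
#'   SNPs; the analysed instrument set is whatever [select_instruments()]
#'   retains), `outlier_ids`, and the `config`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_snps
  ids <- paste0("rs", seq_len(n))
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  se_exp <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exp)
  kcf <- config$case_fraction * (1 - config$case_fraction)
  se_out <- 1 / sqrt(2 * maf * (1 - maf) * config$n_out)
  if (config$outcome_type == "binary") se_out <- se_out / sqrt(kcf)

  n_large <- ceiling(1.5 * config$n_instruments)
  inst <- if (n_large > 0) sort(sample.int(n, n_large)) else integer(0)
  gamma <- numeric(n)
  if (length(inst)) {
    gamma[inst] <- stats::rnorm(length(inst), 0,
                                mixture_scale(se_exp[inst],
                                              hit_prob = MIX_HIT_PROB))
  }

  alpha <- numeric(n)
  ps <- config$pleiotropy_sd
  if (ps > 0) {
    alpha <- switch(
      config$pleiotropy_mode,
      none = numeric(n),
      balanced = stats::rnorm(n, 0, ps),
      directional = stats::rnorm(n, ps, ps),
      inside_violated = {
        g_scale <- if (length(inst)) mean(abs(gamma[inst])) else 1
        0.7 * ps * gamma / g_scale + stats::rnorm(n, 0, ps * sqrt(1 - 0.49))
      })
  }
  big_gamma <- config$causal_beta * gamma + alpha
  ## outliers sit on the strongest large-effect SNPs so they are all but
  ## certain to survive instrument selection
  outlier_idx <- if (config$n_outliers > 0 && length(inst)) {
    inst[order(-abs(gamma[inst]))][seq_len(min(config$n_outliers,
                                               length(inst)))]
  } else integer(0)
  big_gamma[outlier_idx] <- big_gamma[outlier_idx] + config$outlier_shift

  if (!is.null(config$ld_blocks)) {
    R <- simulate_ld(n, config$ld_blocks$block_size, config$ld_blocks$within_r)
    L <- chol(R)
    gamma_m <- as.vector(R %*% gamma)
    big_gamma_m <- as.vector(R %*% big_gamma)
    z_exp <- as.vector(crossprod(L, stats::rnorm(n)))
    z_out <- as.vector(crossprod(L, stats::rnorm(n)))
  } else {
    gamma_m <- gamma
    big_gamma_m <- big_gamma
    z_exp <- stats::rnorm(n)
    z_out <- stats::rnorm(n)
  }
  beta_exp <- gamma_m + se_exp * z_exp
  beta_out <- big_gamma_m + se_out * z_out

  al <- random_alleles(n)
  chr <- rep("1", n)
  pos <- seq_len(n) * 1e5

  exposure <- gwas_table(
    data.frame(snp_id = ids, effect_allele = al$ea, other_allele = al$oa,
               beta = beta_exp, se = se_exp,
               pvalue = p_normal(beta_exp, se_exp), eaf = maf,
               n = config$n_exp, chr = chr, pos = pos,
               stringsAsFactors = FALSE),
    trait_id = "exposure", trait_type = "continuous")
  outcome <- gwas_table(
    data.frame(snp_id = ids, effect_allele = al$ea, other_allele = al$oa,
               beta = beta_out, se = se_out,
               pvalue = p_normal(beta_out, se_out), eaf = NA_real_,
               n = config$n_out, chr = chr, pos = pos,
               stringsAsFactors = FALSE),
    trait_id = "outcome", trait_type = config$outcome_type)
  list(exposure = exposure, outcome = outcome,
       truth = list(causal_beta = config$causal_beta, gamma = gamma,
                    per_snp_pleiotropy = alpha,
                    instrument_ids = ids[inst],
                    outlier_ids = ids[outlier_idx], config = config))
}

dti_labels <- function(n) {
  if (n %% 5L == 0L && n >= 5L) {
    params <- c("FA", "AxD", "MD", "MO", "RD")
    tracts <- sprintf("T%02d", seq_len(n %/% 5L))
    as.vector(t(outer(tracts, params, paste, sep = ".")))
  } else {
    sprintf("DTI%03d", seq_len(n))
  }
}

DISORDER_LABELS <- c("AD", "ADHD", "AN", "ANX", "ASD", "BP",
                     "INS", "MDD", "OCD", "PTSD", "SCZ", "TD")

#' Simulate a labelled study collection of exposure-outcome pairs
#'
#' Emulates the structure of an imaging-exposure MR scan: `n_dti` white-matter
#' exposures (labelled tract-by-parameter when `n_dti` is a multiple of 5,
#' five diffusion parameters per tract), `n_roi` volume exposures and
#' `n_disorders` binary disorder outcomes, enumerating every exposure-outcome
#' pair. Each exposure GWAS is simulated once (DTI sample size 17,706; ROI
#' 19,629); each disorder outcome GWAS covers all exposures' SNP panels with
#' log-uniform sample sizes between 9,725 and 1,331,010 and a case fraction
#' drawn in (0.2, 0.5). A stated fraction of pairs is causal (effect
#' `causal_beta`, random sign); the rest are null. A fraction of exposures is
#' generated with zero designated instruments (5% of DTI, 20% of ROI by
#' default, matching the discard rates such scans typically see) to exercise
#' the no-strong-instrument path; the remainder receive 1-8 designated
#' instruments.
#'
#' @param n_dti,n_roi,n_disorders Counts of exposures and outcomes.
#' @param fraction_causal Fraction of pairs with a true causal effect.
#' @param seed Mandatory integer seed.
#' @param causal_beta Magnitude of the causal effect for causal pairs
#'   (default 0.15 log-odds per SD).
#' @param n_snps_per_exposure SNP-panel size per exposure (default 60).
#' @param frac_no_instrument_dti,frac_no_instrument_roi Fractions of
#'   exposures simulated without any strong instrument.
#' @return Object of class `mr_study_collection`: named lists `exposures` and
#'   `outcomes` of [gwas_table()]s, `truth` (per-pair data frame with
#'   `exposure_id`, `outcome_id`, `exposure_class`, `causal_beta`),
#'   `exposure_meta`, `outcome_meta`, and `seed`.
#' @export
simulate_study_collection <- function(n_dti, n_roi, n_disorders,
                                      fraction_causal, seed,
                                      causal_beta = 0.15,
                                      n_snps_per_exposure = 60L,
                                      frac_no_instrument_dti = 0.05,
                                      frac_no_instrument_roi = 0.20) {
  stopifnot(n_dti >= 0, n_roi >= 0, n_dti + n_roi >= 1, n_disorders >= 1,
            fraction_causal >= 0, fraction_causal <= 1)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(derive_seed(seed, 0L))

  exp_ids <- c(if (n_dti > 0) dti_labels(n_dti),
               if (n_roi > 0) sprintf("ROI%03d", seq_len(n_roi)))
  exp_class <- c(rep("DTI", n_dti), rep("ROI", n_roi))
  n_exp_sample <- ifelse(exp_class == "DTI", 17706, 19629)
  frac0 <- ifelse(exp_class == "DTI", frac_no_instrument_dti,
                  frac_no_instrument_roi)
  no_inst <- stats::runif(length(exp_ids)) < frac0
  n_inst <- ifelse(no_inst, 0L, sample(1:8, length(exp_ids), replace = TRUE))

  out_ids <- if (n_disorders <= length(DISORDER_LABELS)) {
    DISORDER_LABELS[seq_len(n_disorders)]
  } else {
    c(DISORDER_LABELS, sprintf("D%02d", seq(13L, n_disorders)))
  }
  n_out_sample <- round(exp(stats::runif(n_disorders, log(9725),
                                         log(1331010))))
  case_fraction <- stats::runif(n_disorders, 0.2, 0.5)

  n_pairs <- length(exp_ids) * n_disorders
  truth <- expand.grid(exposure_id = exp_ids, outcome_id = out_ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$exposure_class <- exp_class[match(truth$exposure_id, exp_ids)]
  causal <- stats::runif(n_pairs) < fraction_causal
  truth$causal_beta <- ifelse(
    causal, causal_beta * sample(c(-1, 1), n_pairs, replace = TRUE), 0)

  exposures <- vector("list", length(exp_ids))
  names(exposures) <- exp_ids
  out_records <- rep(list(vector("list", length(exp_ids))), n_disorders)

  for (e in seq_along(exp_ids)) {
    base <- simulate_pair(sim_config(
      n_snps = n_snps_per_exposure, n_exp = n_exp_sample[e], n_out = 10000,
      causal_beta = 0, n_instruments = n_inst[e], seed = derive_seed(seed, e)))
    erec <- base$exposure$records
    erec$snp_id <- paste0(exp_ids[e], ":", erec$snp_id)
    exposures[[e]] <- gwas_table(erec, exp_ids[e], "continuous")
    gamma <- base$truth$gamma
    maf <- erec$eaf
    set.seed(derive_seed(seed, length(exp_ids) * 7L + e))
    for (d in seq_len(n_disorders)) {
      cb <- truth$causal_beta[truth$exposure_id == exp_ids[e] &
                                truth$outcome_id == out_ids[d]]
      kcf <- case_fraction[d] * (1 - case_fraction[d])
      se_o <- 1 / sqrt(2 * maf * (1 - maf) * n_out_sample[d] * kcf)
      beta_o <- cb * gamma + se_o * stats::rnorm(length(gamma))
      out_records[[d]][[e]] <- data.frame(
        snp_id = erec$snp_id, effect_allele = erec$effect_allele,
        other_allele = erec$other_allele, beta = beta_o, se = se_o,
        pvalue = p_normal(beta_o, se_o), eaf = NA_real_,
        n = n_out_sample[d], chr = erec$chr, pos = erec$pos,
        stringsAsFactors = FALSE)
    }
  }
  outcomes <- lapply(seq_len(n_disorders), function(d) {
    gwas_table(do.call(rbind, out_records[[d]]), out_ids[d], "binary")
  })
  names(outcomes) <- out_ids

  structure(
    list(exposures = exposures, outcomes = outcomes, truth = truth,
         exposure_meta = data.frame(
           exposure_id = exp_ids, exposure_class = exp_class,
           n_sample = n_exp_sample, n_designated_instruments = n_inst,
           stringsAsFactors = FALSE),
         outcome_meta = data.frame(
           outcome_id = out_ids, n_sample = n_out_sample,
           case_fraction = case_fraction, stringsAsFactors = FALSE),
         seed = seed),
    class = "mr_study_collection"
  )
}

#' @export
print.mr_study_collection <- function(x, ...) {
  cat(sprintf("Synthetic MR study collection: %d exposure(s) x %d disorder(s) = %d candidate pair(s)\n",
              length(x$exposures), length(x$outcomes), nrow(x$truth)))
  cat(sprintf("  %d causal pair(s); seed %d\n",
              sum(x$truth$causal_beta != 0), x$seed))
  invisible(x)
}

#' Write a study collection to disk
#'
#' Emits every exposure and outcome table in the same TSV format
#' [read_gwas_table()] ingests (identity column map), the per-pair truth
#' table, and the study metadata in DCF format.
#'
#' @param collection An [simulate_study_collection()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "mr_study_collection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(collection$exposures)) {
    write_gwas_table(collection$exposures[[nm]],
                     file.path(dir, paste0("exposure_", nm, ".tsv")))
  }
  for (nm in names(collection$outcomes)) {
    write_gwas_table(collection$outcomes[[nm]],
                     file.path(dir, paste0("outcome_", nm, ".tsv")))
  }
  utils::write.table(collection$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(seed = collection$seed,
                     n_exposures = length(collection$exposures),
                     n_outcomes = length(collection$outcomes))
  write.dcf(meta, file.path(dir, "collection.dcf"))
  invisible(dir)
}
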