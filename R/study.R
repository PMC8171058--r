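#' Run the full MR study over a collection
#'
#' Orchestrates, for every enumerated exposure-outcome pair: instrument
#' selection (p-value threshold plus greedy LD clumping), harmonization, MR
#' estimation (IVW primary with two or more instruments, Wald ratio with
#' one; Egger and weighted median added with three or more), the sensitivity
#' battery (modified Cochran Q, Rucker Q, Egger intercept, MR-PRESSO),
#' reverse MR, instrument-strength/power columns, then pools p-values
#' overall, per disease, and after heterogeneity/outlier removal, and
#' assigns significance tiers. Pairs without a strong instrument are kept as
#' excluded rows with a reason code; a failure in one pair never aborts the
#' study. Fully deterministic under a fixed seed.
#'
#' @param collection An [simulate_study_collection()] result, or any list
#'   with the same `exposures` / `outcomes` / `exposure_meta` /
#'   `outcome_meta` / `truth` shape built from real tables.
#' @param p_threshold Instrument p-value threshold (default 5e-8).
#' @param r2_threshold LD clumping threshold (default 0.001).
#' @param ld Optional LD source (see [ld_lookup()]).
#' @param presso_n_sim MR-PRESSO simulations per pair (2500 by default;
#'   reduce for quick runs).
#' @param n_boot Bootstrap replicates for the weighted median (default 500).
#' @param seed Global integer seed; per-pair seeds are derived by
#'   [derive_seed()].
#' @param reverse Logical; run reverse MR per pair (default TRUE).
#' @param pool `"ivw_and_wald"` (default: both primary methods contribute to
#'   pooling) or `"ivw_only"`.
#' @param sw_denominator `"enumerated"` (default: all candidate pairs) or
#'   `"tested"` (pairs with at least one instrument) for the study-wide
#'   Bonferroni denominator.
#' @return Object of class `mr_study`: `pairs` (one row per enumerated
#'   pair), `pooled` (overall, per-disease and stratified `mr_pooled`
#'   results per exposure class), `tiers`, `counts`, `harmonized` (the
#'   harmonized pairs, for reporting), `sensitivities`, and the
#'   configuration.
#' @export
run_study <- function(collection, p_threshold = 5e-8, r2_threshold = 0.001,
                      ld = NULL, presso_n_sim = 2500, n_boot = 500,
                      seed = 1L, reverse = TRUE,
                      pool = c("ivw_and_wald", "ivw_only"),
                      sw_denominator = c("enumerated", "tested")) {
  pool <- match.arg(pool)
  sw_denominator <- match.arg(sw_denominator)
  truth <- collection$truth
  n_pairs <- nrow(truth)
  inst_cache <- new.env(parent = emptyenv())
  rows <- vector("list", n_pairs)
  harmonized <- vector("list", n_pairs)
  sensitivities <- vector("list", n_pairs)

  for (i in seq_len(n_pairs)) {
    eid <- truth$exposure_id[i]
    oid <- truth$outcome_id[i]
    exposure <- collection$exposures[[eid]]
    outcome <- collection$outcomes[[oid]]
    emeta <- collection$exposure_meta[
      collection$exposure_meta$exposure_id == eid, ]
    ometa <- collection$outcome_meta[
      collection$outcome_meta$outcome_id == oid, ]
    row <- data.frame(
      exposure_id = eid, outcome_id = oid,
      exposure_class = truth$exposure_class[i] %||% NA_character_,
      status = "ok", n_instruments = 0L, primary_method = NA_character_,
      beta = NA_real_, se = NA_real_, pvalue = NA_real_,
      or_point = NA_real_,
      ivw_beta = NA_real_, ivw_p = NA_real_,
      wald_beta = NA_real_, wald_p = NA_real_, smr_p = NA_real_,
      egger_beta = NA_real_, egger_p = NA_real_,
      egger_intercept = NA_real_, egger_intercept_p = NA_real_,
      wmedian_beta = NA_real_, wmedian_p = NA_real_,
      cochran_q = NA_real_, cochran_p = NA_real_,
      rucker_q = NA_real_, rucker_p = NA_real_,
      presso_global_p = NA_real_, presso_n_outliers = NA_integer_,
      reverse_p = NA_real_, r2_total = NA_real_, f_min = NA_real_,
      power = NA_real_, stringsAsFactors = FALSE)

    res <- tryCatch({
      if (!exists(eid, envir = inst_cache)) {
        assign(eid, select_instruments(exposure, p_threshold = p_threshold,
                                       ld = ld,
                                       r2_threshold = r2_threshold),
               envir = inst_cache)
      }
      inst <- get(eid, envir = inst_cache)
      if (length(inst) == 0L) {
        row$status <- "no_strong_instrument"
        list(row = row, pair = NULL, sens = NULL)
      } else {
        pair <- harmonize_pair(exposure, outcome, inst)
        k <- nrow(pair$snps)
        if (k == 0L) {
          row$status <- "no_snps_after_harmonization"
          list(row = row, pair = pair, sens = NULL)
        } else {
          pair_seed <- derive_seed(seed, i)
          fit <- mr_fit(pair, n_boot = n_boot, seed = pair_seed)
          row$n_instruments <- k
          row$primary_method <- fit$primary_method
          prim <- est_row(fit, fit$primary_method)
          row$beta <- prim$beta; row$se <- prim$se; row$pvalue <- prim$pvalue
          row$or_point <- exp(prim$beta)
          for (m in c("ivw", "wald_ratio", "smr", "egger_slope",
                      "egger_intercept", "weighted_median")) {
            er <- est_row(fit, m)
            if (nrow(er) == 0L) next
            switch(m,
                   ivw = { row$ivw_beta <- er$beta; row$ivw_p <- er$pvalue },
                   wald_ratio = { row$wald_beta <- er$beta
                                  row$wald_p <- er$pvalue },
                   smr = { row$smr_p <- er$pvalue },
                   egger_slope = { row$egger_beta <- er$beta
                                   row$egger_p <- er$pvalue },
                   egger_intercept = { row$egger_intercept <- er$beta
                                       row$egger_intercept_p <- er$pvalue },
                   weighted_median = { row$wmedian_beta <- er$beta
                                       row$wmedian_p <- er$pvalue })
          }
          rev_res <- if (reverse) {
            reverse_mr(outcome, exposure, p_threshold = p_threshold, ld = ld,
                       r2_threshold = r2_threshold)
          } else NULL
          sens <- mr_sensitivity(pair, n_sim = presso_n_sim,
                                 seed = derive_seed(pair_seed, 3L),
                                 reverse = rev_res)
          row$cochran_q <- sens$cochran_q; row$cochran_p <- sens$cochran_p
          row$rucker_q <- sens$rucker_q; row$rucker_p <- sens$rucker_p
          row$presso_global_p <- sens$presso_global_p
          row$presso_n_outliers <- length(sens$presso_outliers)
          row$reverse_p <- sens$reverse_mr_p
          pw <- mr_power(pair, n_exposure = emeta$n_sample[1],
                         n_outcome = ometa$n_sample[1],
                         case_fraction = ometa$case_fraction[1],
                         eaf = exposure$records$eaf[
                           match(pair$snps$snp_id, exposure$records$snp_id)])
          row$r2_total <- pw$r2_total; row$f_min <- pw$f_min
          row$power <- pw$power
          list(row = row, pair = pair, sens = sens)
        }
      }
    }, error = function(e) {
      row$status <- paste0("error: ", conditionMessage(e))
      list(row = row, pair = NULL, sens = NULL)
    })
    rows[[i]] <- res$row
    harmonized[[i]] <- res$pair
    sensitivities[[i]] <- res$sens
  }
  pairs_df <- do.call(rbind, rows)
  rownames(pairs_df) <- NULL

  analyzed <- pairs_df$status == "ok"
  pairs_df$tier <- NA_character_
  pvec <- if (pool == "ivw_only") pairs_df$ivw_p else pairs_df$pvalue
  pooled <- list()
  tiers <- list()
  classes <- unique(pairs_df$exposure_class)
  classes <- classes[!is.na(classes)]
  for (cl in classes) {
    in_cl <- pairs_df$exposure_class == cl
    use <- in_cl & analyzed & !is.na(pvec)
    ids <- paste(pairs_df$exposure_id, pairs_df$outcome_id)[use]
    pooled[[cl]] <- list(overall = pool_pvalues(pvec[use], stratum = cl,
                                                pair_ids = ids))
    for (d in unique(pairs_df$outcome_id[in_cl])) {
      sel <- use & pairs_df$outcome_id == d
      pooled[[cl]][[paste0("disease_", d)]] <-
        pool_pvalues(pvec[sel], stratum = paste(cl, d))
    }
    idx <- which(in_cl & analyzed)
    pooled[[cl]]$heterogeneity_removed <- stratified_rerun(
      harmonized[idx], sensitivities[idx], "remove_heterogeneous",
      stratum = paste(cl, "heterogeneity-removed"))
    pooled[[cl]]$outliers_removed <- stratified_rerun(
      harmonized[idx], sensitivities[idx], "remove_outlier_snps",
      stratum = paste(cl, "outliers-removed"))

    n_expo <- length(unique(pairs_df$exposure_id[in_cl]))
    n_total <- if (sw_denominator == "enumerated") sum(in_cl) else
      sum(in_cl & analyzed)
    tiers[[cl]] <- classify_tiers(
      ifelse(analyzed[in_cl], pairs_df$pvalue[in_cl], NA_real_),
      n_exposures = n_expo, n_pairs_total = n_total,
      het_pvalues = pairs_df$cochran_p[in_cl])
    pairs_df$tier[in_cl] <- as.character(tiers[[cl]]$tiers)
  }

  structure(
    list(pairs = pairs_df, pooled = pooled, tiers = tiers,
         counts = c(enumerated = n_pairs, analyzed = sum(analyzed),
                    excluded = sum(!analyzed)),
         harmonized = harmonized, sensitivities = sensitivities,
         config = list(p_threshold = p_threshold,
                       r2_threshold = r2_threshold,
                       presso_n_sim = presso_n_sim, n_boot = n_boot,
                       seed = seed, pool = pool,
                       sw_denominator = sw_denominator)),
    class = "mr_study"
  )
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf("MR study: %d pair(s) enumerated, %d analyzed, %d excluded\n",
              x$counts["enumerated"], x$counts["analyzed"],
              x$counts["excluded"]))
  for (cl in names(x$pooled)) {
    print(x$pooled[[cl]]$overall)
  }
  invisible(x)
}

#' Forest-, funnel- and leave-one-out tables for top findings
#'
#' For every analyzed pair at or above the requested tier: a forest table
#' with one Wald-ratio row per SNP plus the IVW meta-analysis row (k + 1
#' rows) and the Egger slope as a reference value; a leave-one-out table;
#' and a funnel table. Odds-ratio columns are the row-wise exponentials of
#' the beta columns.
#'
#' @param study An [run_study()] result.
#' @param tier Minimum tier (default `"single_disease"`).
#' @return Named list (one element per top pair) of lists with `forest`,
#'   `leave_one_out`, `funnel`, `egger_beta`.
#' @export
report_top_findings <- function(study, tier = "single_disease") {
  stopifnot(inherits(study, "mr_study"))
  tier_rank <- match(tier, TIER_LEVELS)
  sel <- which(study$pairs$status == "ok" &
                 match(study$pairs$tier, TIER_LEVELS) >= tier_rank)
  out <- list()
  for (i in sel) {
    pair <- study$harmonized[[i]]
    k <- nrow(pair$snps)
    wald_rows <- do.call(rbind, lapply(seq_len(k), function(j) {
      w <- wald_ratio(pair, i = j)
      data.frame(label = pair$snps$snp_id[j], method = "wald_ratio",
                 beta = w$beta, ci_low = w$ci_low, ci_high = w$ci_high,
                 pvalue = w$pvalue, stringsAsFactors = FALSE)
    }))
    meta <- if (k >= 2L) mr_ivw(pair) else wald_ratio(pair)
    forest <- rbind(wald_rows,
                    data.frame(label = "IVW meta-analysis",
                               method = meta$method, beta = meta$beta,
                               ci_low = meta$ci_low, ci_high = meta$ci_high,
                               pvalue = meta$pvalue, stringsAsFactors = FALSE))
    forest$odds_ratio <- exp(forest$beta)
    forest$or_ci_low <- exp(forest$ci_low)
    forest$or_ci_high <- exp(forest$ci_high)
    nm <- paste(pair$exposure_id, pair$outcome_id, sep = "-")
    out[[nm]] <- list(
      forest = forest,
      leave_one_out = if (k >= 3L) leave_one_out(pair) else NULL,
      funnel = funnel_data(pair),
      egger_beta = if (k >= 3L) mr_egger(pair)$slope$beta else NA_real_)
  }
  out
}

#' Write study result tables
#'
#' Emits the per-pair results (`pairs.tsv`), a disease-by-class inflation
#' table (`pooled.tsv`: lambda, CI bounds, KS p per disease and exposure
#' class), QQ-plot-ready tables per class (`qq_<class>.tsv`), and a DCF
#' manifest with the configuration. Output is byte-identical across runs
#' with the same seed.
#'
#' @param study An [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(study, dir) {
  stopifnot(inherits(study, "mr_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(study$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pooled_rows <- list()
  for (cl in names(study$pooled)) {
    for (nm in names(study$pooled[[cl]])) {
      p <- study$pooled[[cl]][[nm]]
      pooled_rows[[paste(cl, nm)]] <- data.frame(
        exposure_class = cl, stratum = nm, lambda = p$lambda_hat,
        lambda_ci_low = p$lambda_ci[1], lambda_ci_high = p$lambda_ci[2],
        ks_p = p$ks_p, n_pvalues = p$n_pvalues, stringsAsFactors = FALSE)
    }
    analyzed <- study$pairs$status == "ok" &
      study$pairs$exposure_class == cl
    utils::write.table(qq_table(study$pairs$pvalue[analyzed], stratum = cl),
                       file.path(dir, paste0("qq_", cl, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(do.call(rbind, pooled_rows),
                     file.path(dir, "pooled.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- study$config
  write.dcf(data.frame(seed = cfg$seed, p_threshold = cfg$p_threshold,
                       r2_threshold = cfg$r2_threshold,
                       presso_n_sim = cfg$presso_n_sim,
                       n_boot = cfg$n_boot, pool = cfg$pool,
                       sw_denominator = cfg$sw_denominator),
            file.path(dir, "manifest.dcf"))
  invisible(dir)
}
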