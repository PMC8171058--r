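STRAND_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) STRAND_COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome associations for a set of instruments
#'
#' Aligns each instrument's outcome association to the exposure's effect
#' allele. If the outcome record lists the same allele pair it is kept as-is;
#' if effect and other alleles are swapped the outcome beta is negated; if the
#' alleles match only after strand complement, the complement is applied first
#' and the same logic follows. Palindromic SNPs (A/T or C/G) are kept under a
#' forward-strand assumption and counted, not dropped — appropriate when most
#' input GWAS lack allele frequencies that would allow a frequency check.
#' Instruments missing from the outcome table, or with irreconcilable allele
#' pairs, are dropped and counted.
#'
#' @param exposure,outcome [gwas_table()] objects.
#' @param instruments Character vector of instrument SNP ids drawn from the
#'   exposure table (e.g. from [select_instruments()]).
#' @return An object of class `harmonized_pair`: list with `exposure_id`,
#'   `outcome_id`, `outcome_type`, `snps` (data frame with `snp_id`,
#'   `beta_exp`, `se_exp`, `p_exp`, `beta_out`, `se_out`, `p_out`),
#'   `n_dropped_mismatch`, `n_missing_outcome`, `palindromic_kept`. The `snps`
#'   table may be empty, in which case the pair is excluded downstream.
#' @export
harmonize_pair <- function(exposure, outcome, instruments) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  ex <- exposure$records
  ou <- outcome$records
  instruments <- unique(as.character(instruments))
  missing_exp <- setdiff(instruments, ex$snp_id)
  if (length(missing_exp)) {
    stop("instrument(s) absent from the exposure table: ",
         paste(utils::head(missing_exp, 3), collapse = ", "), call. = FALSE)
  }
  ie <- match(instruments, ex$snp_id)
  io <- match(instruments, ou$snp_id)
  present <- !is.na(io)
  n_missing_outcome <- sum(!present)
  ie <- ie[present]; io <- io[present]

  ea_x <- ex$effect_allele[ie]; oa_x <- ex$other_allele[ie]
  ea_y <- ou$effect_allele[io]; oa_y <- ou$other_allele[io]
  beta_out <- ou$beta[io]

  direct  <- ea_y == ea_x & oa_y == oa_x
  swapped <- ea_y == oa_x & oa_y == ea_x
  cea <- unname(STRAND_COMPLEMENT[ea_y]); coa <- unname(STRAND_COMPLEMENT[oa_y])
  flip_direct  <- !direct & !swapped & cea == ea_x & coa == oa_x
  flip_swapped <- !direct & !swapped & cea == oa_x & coa == ea_x

  keep <- direct | swapped | flip_direct | flip_swapped
  sign_flip <- swapped | flip_swapped
  beta_out[sign_flip] <- -beta_out[sign_flip]
  palin <- is_palindromic(ea_x, oa_x) & keep

  snps <- data.frame(
    snp_id = ex$snp_id[ie][keep],
    beta_exp = ex$beta[ie][keep],
    se_exp = ex$se[ie][keep],
    p_exp = ex$pvalue[ie][keep],
    beta_out = beta_out[keep],
    se_out = ou$se[io][keep],
    p_out = ou$pvalue[io][keep],
    stringsAsFactors = FALSE
  )
  rownames(snps) <- NULL
  structure(
    list(exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
         outcome_type = outcome$trait_type, snps = snps,
         n_dropped_mismatch = sum(!keep), n_missing_outcome = n_missing_outcome,
         palindromic_kept = sum(palin)),
    class = "harmonized_pair"
  )
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("Harmonized pair: %s -> %s\n", x$exposure_id, x$outcome_id))
  cat(sprintf("  %d instrument SNP(s); %d allele mismatch(es) dropped; %d missing from outcome; %d palindromic kept\n",
              nrow(x$snps), x$n_dropped_mismatch, x$n_missing_outcome,
              x$palindromic_kept))
  invisible(x)
}

#' Write a harmonized pair as TSV
#'
#' One row per instrument with the six per-SNP fields plus the outcome
#' p-value, prefixed by exposure and outcome ids.
#'
#' @param x A [harmonize_pair()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized_pair <- function(x, path) {
  stopifnot(inherits(x, "harmonized_pair"))
  out <- cbind(exposure_id = x$exposure_id, outcome_id = x$outcome_id, x$snps)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a harmonized pair from already-aligned effect vectors
#'
#' Convenience constructor for data whose outcome effects are already
#' expressed on the exposure's effect allele (the simulator uses it, and it is
#' handy for toy examples); skips all allele bookkeeping.
#'
#' @param snp_id SNP identifiers.
#' @param beta_exp,se_exp Exposure effects and standard errors.
#' @param beta_out,se_out Outcome effects and standard errors.
#' @param p_exp,p_out P-values; default two-sided normal from beta/se.
#' @param exposure_id,outcome_id Trait labels.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @return A `harmonized_pair`, as from [harmonize_pair()].
#' @export
new_harmonized_pair <- function(snp_id, beta_exp, se_exp, beta_out, se_out,
                                p_exp = p_normal(beta_exp, se_exp),
                                p_out = p_normal(beta_out, se_out),
                                exposure_id = "exposure",
                                outcome_id = "outcome",
                                outcome_type = "binary") {
  stopifnot(all(se_exp > 0), all(se_out > 0))
  structure(
    list(exposure_id = exposure_id, outcome_id = outcome_id,
         outcome_type = outcome_type,
         snps = data.frame(snp_id = as.character(snp_id),
                           beta_exp = beta_exp, se_exp = se_exp,
                           p_exp = p_exp, beta_out = beta_out,
                           se_out = se_out, p_out = p_out,
                           stringsAsFactors = FALSE),
         n_dropped_mismatch = 0L, n_missing_outcome = 0L,
         palindromic_kept = 0L),
    class = "harmonized_pair"
  )
}
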