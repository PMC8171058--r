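#' Construct a GWAS summary-statistic table
#'
#' A `gwas_table` holds one trait's per-SNP summary associations: identifier,
#' effect/other allele, effect size (log-odds for binary traits), standard
#' error, p-value, and optionally effect-allele frequency, sample size and
#' position. Rows violating basic validity (non-positive or missing `se`,
#' p-value outside `(0, 1]` after flooring, identical alleles, alleles outside
#' A/C/G/T) are dropped and counted; duplicate `snp_id` rows keep the smallest
#' p-value.
#'
#' @param records A data frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`, and optionally `eaf`, `n`,
#'   `chr`, `pos`.
#' @param trait_id Character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`. Binary traits are expected
#'   to carry `beta` on the log-odds scale (see [read_gwas_table()]).
#' @return An object of class `gwas_table`: a list with elements `trait_id`,
#'   `trait_type`, `records` (validated data frame) and `n_dropped`.
#' @seealso [read_gwas_table()], [select_instruments()], [harmonize_pair()]
#' @export
gwas_table <- function(records, trait_id, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  needed <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pvalue")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- records
  rec$snp_id <- as.character(rec$snp_id)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  rec$beta <- as.numeric(rec$beta)
  rec$se <- as.numeric(rec$se)
  rec$pvalue <- floor_p(as.numeric(rec$pvalue))
  if (is.null(rec$eaf)) rec$eaf <- NA_real_
  if (is.null(rec$n)) rec$n <- NA_real_

  ok <- !is.na(rec$snp_id) & nzchar(rec$snp_id) &
    rec$effect_allele %in% c("A", "C", "G", "T") &
    rec$other_allele %in% c("A", "C", "G", "T") &
    rec$effect_allele != rec$other_allele &
    !is.na(rec$beta) & is.finite(rec$beta) &
    !is.na(rec$se) & rec$se > 0 &
    !is.na(rec$pvalue) & rec$pvalue > 0 & rec$pvalue <= 1
  ok <- ok & (is.na(rec$eaf) | (rec$eaf > 0 & rec$eaf < 1))
  n_dropped <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]

  if (anyDuplicated(rec$snp_id)) {
    o <- order(rec$pvalue)
    rec <- rec[o, , drop = FALSE]
    dup <- duplicated(rec$snp_id)
    n_dropped <- n_dropped + sum(dup)
    rec <- rec[!dup, , drop = FALSE]
  }
  rownames(rec) <- NULL
  structure(
    list(trait_id = as.character(trait_id), trait_type = trait_type,
         records = rec, n_dropped = n_dropped),
    class = "gwas_table"
  )
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("GWAS summary table: %s (%s)\n", x$trait_id, x$trait_type))
  cat(sprintf("  %d SNPs (%d rows dropped at ingestion)\n",
              nrow(x$records), x$n_dropped))
  invisible(x)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited file with a header, maps its columns onto
#' the canonical fields, log-transforms odds ratios when the effect column is
#' declared as an OR, and validates rows (see [gwas_table()]).
#'
#' @param path Path to the delimited file; the delimiter is sniffed from the
#'   header line (tab wins over comma).
#' @param column_map Named character vector or list mapping canonical names
#'   (`snp_id`, `effect_allele`, `other_allele`, `effect`, `se`, `pvalue`, and
#'   optionally `eaf`, `n`, `chr`, `pos`) to column names in the file.
#' @param trait_id Trait identifier; defaults to the file name.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param effect_is_or Logical; if `TRUE` the effect column holds odds ratios,
#'   which are log-transformed to betas at ingestion.
#' @return A [gwas_table()].
#' @export
read_gwas_table <- function(path, column_map, trait_id = NULL,
                            trait_type = c("continuous", "binary"),
                            effect_is_or = FALSE) {
  trait_type <- match.arg(trait_type)
  column_map <- as.list(column_map)
  mandatory <- c("snp_id", "effect_allele", "other_allele", "effect", "se", "pvalue")
  missing_map <- setdiff(mandatory, names(column_map))
  if (length(missing_map)) {
    stop("column_map does not name mandatory column(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("no rows in ", path, call. = FALSE)
  absent <- vapply(column_map, function(cn) !cn %in% names(raw), logical(1))
  if (any(absent[names(column_map) %in% mandatory])) {
    bad <- unlist(column_map[absent & names(column_map) %in% mandatory])
    stop("mapped column(s) not found in file: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  get_col <- function(field) {
    cn <- column_map[[field]]
    if (is.null(cn) || !cn %in% names(raw)) return(NULL)
    raw[[cn]]
  }
  eff <- as.numeric(get_col("effect"))
  if (effect_is_or) {
    eff[!is.na(eff) & eff <= 0] <- NA_real_  # OR must be positive
    eff <- log(eff)
  }
  rec <- data.frame(
    snp_id = get_col("snp_id"),
    effect_allele = get_col("effect_allele"),
    other_allele = get_col("other_allele"),
    beta = eff,
    se = as.numeric(get_col("se")),
    pvalue = as.numeric(get_col("pvalue")),
    stringsAsFactors = FALSE
  )
  for (opt in c("eaf", "n", "chr", "pos")) {
    v <- get_col(opt)
    if (!is.null(v)) rec[[opt]] <- if (opt == "chr") as.character(v) else as.numeric(v)
  }
  tab <- gwas_table(rec, trait_id %||% basename(path), trait_type)
  if (nrow(tab$records) == 0L) {
    stop("no valid rows after ingestion of ", path, call. = FALSE)
  }
  tab
}

#' Write a GWAS table to a delimited file
#'
#' Writes the canonical columns as TSV, the same format [read_gwas_table()]
#' reads (identity column map).
#'
#' @param x A [gwas_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(x, path) {
  stopifnot(inherits(x, "gwas_table"))
  utils::write.table(x$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Identity column map for files written by [write_gwas_table()]
#' @return Named list usable as `column_map`.
#' @export
canonical_column_map <- function() {
  list(snp_id = "snp_id", effect_allele = "effect_allele",
       other_allele = "other_allele", effect = "beta", se = "se",
       pvalue = "pvalue", eaf = "eaf", n = "n", chr = "chr", pos = "pos")
}
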