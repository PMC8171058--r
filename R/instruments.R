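#' Pairwise LD lookup from a matrix or long table
#'
#' Accepts either a square correlation matrix with SNP ids as dimnames
#' (entries are r; r-squared is taken as the square) or a long-format data
#' frame with columns `snp_a`, `snp_b`, `r2`. Returns a function
#' `f(id_a, id_b)` giving r-squared (0 when a pair is unknown).
#'
#' @param ld A square matrix, a long data frame, or `NULL` (all r2 = 0).
#' @return A lookup function of two SNP-id vectors.
#' @keywords internal
ld_lookup <- function(ld) {
  if (is.null(ld)) {
    return(function(a, b) rep(0, max(length(a), length(b))))
  }
  if (is.matrix(ld)) {
    ids <- rownames(ld)
    if (is.null(ids) || !identical(ids, colnames(ld))) {
      stop("LD matrix must be square with matching SNP-id dimnames", call. = FALSE)
    }
    r2 <- ld^2
    return(function(a, b) {
      ia <- match(a, ids); ib <- match(b, ids)
      out <- rep(0, max(length(ia), length(ib)))
      known <- !is.na(ia) & !is.na(ib)
      out[known] <- r2[cbind(ia[known], ib[known])]
      out
    })
  }
  if (is.data.frame(ld)) {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld)))
    key <- c(paste(ld$snp_a, ld$snp_b, sep = "\r"),
             paste(ld$snp_b, ld$snp_a, sep = "\r"))
    val <- c(ld$r2, ld$r2)
    return(function(a, b) {
      out <- val[match(paste(a, b, sep = "\r"), key)]
      out[is.na(out)] <- 0
      out[a == b] <- 1
      out
    })
  }
  stop("unsupported LD source", call. = FALSE)
}

#' Select independent genome-wide-significant instruments
#'
#' Retains SNPs with exposure p-value below `p_threshold` (default the
#' genome-wide threshold 5e-8) and prunes them by greedy LD clumping: SNPs are
#' visited in order of ascending p-value; each visited SNP is kept and every
#' remaining SNP with r-squared at or above `r2_threshold` to it (within
#' `window_kb` when positions are available) is removed.
#'
#' @param gwas A [gwas_table()] for the exposure.
#' @param p_threshold Instrument p-value threshold; SNPs with `p < p_threshold`
#'   survive. Default `5e-8`.
#' @param ld LD source for [ld_lookup()]; `NULL` treats all SNPs as
#'   independent.
#' @param r2_threshold Clumping threshold; default `0.001` (SNPs with
#'   `r2 >= 0.001` to a kept SNP are removed).
#' @param window_kb Clumping window in kilobases, applied only when the table
#'   carries `chr`/`pos` columns; default 10000 kb. Pairs on different
#'   chromosomes or farther apart than the window are never pruned.
#' @return Character vector of kept SNP ids, ordered by ascending p-value.
#'   Empty when no SNP passes `p_threshold` (the exposure then has no strong
#'   instrument).
#' @export
select_instruments <- function(gwas, p_threshold = 5e-8, ld = NULL,
                               r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(gwas, "gwas_table"))
  rec <- gwas$records
  rec <- rec[rec$pvalue < p_threshold, , drop = FALSE]
  if (nrow(rec) == 0L) return(character(0))
  rec <- rec[order(rec$pvalue, rec$snp_id), , drop = FALSE]
  r2_of <- ld_lookup(ld)
  has_pos <- all(c("chr", "pos") %in% names(rec)) && !anyNA(rec$pos)
  kept <- character(0)
  ids <- rec$snp_id
  while (length(ids)) {
    top <- ids[1L]
    kept <- c(kept, top)
    ids <- ids[-1L]
    if (!length(ids)) break
    tagged <- r2_of(ids, rep(top, length(ids))) >= r2_threshold
    if (has_pos) {
      i_top <- match(top, rec$snp_id)
      i_rest <- match(ids, rec$snp_id)
      in_window <- rec$chr[i_rest] == rec$chr[i_top] &
        abs(rec$pos[i_rest] - rec$pos[i_top]) <= window_kb * 1000
      tagged <- tagged & in_window
    }
    ids <- ids[!tagged]
  }
  kept
}
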