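#' @keywords internal
"_PACKAGE"

## Smallest positive p-value admitted anywhere in the package. Input p-values
## of exactly 0 are floored to this before any log or quantile transform.
P_FLOOR <- .Machine$double.xmin

#' Derive a stage seed from a global seed
#'
#' Stable integer hash so that each pipeline stage can be rerun in isolation
#' with a reproducible seed. Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed Global integer seed.
#' @param stage Integer stage index (>= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  x <- (as.double(seed) %% m) + 1
  for (s in c(stage, 17L)) {
    x <- (x * 48271 + as.double(s) + 1) %% m
  }
  as.integer(x %% (m - 2)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## two-sided normal p-value from an estimate and its se
p_normal <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

floor_p <- function(p) {
  p[!is.na(p) & p <= 0] <- P_FLOOR
  p
}
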