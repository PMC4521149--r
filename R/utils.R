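# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs the global stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# E-values printed as "0.0" (or anything below double underflow) are clamped
# before taking logs; log10(0) is undefined and 1e-300 preserves ordering.
EVALUE_FLOOR <- 1e-300

#' Log10 of an e-value with underflow clamp
#'
#' E-values of exactly zero (as printed for extremely significant hits) are
#' clamped to 1e-300 before the logarithm so that comparisons in log space
#' remain defined while preserving the ordering of all representable values.
#'
#' @param evalue Numeric vector of non-negative e-values.
#' @return `log10(pmax(evalue, 1e-300))`.
#' @export
log10_evalue <- function(evalue) {
  stopifnot(is.numeric(evalue), all(evalue >= 0, na.rm = TRUE))
  log10(pmax(evalue, EVALUE_FLOOR))
}

# Abort with a message naming the offending file/line, mirroring how the
# readers report malformed input.
parse_error <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
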