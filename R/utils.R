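#' Internal helpers
#'
#' Small argument-checking and RNG utilities shared across the package.
#' All stochastic generators take an explicit `seed` and evaluate under
#' [withr::with_seed()] so that no global RNG state leaks in or out.
#'
#' @name imepipe-utils
#' @keywords internal
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                   strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %s", name, lower), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper), call. = FALSE)
  invisible(x)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a child seed from a parent seed
#'
#' Stage-level reproducibility: one pipeline seed fans out to per-stage
#' seeds by fixed offsets, so re-running a single stage reproduces its
#' output regardless of the order stages ran in. Kept below 2^31.
#'
#' @param seed parent integer seed.
#' @param offset fixed per-stage offset.
#' @return integer seed.
#' @keywords internal
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629)
}
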