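#' Evaluate an expression under a local, restorable RNG seed
#'
#' All stochastic generators in the package route their randomness through
#' this helper so that (i) a fixed seed gives bit-identical output and (ii)
#' the caller's RNG state is never disturbed.
#'
#' @param seed Integer scalar seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

## shared argument checks ----------------------------------------------------

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (x < lo || x > hi)
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, lo, hi, x),
         call. = FALSE)
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

clip01 <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))
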