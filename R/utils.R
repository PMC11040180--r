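# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (0.125 -> 0.13 at 2 digits),
#' matching how percentage tables are conventionally printed.  Base
#' `round()` uses round-half-even and would print 61.538 as 61.54 but
#' 87.505 as 87.5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic routines in the
# package route their randomness through this.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# validated frequency vector: numeric, non-negative, sums to 1
check_freqs <- function(p, tol = 1e-8) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) || any(p < 0)) {
    stop("frequencies must be a non-negative numeric vector", call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("frequencies sum to %.10f, not 1", sum(p)), call. = FALSE)
  }
  invisible(p)
}

is_probability <- function(x) is.numeric(x) && length(x) >= 1L &&
  !anyNA(x) && all(x >= 0) && all(x <= 1)
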