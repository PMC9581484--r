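# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bxs <- function(fmt, ..., class = "bxs_error") {
  stop(structure(
    class = unique(c(class, "bxs_error", "error", "condition")),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' @noRd
assert_that <- function(cond, fmt, ..., class = "bxs_error") {
  if (!isTRUE(cond)) stop_bxs(fmt, ..., class = class)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

#' Run code with a temporary RNG seed
#'
#' All stochastic operations in the package funnel through this helper so a
#' user-supplied seed makes them reproducible without clobbering the caller's
#' RNG state.  `seed = NULL` leaves the RNG stream untouched.
#' @noRd
with_seed_bxs <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  assert_that(is_count(seed + 1), "seed must be a single integer, got %s",
              deparse(seed))
  withr::with_seed(as.integer(seed), force(code))
}

# unit-normalize rows of a matrix of 3-vectors, guarding zero rows
normalize_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(v)
  v / n
}

# coordinate-wise median that tolerates empty input
median_or_na <- function(x) if (length(x) == 0L) NA_real_ else stats::median(x)
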