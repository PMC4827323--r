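the <- new.env(parent = emptyenv())
the$fit_count <- 0L

#' Count of model fits performed so far
#'
#' Every solve of the regularized normal equations (one Ridge or RFF-Ridge
#' model on one training set) increments an internal counter. The counter
#' makes the grid-search evaluation arithmetic checkable: a grid of `g`
#' hyperparameter points evaluated with `k`-fold cross-validation must perform
#' exactly `g * k` fits, and a single train/test split exactly `g`.
#'
#' @return Integer number of fits since the last [reset_fit_count()].
#' @seealso [grid_search()]
#' @export
#' @examples
#' reset_fit_count()
#' fit_rr(matrix(rnorm(20), 10, 2), rnorm(10), lambda = 1)
#' fit_count()
fit_count <- function() the$fit_count

#' @rdname fit_count
#' @export
reset_fit_count <- function() {
  the$fit_count <- 0L
  invisible(0L)
}

bump_fit_count <- function() {
  the$fit_count <- the$fit_count + 1L
  invisible(the$fit_count)
}

# Fixed-kind seeded evaluation so stored seeds reproduce draws across sessions.
with_seed <- function(seed, code) {
  withr::with_seed(
    seed, code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s.", name, format(lower)))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s.", name, format(lower)))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s.", name, format(upper)))
  }
  invisible(x)
}
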