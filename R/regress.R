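chol_fail <- function(e) {
  abort(paste0("regularized system is singular; use lambda > 0 ",
               "(Cholesky factorization failed)."))
}

# Solve (G + lambda I) w = b via Cholesky on a precomputed Gram matrix.
# One call = one model fit (counted); grid searches cache G across lambdas
# without changing the fit count.
ridge_solve_gram <- function(G, b, lambda) {
  bump_fit_count()
  diag(G) <- diag(G) + lambda
  R <- tryCatch(chol(G), error = chol_fail)
  as.numeric(backsolve(R, forwardsolve(t(R), b)))
}

# Solve (X'X + lambda I) w = X'y, never via explicit inversion. Uses the
# dual identity w = X'(XX' + lambda I)^-1 y when the feature dimension
# exceeds the sample count (algebraically exact).
ridge_solve <- function(X, y, lambda) {
  if (lambda > 0 && ncol(X) > nrow(X)) {
    bump_fit_count()
    K <- tcrossprod(X)
    diag(K) <- diag(K) + lambda
    R <- tryCatch(chol(K), error = chol_fail)
    alpha <- backsolve(R, forwardsolve(t(R), y))
    return(as.numeric(crossprod(X, alpha)))
  }
  ridge_solve_gram(crossprod(X), crossprod(X, y), lambda)
}

augment_bias <- function(X) cbind(X, `(bias)` = 1)

#' Fit Ridge Regression in closed form
#'
#' Solves `w = (X'X + lambda I)^-1 X'y` on the bias-augmented design (a
#' column of ones is appended and penalized with the same `lambda`; the
#' targets are activations in `[0, 1]` while the filtered features are
#' centered, so an intercept is required to reach the "on" plateau). The
#' solve uses a symmetric positive-definite factorization, never an explicit
#' inverse.
#'
#' @param X Feature tibble or numeric `T x P` matrix.
#' @param y Numeric target vector of length `T`.
#' @param lambda Regularization coefficient, `>= 0`.
#' @param intercept Append the bias column (default). With `FALSE` the
#'   weights solve the unaugmented normal equations.
#' @return An `omg_rr` model: weights `w` of length `P + 1` with the
#'   intercept last (when `intercept = TRUE`), and `lambda`.
#' @export
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, -1, 0.5) + 0.2
#' fit_rr(X, y, lambda = 1e-6)
fit_rr <- function(X, y, lambda, intercept = TRUE) {
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  check_scalar_number(lambda, "lambda", lower = 0)
  if (nrow(X) < 2L) abort("need at least 2 samples.")
  if (nrow(X) != length(y)) abort("nrow(X) must equal length(y).")
  Xb <- if (intercept) augment_bias(X) else X
  w <- ridge_solve(Xb, y, lambda)
  structure(list(w = w, lambda = lambda,
                 features = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                 intercept = intercept),
            class = "omg_rr")
}

#' Draw Random-Fourier-Feature frequencies and phases
#'
#' Frequencies `Omega` are `N(0, sigma^2)` i.i.d. entries of a `P x D`
#' matrix and phases `beta` are `U(-pi, pi)`. The standard-normal part of the
#' draw depends only on `(P, D, seed)` and is scaled by `sigma`, so grid
#' searches over `sigma` at a fixed seed reuse one underlying draw and
#' `lambda` comparisons are not confounded by resampling noise.
#'
#' @param p Input dimension.
#' @param D Feature-space dimensionality.
#' @param sigma Bandwidth (frequency scale), `> 0`.
#' @param seed Integer seed.
#' @return A list with `omega` (`p x D`) and `beta` (length `D`).
#' @export
rff_draw <- function(p, D, sigma, seed) {
  check_scalar_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  check_scalar_number(D, "D", lower = 1)
  with_seed(as.integer(seed), {
    z <- matrix(rnorm(p * D), p, D)
    beta <- runif(D, -pi, pi)
    list(omega = sigma * z, beta = beta)
  })
}

#' Random-Fourier-Feature map
#'
#' `Phi = sqrt(2 / D) * cos(X Omega + beta)`, applied row-wise; every entry
#' is bounded by `sqrt(2 / D)` in absolute value. With `Omega` drawn as in
#' [rff_draw()], `E[phi(x) phi(y)'] = exp(-sigma^2 ||x - y||^2 / 2)`, the
#' Gaussian kernel.
#'
#' @param X `T x P` matrix (or feature tibble).
#' @param omega `P x D` frequency matrix.
#' @param beta Phase vector of length `D`.
#' @return `T x D` feature matrix.
#' @export
rff_map <- function(X, omega, beta) {
  X <- as_feature_matrix(X)
  if (ncol(X) != nrow(omega)) abort("ncol(X) must equal nrow(omega).")
  D <- ncol(omega)
  if (length(beta) != D) abort("length(beta) must equal ncol(omega).")
  sqrt(2 / D) * cos(sweep(X %*% omega, 2, beta, `+`))
}

#' Fit Ridge Regression with Random Fourier Features
#'
#' Samples `(Omega, beta)` from `seed`, maps the input through [rff_map()]
#' and fits ridge weights `w = (Phi'Phi + lambda I)^-1 Phi'y` on the
#' bias-augmented feature matrix, exactly as [fit_rr()].
#'
#' @inheritParams fit_rr
#' @param sigma Bandwidth of the frequency distribution, `> 0`.
#' @param D Feature-space dimensionality (default 500).
#' @param seed Integer seed for the feature draw; refitting with the same
#'   seed reproduces the model exactly.
#' @return An `omg_rrff` model.
#' @export
fit_rrff <- function(X, y, lambda, sigma, D = 500, seed = 0L,
                     intercept = TRUE) {
  X <- as_feature_matrix(X)
  draw <- rff_draw(ncol(X), D, sigma, seed)
  Phi <- rff_map(X, draw$omega, draw$beta)
  Phib <- if (intercept) augment_bias(Phi) else Phi
  check_scalar_number(lambda, "lambda", lower = 0)
  w <- ridge_solve(Phib, as.numeric(y), lambda)
  structure(list(w = w, lambda = lambda, sigma = sigma, D = as.integer(D),
                 seed = as.integer(seed), p = ncol(X), omega = draw$omega,
                 beta = draw$beta,
                 features = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                 intercept = intercept),
            class = "omg_rrff")
}

#' @export
predict.omg_rr <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  np <- length(object$w) - as.integer(object$intercept)
  if (ncol(X) != np) {
    abort(sprintf("model expects %d features, got %d.", np, ncol(X)))
  }
  Xb <- if (object$intercept) augment_bias(X) else X
  as.numeric(Xb %*% object$w)
}

#' @export
predict.omg_rrff <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$p) {
    abort(sprintf("model expects %d features, got %d.", object$p, ncol(X)))
  }
  Phi <- rff_map(X, object$omega, object$beta)
  Phib <- if (object$intercept) augment_bias(Phi) else Phi
  as.numeric(Phib %*% object$w)
}

#' Clip predictions to the activation range
#'
#' Raw regression output is not clipped; this optional post-processing maps
#' predictions into `[0, 1]`.
#'
#' @param y_hat Numeric predictions.
#' @return Clipped predictions.
#' @export
clip_unit <- function(y_hat) pmin(pmax(y_hat, 0), 1)

#' @export
print.omg_rr <- function(x, ...) {
  cat(sprintf("<Ridge Regression: %d features%s, lambda = %g>\n",
              length(x$features),
              if (x$intercept) " + bias" else "", x$lambda))
  invisible(x)
}

#' @export
print.omg_rrff <- function(x, ...) {
  cat(sprintf(
    "<RFF Ridge Regression: %d features -> D = %d, sigma = %g, lambda = %g, seed = %d>\n",
    x$p, x$D, x$sigma, x$lambda, x$seed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.omg_rr <- function(x, ...) {
  terms <- c(x$features, if (x$intercept) "(bias)")
  tibble(term = terms, estimate = x$w)
}

#' @exportS3Method generics::tidy
tidy.omg_rrff <- function(x, ...) {
  terms <- c(paste0("rff_", seq_len(x$D)), if (x$intercept) "(bias)")
  tibble(term = terms, estimate = x$w)
}

#' @exportS3Method generics::glance
glance.omg_rr <- function(x, ...) {
  tibble(method = "rr", lambda = x$lambda,
         n_features = length(x$features),
         weight_norm = sqrt(sum(x$w^2)))
}

#' @exportS3Method generics::glance
glance.omg_rrff <- function(x, ...) {
  tibble(method = "rrff", lambda = x$lambda, sigma = x$sigma, D = x$D,
         seed = x$seed, n_features = x$p,
         weight_norm = sqrt(sum(x$w^2)))
}
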