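#' Optical perturbation setting
#'
#' One point of a robustness sweep over image degradations: Gaussian blur
#' kernel size, contrast scale `alpha` and additive brightness `beta`.
#'
#' @param blur_kernel Odd kernel size `>= 1` (1 = no blur); the reference
#'   sweep goes up to 29 pixels.
#' @param alpha Contrast scale in `(0, 1]`-ish range (`> 0` required);
#'   `alpha = 0.2` is 20% of the original contrast.
#' @param beta Additive brightness offset in pixel units (may be negative).
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(blur_kernel = 1, alpha = 1, beta = 0) {
  check_scalar_number(blur_kernel, "blur_kernel", lower = 1)
  if (blur_kernel %% 2 == 0) abort("`blur_kernel` must be odd.")
  check_scalar_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_scalar_number(beta, "beta")
  structure(list(blur_kernel = as.integer(blur_kernel), alpha = alpha,
                 beta = beta),
            class = "perturbation_spec")
}

#' Contrast / brightness adjustment
#'
#' Per-pixel affine map `alpha * f(x, y) + beta`, then clipped to
#' `[0, 255]` and rounded to integer pixel depth (scale, add, clip, round).
#' Before clipping the operator is affine: applying `(a1, b1)` then
#' `(a2, b2)` equals applying `(a1 * a2, a2 * b1 + b2)`.
#'
#' @param image Numeric matrix of pixel values in `[0, 255]`.
#' @param alpha Contrast scale, `> 0`.
#' @param beta Brightness offset.
#' @return Adjusted image matrix.
#' @export
#' @examples
#' adjust_contrast_brightness(matrix(100), 0.5, 10)  # 60
adjust_contrast_brightness <- function(image, alpha, beta) {
  if (!is.numeric(image)) abort("`image` must be numeric.")
  check_scalar_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_scalar_number(beta, "beta")
  if (any(image < 0 | image > 255)) {
    abort("pixel values must lie in [0, 255].")
  }
  out <- round(pmin(pmax(alpha * image + beta, 0), 255))
  if (is.matrix(image)) dim(out) <- dim(image)
  out
}

gaussian_kernel_1d <- function(k) {
  if (k == 1) return(1)
  sigma <- k / 6  # +-3 sigma support inside the kernel
  x <- seq(-(k - 1) / 2, (k - 1) / 2)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

reflect_pad <- function(v, r) {
  n <- length(v)
  c(v[(r + 1):2], v, v[(n - 1):(n - r)])
}

convolve_1d <- function(v, w) {
  r <- (length(w) - 1) / 2
  if (r == 0) return(v)
  vp <- reflect_pad(v, r)
  out <- stats::filter(vp, w, method = "convolution", sides = 2)
  as.numeric(out[(r + 1):(r + length(v))])
}

#' Gaussian blur
#'
#' Convolution with a normalized 2-D Gaussian kernel of side `k`
#' (`sigma = k / 6`, so the +-3 sigma support fits the kernel), separable
#' row/column passes with reflected borders. Kernel normalization keeps the
#' image mean within 1%; `k = 1` is the identity and a uniform image is
#' unchanged.
#'
#' @param image Numeric pixel matrix.
#' @param k Odd kernel size, `1 <= k <= min(dim(image))`.
#' @return Blurred image matrix (numeric; not re-quantized).
#' @export
gaussian_blur <- function(image, k) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.")
  }
  check_scalar_number(k, "k", lower = 1)
  if (k %% 2 == 0) abort("kernel size `k` must be odd.")
  if (k > min(dim(image))) abort("`k` exceeds the image size.")
  if (k == 1) return(image)
  w <- gaussian_kernel_1d(k)
  out <- apply(image, 2, convolve_1d, w = w)           # down columns
  out <- t(apply(out, 1, convolve_1d, w = w))          # along rows
  dim(out) <- dim(image)
  out
}

#' Keep only the most proximal markers
#'
#' Markers are laid out in rows of two with ids `0, 1` most proximal; the
#' "simulated amputee" analysis keeps the six most proximal markers (rows
#' 0-2), shrinking the downstream feature matrix to `6 * n` columns while
#' leaving the frame axis untouched.
#'
#' @param poses A pose tibble.
#' @param n Number of markers to keep (default 6).
#' @return The trimmed pose tibble.
#' @export
trim_proximal <- function(poses, n = 6) {
  ids <- marker_ids(poses)
  check_scalar_number(n, "n", lower = 1)
  if (n > length(ids)) {
    abort(sprintf("`n` = %d exceeds the %d available markers.",
                  n, length(ids)))
  }
  # proximal order: by row (id %/% 2), then column (id %% 2)
  ord <- ids[order(ids %/% 2, ids %% 2)]
  keep <- ord[seq_len(n)]
  out <- filter(poses, .data$tag_id %in% keep)
  res <- new_poses(out, sort(keep), attr(poses, "fps"))
  attr(res, "mixing_gain") <- attr(poses, "mixing_gain")
  res
}

#' Robustness sweep
#'
#' Runs the evaluation pipeline (by default scheme 5, the train-on-plateau /
#' predict-all split, with Ridge Regression) across a set of robustness
#' settings and reports one entry per setting.
#'
#' Two paths are available. The trajectory-level path (`trim_markers`)
#' re-evaluates on reduced marker sets, e.g. `c(10, 6)` for the full layout
#' versus the six most proximal markers. The image-level path
#' (`perturbations`) degrades an image sequence with
#' [adjust_contrast_brightness()] and [gaussian_blur()] and re-runs marker
#' detection through a user-supplied `detector` adapter (a
#' `function(images)` returning a pose tibble); the fiducial detector itself
#' is out of scope, so image specs without an adapter are rejected with
#' guidance.
#'
#' @param poses Pose tibble (raw).
#' @param stimulus Aligned stimulus tibble.
#' @param trim_markers Integer vector of marker counts to evaluate
#'   (`NULL` for none; the full count gives the baseline).
#' @param perturbations List of [perturbation_spec()]s (optional).
#' @param images List of pixel matrices, one per frame (required with
#'   `perturbations`).
#' @param detector Adapter `function(images) -> pose tibble` (required with
#'   `perturbations`).
#' @param scheme,method,grid,D,seed Pipeline settings, see [run_scheme()].
#' @return A tibble with one row per (setting, DOF): `setting`, `scheme`,
#'   `method`, `dof`, `nrmse` (fold mean), `lambda`, `sigma`.
#' @export
robustness_sweep <- function(poses, stimulus, trim_markers = NULL,
                             perturbations = NULL, images = NULL,
                             detector = NULL, scheme = 5,
                             method = c("rr", "rrff"), grid = grid_spec(),
                             D = 500, seed = 0L) {
  method <- match.arg(method)
  run_one <- function(p, setting) {
    features <- build_features(impute_last_known(p))
    rep <- run_scheme(features, stimulus, scheme, method = method,
                      grid = grid, D = D, seed = seed)
    rep |>
      group_by(.data$scheme, .data$method, .data$dof) |>
      summarise(nrmse = mean(.data$nrmse),
                lambda = .data$lambda[1], sigma = .data$sigma[1],
                .groups = "drop") |>
      mutate(setting = setting, .before = 1)
  }
  out <- list()
  if (is.null(trim_markers)) {
    out <- list(run_one(poses, "baseline"))
  } else {
    for (n in trim_markers) {
      out[[length(out) + 1L]] <-
        run_one(trim_proximal(poses, n), sprintf("markers_%d", n))
    }
  }
  if (!is.null(perturbations)) {
    if (is.null(detector) || is.null(images)) {
      abort(paste0(
        "image-level perturbations need an image sequence and a marker-",
        "detector adapter: pass `images` (list of pixel matrices) and ",
        "`detector = function(images) -> pose tibble`."))
    }
    for (spec in perturbations) {
      stopifnot(inherits(spec, "perturbation_spec"))
      degraded <- lapply(images, function(img) {
        img <- adjust_contrast_brightness(img, spec$alpha, spec$beta)
        gaussian_blur(img, spec$blur_kernel)
      })
      p <- detector(degraded)
      out[[length(out) + 1L]] <- run_one(
        p, sprintf("blur%d_a%g_b%g", spec$blur_kernel, spec$alpha, spec$beta))
    }
  }
  res <- bind_rows(out)
  structure(res, class = c("omg_sweep", class(res)))
}
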