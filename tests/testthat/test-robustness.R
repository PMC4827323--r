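test_that("contrast/brightness follows the affine pixel law", {
  img <- matrix(c(0, 50, 100, 200), 2, 2)
  expect_equal(adjust_contrast_brightness(img, 1, 0), img)
  expect_equal(adjust_contrast_brightness(matrix(100), 0.5, 10), matrix(60))
  expect_equal(adjust_contrast_brightness(matrix(200), 0.2, 0), matrix(40))
  # saturation: scale, add, clip, round
  expect_equal(adjust_contrast_brightness(matrix(200), 1.5, 0), matrix(255))
  expect_equal(adjust_contrast_brightness(matrix(10), 1, -50), matrix(0))
  expect_error(adjust_contrast_brightness(img, 0, 0), "alpha")
  expect_error(adjust_contrast_brightness(matrix(300), 1, 0), "255")
})

test_that("successive affine adjustments compose before clipping", {
  set.seed(20)
  img <- matrix(2 * sample(0:50, 64, replace = TRUE), 8, 8)
  # even pixels with alpha1 = 0.5 keep every intermediate integer and inside
  # [0, 255], so rounding and clipping are inert and the affine identity
  # (alpha1*alpha2, alpha2*beta1 + beta2) holds exactly
  two_step <- adjust_contrast_brightness(
    adjust_contrast_brightness(img, 0.5, 10), 2, 5)
  one_step <- adjust_contrast_brightness(img, 0.5 * 2, 2 * 10 + 5)
  expect_equal(two_step, one_step)
})

test_that("gaussian blur preserves means, constants and the identity case", {
  set.seed(21)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  expect_identical(gaussian_blur(img, 1), img)
  flat <- matrix(7, 40, 40)
  expect_equal(gaussian_blur(flat, 9), flat)
  for (k in c(5, 29)) {
    out <- gaussian_blur(img, k)
    expect_lt(abs(mean(out) - mean(img)) / mean(img), 0.01)
    expect_lte(stats::sd(out), stats::sd(img))  # smoothing reduces variance
  }
  expect_error(gaussian_blur(img, 4), "odd")
  expect_error(gaussian_blur(matrix(0, 10, 10), 29), "size")
})

test_that("separable blur matches a dense 2-D convolution oracle", {
  set.seed(22)
  img <- matrix(runif(100, 0, 255), 10, 10)
  k <- 5
  r <- (k - 1) / 2
  w1 <- exp(-(seq(-r, r))^2 / (2 * (k / 6)^2))
  w1 <- w1 / sum(w1)
  kern <- outer(w1, w1)
  reflect_idx <- function(i, n) ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i))
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) {
    for (j in 1:10) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + kern[di + r + 1, dj + r + 1] *
            img[reflect_idx(i + di, 10), reflect_idx(j + dj, 10)]
        }
      }
      oracle[i, j] <- acc
    }
  }
  expect_equal(gaussian_blur(img, k), oracle, tolerance = 1e-12)
})

test_that("proximal trimming keeps the first rows and the frame axis", {
  sub <- tiny_subject(n_markers = 10)
  trimmed <- trim_proximal(sub$poses, 6)
  expect_equal(marker_ids(trimmed), 0:5)
  expect_equal(length(unique(trimmed$frame_id)),
               length(unique(sub$poses$frame_id)))
  feats <- build_features(impute_last_known(trimmed))
  expect_equal(ncol(as_feature_matrix(feats)), 36)
  # n = M is the identity
  expect_equal(trim_proximal(sub$poses, 10)$x, sub$poses$x)
  expect_error(trim_proximal(sub$poses, 11), "exceeds")
})

test_that("a trim-only sweep reports one finite entry per marker count", {
  sub <- tiny_subject(n_markers = 10, noise_sd = 1e-4, seed = 2L)
  grid <- grid_spec(n_lambda = 3, n_sigma = 3)
  sweep <- robustness_sweep(sub$poses, sub$stimulus, trim_markers = c(10, 6),
                            scheme = 5, method = "rr", grid = grid)
  expect_equal(unique(sweep$setting), c("markers_10", "markers_6"))
  expect_equal(nrow(sweep), 2 * length(dof_names(sub$stimulus)))
  expect_true(all(is.finite(sweep$nrmse)))
  # empty settings give the baseline report only
  base <- robustness_sweep(sub$poses, sub$stimulus, scheme = 5,
                           method = "rr", grid = grid)
  expect_equal(unique(base$setting), "baseline")
})

test_that("image perturbations without a detector adapter are rejected", {
  sub <- tiny_subject(n_markers = 4)
  expect_error(
    robustness_sweep(sub$poses, sub$stimulus,
                     perturbations = list(perturbation_spec(alpha = 0.2))),
    "detector adapter")
})

test_that("a detector adapter feeds perturbed sequences through the pipeline", {
  sub <- tiny_subject(n_markers = 4, noise_sd = 1e-4, seed = 3L)
  images <- list(matrix(runif(64, 0, 255), 8, 8))
  seen <- NULL
  stub_detector <- function(imgs) {
    seen <<- imgs
    sub$poses
  }
  grid <- grid_spec(n_lambda = 2, n_sigma = 2)
  sweep <- robustness_sweep(
    sub$poses, sub$stimulus, trim_markers = 4,
    perturbations = list(perturbation_spec(blur_kernel = 3, alpha = 0.5)),
    images = images, detector = stub_detector,
    scheme = 5, method = "rr", grid = grid)
  expect_equal(unique(sweep$setting), c("markers_4", "blur3_a0.5_b0"))
  # the adapter received the degraded, not the original, image
  expect_false(identical(seen[[1]], images[[1]]))
  expect_equal(dim(seen[[1]]), dim(images[[1]]))
})

test_that("perturbation specs validate their fields", {
  expect_error(perturbation_spec(blur_kernel = 4), "odd")
  expect_error(perturbation_spec(alpha = 0), "alpha")
  ok <- perturbation_spec(blur_kernel = 29, alpha = 0.2, beta = -50)
  expect_equal(ok$blur_kernel, 29)
})
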