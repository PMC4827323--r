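#' Normalized root mean squared error
#'
#' `sqrt(mean((y_hat - y)^2)) / range`. The default range is
#' `max(y) - min(y)`; when the target is constant the range falls back to 1
#' (so NRMSE equals RMSE, as it does whenever the target spans `[0, 1]`).
#'
#' @param y_hat Predictions.
#' @param y Ground truth, same length.
#' @param range Normalization constant, `> 0`.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' nrmse(c(0.5, 0.5), c(0, 1))  # 0.5
nrmse <- function(y_hat, y, range = NULL) {
  if (length(y) == 0) abort("empty input.")
  if (length(y_hat) != length(y)) abort("lengths differ.")
  if (is.null(range)) {
    range <- max(y) - min(y)
    if (range <= 0) range <- 1
  }
  check_scalar_number(range, "range", lower = 0, strict_lower = TRUE)
  sqrt(mean((y_hat - y)^2)) / range
}

#' Hyperparameter grid
#'
#' Log-spaced grids: `n_lambda` values of the regularization `lambda` with
#' exponents equally spaced in `lambda_exponents` (default ten values,
#' `[-6, 0]`), and `n_sigma` values of the RFF bandwidth `sigma` with
#' exponents in `sigma_exponents` (default ten values, `[-3, 3]`). The RFF
#' search space is the Cartesian product (10 x 10 = 100 pairs by default).
#'
#' @param lambda_exponents,sigma_exponents Length-2 exponent ranges.
#' @param n_lambda,n_sigma Points per grid.
#' @return An `omg_grid` list with numeric vectors `lambda` and `sigma`.
#' @export
grid_spec <- function(lambda_exponents = c(-6, 0), sigma_exponents = c(-3, 3),
                      n_lambda = 10, n_sigma = 10) {
  structure(
    list(lambda = 10^seq(lambda_exponents[1], lambda_exponents[2],
                         length.out = n_lambda),
         sigma = 10^seq(sigma_exponents[1], sigma_exponents[2],
                        length.out = n_sigma)),
    class = "omg_grid"
  )
}

chunk_shuffled <- function(idx, k) {
  fold_id <- rep_len(seq_len(k), length(idx))
  lapply(seq_len(k), function(f) sort(idx[fold_id == f]))
}

chunk_contiguous <- function(n, k) {
  bounds <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(f) seq.int(bounds[f] + 1, bounds[f + 1]))
}

#' Build a train/test split plan for one validation scheme
#'
#' The five schemes:
#' 1. 10-fold cross-validation with shuffling over all frames.
#' 2. 10-fold cross-validation with shuffling over plateau (on-off) frames
#'    only.
#' 3. Single split: train on all plateau frames, test on all intermediate
#'    frames (no cross-validation).
#' 4. 5-fold cross-validation over all frames, folds contiguous in time
#'    without shuffling (one repetition per fold under the default protocol).
#' 5. 5 contiguous folds; train on the plateau frames of four folds, test on
#'    all frames of the held-out fold.
#'
#' Fold sizes differ by at most one; every plan partitions its target index
#' set with no train/test overlap.
#'
#' @param scheme Scheme id in `1:5`.
#' @param n_frames Total number of frames `T`.
#' @param plateau Logical vector of length `T` marking plateau frames
#'   (required for schemes 2, 3 and 5).
#' @param seed Shuffling seed (schemes 1-2).
#' @return An `omg_split_plan`: list with `scheme`, `seed` and `folds`, each
#'   fold a list with integer `train` and `test` indices.
#' @export
make_split_plan <- function(scheme, n_frames, plateau = NULL, seed = 0L) {
  if (!scheme %in% 1:5) abort("`scheme` must be in 1:5.")
  n_frames <- as.integer(n_frames)
  if (scheme %in% c(2, 3, 5)) {
    if (is.null(plateau)) abort(sprintf("scheme %d needs a plateau mask.", scheme))
    if (length(plateau) != n_frames) {
      abort("`plateau` must have length `n_frames`.")
    }
    if (!any(plateau)) abort("plateau mask is empty.")
  }
  folds <- switch(
    as.character(scheme),
    "1" = {
      if (n_frames < 10) abort("scheme 1 needs at least 10 frames.")
      test <- with_seed(seed, chunk_shuffled(sample(n_frames), 10L))
      lapply(test, function(f) list(train = setdiff(seq_len(n_frames), f),
                                    test = f))
    },
    "2" = {
      idx <- which(plateau)
      if (length(idx) < 10) abort("scheme 2 needs at least 10 plateau frames.")
      test <- with_seed(seed, chunk_shuffled(sample(idx), 10L))
      lapply(test, function(f) list(train = setdiff(idx, f), test = f))
    },
    "3" = {
      if (all(plateau)) abort("scheme 3 needs intermediate frames to test on.")
      list(list(train = which(plateau), test = which(!plateau)))
    },
    "4" = {
      if (n_frames < 5) abort("scheme 4 needs at least 5 frames.")
      chunks <- chunk_contiguous(n_frames, 5L)
      lapply(chunks, function(f) list(train = setdiff(seq_len(n_frames), f),
                                      test = f))
    },
    "5" = {
      chunks <- chunk_contiguous(n_frames, 5L)
      lapply(chunks, function(f) {
        train <- intersect(which(plateau), setdiff(seq_len(n_frames), f))
        if (length(train) == 0) abort("plateau mask empty on training folds.")
        list(train = train, test = f)
      })
    }
  )
  structure(list(scheme = as.integer(scheme), seed = as.integer(seed),
                 n_frames = n_frames, folds = folds),
            class = "omg_split_plan")
}

#' Grid search over hyperparameters under a split plan
#'
#' For every grid point, fits on each fold's training indices, evaluates
#' NRMSE on the matching test indices and averages across folds; returns the
#' argmin grid point. Fit count: `(#grid points) x (#folds)` solves -- 10
#' lambdas for RR, 100 `(lambda, sigma)` pairs for RR-RFF -- which
#' [fit_count()] makes observable. The RFF frequency/phase draw is made once
#' per seed (scaled per sigma), so lambda comparisons share one draw. Ties
#' resolve to the first grid point in (sigma, lambda) order.
#'
#' @param X Feature tibble or matrix.
#' @param y Target vector.
#' @param plan An [make_split_plan()] plan.
#' @param method `"rr"` or `"rrff"`.
#' @param grid An [grid_spec()].
#' @param D RFF dimensionality.
#' @param seed RFF draw seed.
#' @return An `omg_grid_search` list: `best` (lambda, sigma, mean NRMSE),
#'   `fold_nrmse` for the selected point, `results` tibble over the whole
#'   grid, and `n_fits`.
#' @export
grid_search <- function(X, y, plan, method = c("rr", "rrff"),
                        grid = grid_spec(), D = 500, seed = 0L) {
  method <- match.arg(method)
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  stopifnot(inherits(plan, "omg_split_plan"))
  if (nrow(X) != plan$n_frames || length(y) != plan$n_frames) {
    abort("X and y must have `n_frames` rows.")
  }
  # per (design, fold): cache the Gram matrix, then one counted solve per
  # lambda -- each (lambda[, sigma], fold) combination is one model fit.
  eval_fold <- function(Z, fold, sigma) {
    Ztr <- augment_bias(Z[fold$train, , drop = FALSE])
    Zte <- augment_bias(Z[fold$test, , drop = FALSE])
    G <- crossprod(Ztr)
    b <- crossprod(Ztr, y[fold$train])
    y_te <- y[fold$test]
    rng <- max(y_te) - min(y_te)
    if (rng <= 0) rng <- 1
    map(grid$lambda, function(lam) {
      w <- ridge_solve_gram(G, b, lam)
      tibble(lambda = lam, sigma = sigma,
             nrmse = nrmse(as.numeric(Zte %*% w), y_te, range = rng))
    })
  }
  rows <- list()
  if (method == "rr") {
    for (fi in seq_along(plan$folds)) {
      fr <- bind_rows(eval_fold(X, plan$folds[[fi]], NA_real_))
      fr$fold <- fi
      rows[[length(rows) + 1L]] <- fr
    }
  } else {
    draws <- lapply(grid$sigma, function(s) rff_draw(ncol(X), D, s, seed))
    for (si in seq_along(grid$sigma)) {
      Phi <- rff_map(X, draws[[si]]$omega, draws[[si]]$beta)
      for (fi in seq_along(plan$folds)) {
        fr <- bind_rows(eval_fold(Phi, plan$folds[[fi]], grid$sigma[si]))
        fr$fold <- fi
        rows[[length(rows) + 1L]] <- fr
      }
    }
  }
  results <- bind_rows(rows)
  if (all(is.nan(results$nrmse) | is.na(results$nrmse))) {
    abort("grid search produced no finite errors (degenerate data).")
  }
  means <- results |>
    group_by(.data$lambda, .data$sigma) |>
    summarise(mean_nrmse = mean(.data$nrmse), .groups = "drop")
  best <- means[which.min(means$mean_nrmse), ]
  sel <- results$lambda == best$lambda &
    (is.na(results$sigma) | results$sigma == best$sigma)
  structure(
    list(best = list(lambda = best$lambda, sigma = best$sigma,
                     nrmse = best$mean_nrmse),
         fold_nrmse = results$nrmse[sel],
         results = results,
         n_fits = nrow(results)),
    class = "omg_grid_search"
  )
}

#' Run one validation scheme on one subject
#'
#' Per degree of freedom: builds that DOF's plateau mask, the scheme's split
#' plan and a full grid search, then reports the selected hyperparameters and
#' the per-fold NRMSE of the optimum. Hyperparameter selection and error
#' reporting share the same folds (no nesting), so the reported error carries
#' the usual optimistic selection bias.
#'
#' @param features Feature tibble from [build_features()].
#' @param stimulus Aligned stimulus tibble (same frames).
#' @param scheme Scheme id in `1:5`; see [make_split_plan()].
#' @param method `"rr"` or `"rrff"`.
#' @param grid An [grid_spec()].
#' @param D RFF dimensionality.
#' @param seed Seed for fold shuffling and the RFF draw.
#' @param eps Plateau tolerance, see [onoff_mask()].
#' @return An `omg_report` tibble: one row per (DOF, fold) with columns
#'   `scheme`, `method`, `dof`, `fold`, `nrmse`, `lambda`, `sigma`.
#' @export
run_scheme <- function(features, stimulus, scheme, method = c("rr", "rrff"),
                       grid = grid_spec(), D = 500, seed = 0L, eps = 1e-6) {
  method <- match.arg(method)
  X <- as_feature_matrix(features)
  if (nrow(X) != nrow(stimulus) ||
      !identical(as.integer(features$frame_id),
                 as.integer(stimulus$frame_id))) {
    abort("features and stimulus must cover identical frame_ids.")
  }
  out <- lapply(dof_names(stimulus), function(d) {
    y <- stimulus[[d]]
    plateau <- abs(y) <= eps | abs(y - 1) <= eps
    plan <- make_split_plan(scheme, nrow(X), plateau = plateau, seed = seed)
    gs <- grid_search(X, y, plan, method = method, grid = grid, D = D,
                      seed = seed)
    tibble(scheme = as.integer(scheme), method = method, dof = d,
           fold = seq_along(gs$fold_nrmse), nrmse = gs$fold_nrmse,
           lambda = gs$best$lambda, sigma = gs$best$sigma)
  })
  res <- bind_rows(out)
  structure(res, class = c("omg_report", class(res)))
}

#' Evaluate schemes and methods on one subject
#'
#' Full per-subject pipeline: imputes undetected samples, builds the filtered
#' feature matrix (optionally on a marker subset) and runs every requested
#' scheme x method combination.
#'
#' @param poses Pose tibble (raw; imputed internally).
#' @param stimulus Aligned stimulus tibble.
#' @param schemes Scheme ids, subset of `1:5`.
#' @param methods Subset of `c("rr", "rrff")`.
#' @param config A [pipeline_config()] supplying filter settings, grids, `D`
#'   and seed.
#' @return An `omg_report` tibble (rows per scheme, method, DOF, fold).
#' @export
evaluate_subject <- function(poses, stimulus, schemes = 1:5,
                             methods = c("rr", "rrff"),
                             config = pipeline_config()) {
  features <- build_features(
    impute_last_known(poses),
    marker_subset = config$marker_subset,
    low_hz = config$low_hz, high_hz = config$high_hz,
    order = config$filter_order, causal = config$causal
  )
  grid <- grid_spec(config$lambda_exponents, config$sigma_exponents,
                    config$n_lambda, config$n_sigma)
  combos <- tidyr::expand_grid(scheme = schemes, method = methods)
  res <- pmap(combos, function(scheme, method) {
    run_scheme(features, stimulus, scheme, method = method, grid = grid,
               D = config$D, seed = config$seed)
  })
  res <- bind_rows(res)
  structure(res, class = c("omg_report", class(res)))
}

#' Aggregate validation reports across subjects
#'
#' Summarizes per-subject fold-mean NRMSE into mean, SD (with `n - 1`
#' denominator) and SEM (`SD / sqrt(n)`) per scheme x method x DOF.
#'
#' @param report A report tibble with a `subject` column (bind per-subject
#'   [run_scheme()]/[evaluate_subject()] outputs with a subject id).
#' @return Tibble with columns `scheme`, `method`, `dof`, `n_subjects`,
#'   `mean_nrmse`, `sd_nrmse`, `sem_nrmse`.
#' @export
aggregate_report <- function(report) {
  if (!"subject" %in% names(report)) {
    abort("`report` needs a `subject` column to aggregate over.")
  }
  per_subject <- report |>
    group_by(.data$subject, .data$scheme, .data$method, .data$dof) |>
    summarise(nrmse = mean(.data$nrmse), .groups = "drop")
  per_subject |>
    group_by(.data$scheme, .data$method, .data$dof) |>
    summarise(n_subjects = dplyr::n(),
              mean_nrmse = mean(.data$nrmse),
              sd_nrmse = sd(.data$nrmse),
              sem_nrmse = sd(.data$nrmse) / sqrt(dplyr::n()),
              .groups = "drop")
}

#' Two-tailed Student t-test
#'
#' Classical pooled-variance two-sample t-test by default (`welch = TRUE`
#' switches to the Welch variant, `paired = TRUE` to a paired test). When
#' both samples have zero variance, the convention is `p = 1` for equal
#' means and `p = 0` otherwise.
#'
#' @param a,b Numeric samples, each of length `>= 2`.
#' @param paired Paired test.
#' @param welch Unequal-variance (Welch) test.
#' @return A tibble with `estimate` (mean difference), `statistic`,
#'   `parameter` (df) and `p.value`.
#' @export
ttest_two_tailed <- function(a, b, paired = FALSE, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("each sample needs >= 2 values.")
  zero_var <- isTRUE(all.equal(stats::var(a), 0)) &&
    isTRUE(all.equal(stats::var(b), 0)) &&
    (!paired || stats::var(a - b) == 0)
  if (zero_var) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble(estimate = mean(a) - mean(b),
                  statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                  parameter = length(a) + length(b) - 2,
                  p.value = if (eq) 1 else 0))
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = !welch,
                      alternative = "two.sided")
  tibble(estimate = if (paired) unname(tt$estimate)
         else unname(tt$estimate[1] - tt$estimate[2]),
         statistic = unname(tt$statistic),
         parameter = unname(tt$parameter),
         p.value = tt$p.value)
}

#' Write a validation report to tidy CSV / JSON
#'
#' @param report A report tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  readr::write_csv(as_tibble(report), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
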