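#' Replace undetected marker samples by their last known pose
#'
#' Undetected samples (`detected = FALSE`, `NA` pose) are conservatively
#' replaced by the most recent detected pose of the same marker; a leading
#' undetected run copies the first detected pose backwards. The operation is
#' idempotent and leaves detected samples untouched.
#'
#' @param poses A pose tibble.
#' @return The pose tibble with all `detected` flags `TRUE`.
#' @export
impute_last_known <- function(poses) {
  never <- poses |>
    group_by(.data$tag_id) |>
    summarise(any_det = any(.data$detected), .groups = "drop")
  if (any(!never$any_det)) {
    abort(sprintf("marker %s has no detected sample; cannot impute.",
                  never$tag_id[!never$any_det][1]))
  }
  out <- poses |>
    group_by(.data$tag_id) |>
    arrange(.data$frame_id, .by_group = TRUE) |>
    tidyr::fill(all_of(pose_channels), .direction = "downup") |>
    ungroup() |>
    arrange(.data$frame_id, .data$tag_id) |>
    mutate(detected = TRUE)
  new_poses(out, marker_ids(poses), attr(poses, "fps"))
}

butter_coefs <- function(fps, low_hz, high_hz, order) {
  if (low_hz <= 0 || high_hz >= fps / 2 || low_hz >= high_hz) {
    abort("cutoffs must satisfy 0 < low_hz < high_hz < fps / 2.")
  }
  signal::butter(order, c(low_hz, high_hz) / (fps / 2), type = "pass")
}

#' Butterworth bandpass filter
#'
#' Second-order (by default) Butterworth bandpass with cutoffs 0.01 and
#' 0.5 Hz, removing the DC and high-frequency content of each channel and
#' centering it around zero. The default is zero-phase (forward-backward)
#' filtering with odd-reflection padding of length `3 * (2 * order + 1)`;
#' `causal = TRUE` applies a single forward pass instead (with its startup
#' transient).
#'
#' @param x Numeric vector, one channel's time series.
#' @param fps Sampling rate, frames/s; must exceed `2 * high_hz`.
#' @param low_hz,high_hz Cutoff frequencies, Hz.
#' @param order Butterworth design order (a bandpass of design order `n` has
#'   transfer order `2 n`).
#' @param causal Single forward pass instead of zero-phase.
#' @return Filtered numeric vector of the same length.
#' @export
bandpass_filter <- function(x, fps, low_hz = 0.01, high_hz = 0.5, order = 2,
                            causal = FALSE) {
  bf <- butter_coefs(fps, low_hz, high_hz, order)
  pad <- 3L * (2L * order + 1L)
  n <- length(x)
  if (n <= 3L * pad) {
    abort(sprintf("signal too short to filter (need > %d samples).", 3L * pad))
  }
  # Steady-state initial conditions: a bandpass has zero DC gain, so the
  # state-initialized response to x equals the zero-state response to
  # x - x[1] (the filter behaves as if the signal had been at x[1] forever).
  # Without this, the ~100 s settle time at the 0.01 Hz cutoff leaks a large
  # startup transient from the DC offset.
  run <- function(v) as.numeric(signal::filter(bf, v - v[1]))
  if (causal) {
    return(run(x))
  }
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(front, x, back)
  y <- run(xp)
  y <- rev(run(rev(y)))
  y[(pad + 1):(pad + n)]
}

# |H(f)| of the bandpass design, from its transfer polynomial; squared for
# the zero-phase (forward-backward) variant.
filter_gain <- function(f, fps, low_hz = 0.01, high_hz = 0.5, order = 2,
                        zero_phase = FALSE) {
  bf <- butter_coefs(fps, low_hz, high_hz, order)
  z <- exp(-1i * 2 * pi * f / fps)
  h <- sum(bf$b * z^(seq_along(bf$b) - 1)) /
    sum(bf$a * z^(seq_along(bf$a) - 1))
  g <- Mod(h)
  if (zero_phase) g^2 else g
}

feature_names <- function(ids) {
  as.vector(vapply(ids, function(id) paste0("tag", id, "_", pose_channels),
                   character(6)))
}

#' Build the filtered feature matrix
#'
#' Pivots an (imputed) pose tibble to the regression design: one column per
#' marker channel, marker-major then channel order
#' (`tag0_x ... tag0_roll, tag1_x, ...`), each column bandpass filtered and
#' then centered exactly at zero mean. Markers can be restricted to a subset
#' (e.g. the proximal ones) before feature construction.
#'
#' @param poses Imputed pose tibble (all samples detected); see
#'   [impute_last_known()].
#' @param marker_subset Optional integer marker ids to keep.
#' @param low_hz,high_hz,order,causal Filter settings, see
#'   [bandpass_filter()].
#' @return A feature tibble: `frame_id`, `timestamp`, then `6 * M` filtered
#'   channel columns.
#' @export
build_features <- function(poses, marker_subset = NULL, low_hz = 0.01,
                           high_hz = 0.5, order = 2, causal = FALSE) {
  if (anyNA(poses[pose_channels]) || !all(poses$detected)) {
    abort("poses contain undetected samples; run impute_last_known() first.")
  }
  ids <- marker_ids(poses)
  if (!is.null(marker_subset)) {
    marker_subset <- as.integer(marker_subset)
    if (length(marker_subset) == 0) abort("`marker_subset` is empty.")
    unknown <- setdiff(marker_subset, ids)
    if (length(unknown) > 0) {
      abort(sprintf("unknown marker id(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    ids <- ids[ids %in% marker_subset]
  }
  fps <- attr(poses, "fps")
  if (is.null(fps) || !is.finite(fps)) {
    ts <- sort(unique(poses$timestamp))
    fps <- 1 / stats::median(diff(ts))
  }
  frames <- distinct(poses[, c("frame_id", "timestamp")])
  frames <- arrange(frames, .data$frame_id)
  cols <- vector("list", length(ids) * 6L)
  k <- 1L
  for (id in ids) {
    sub <- arrange(filter(poses, .data$tag_id == id), .data$frame_id)
    for (ch in pose_channels) {
      v <- bandpass_filter(sub[[ch]], fps, low_hz, high_hz, order, causal)
      cols[[k]] <- v - mean(v)
      k <- k + 1L
    }
  }
  names(cols) <- feature_names(ids)
  out <- dplyr::bind_cols(frames, as_tibble(cols))
  structure(out, fps = fps, marker_ids = ids,
            class = c("omg_features", class(out)))
}

#' Extract the numeric design matrix from a feature tibble
#'
#' @param features A feature tibble from [build_features()], or a numeric
#'   matrix (returned unchanged).
#' @return A `T x P` numeric matrix.
#' @export
as_feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  cols <- setdiff(names(features), c("frame_id", "timestamp"))
  as.matrix(features[, cols, drop = FALSE])
}

#' Label plateau (on-off) versus intermediate frames
#'
#' A frame is a plateau frame for a DOF when that DOF's stimulus value is
#' within `eps` of 0 or of 1; `is_on` marks the activated plateau. Masks are
#' computed per DOF on that DOF's own column, so a frame can be "on" for the
#' active DOF and "off" for the others.
#'
#' @param stimulus A stimulus tibble.
#' @param eps Plateau tolerance.
#' @return A tibble with columns `frame_id`, `dof`, `is_plateau`, `is_on`.
#' @export
onoff_mask <- function(stimulus, eps = 1e-6) {
  dofs <- dof_names(stimulus)
  vals <- as.matrix(stimulus[, dofs, drop = FALSE])
  if (any(vals < 0 | vals > 1)) abort("stimulus values must lie in [0, 1].")
  out <- lapply(dofs, function(d) {
    v <- stimulus[[d]]
    tibble(frame_id = stimulus$frame_id, dof = d,
           is_on = abs(v - 1) <= eps,
           is_plateau = abs(v) <= eps | abs(v - 1) <= eps)
  })
  select(bind_rows(out), "frame_id", "dof", "is_plateau", "is_on")
}
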