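new_stimulus <- function(df, dof_names, fps) {
  structure(as_tibble(df),
            dof_names = dof_names, fps = fps,
            class = c("omg_stimulus", class(as_tibble(df))))
}

new_poses <- function(df, marker_ids, fps) {
  structure(as_tibble(df),
            marker_ids = as.integer(marker_ids), fps = fps,
            class = c("omg_poses", class(as_tibble(df))))
}

#' Names of the stimulated degrees of freedom
#'
#' @param x A stimulus tibble as produced by [generate_stimulus()] or
#'   [read_stimulus_csv()].
#' @return Character vector of DOF column names, in stimulation order.
#' @export
dof_names <- function(x) {
  attr(x, "dof_names") %||% setdiff(names(x), c("frame_id", "timestamp"))
}

#' Marker ids of a trajectory set, in proximal-to-distal order
#'
#' Markers are laid out in rows of two; ids `0, 1` are the most proximal row.
#' @param x A pose tibble as produced by [simulate_forearm()] or
#'   [read_pose_csv()].
#' @return Integer marker ids.
#' @export
marker_ids <- function(x) {
  attr(x, "marker_ids") %||% sort(unique(x$tag_id))
}

# Raised-cosine ramped plateau: u is time since activation onset.
activation_value <- function(u, flexion_s, ramp_s) {
  v <- numeric(length(u))
  active <- u >= 0 & u < flexion_s
  if (ramp_s == 0) {
    v[active] <- 1
    return(v)
  }
  up <- active & u < ramp_s
  hold <- u >= ramp_s & u < flexion_s - ramp_s
  down <- active & u >= flexion_s - ramp_s
  v[up] <- 0.5 * (1 - cos(pi * u[up] / ramp_s))
  v[hold] <- 1
  v[down] <- 0.5 * (1 + cos(pi * (u[down] - (flexion_s - ramp_s)) / ramp_s))
  v
}

#' Generate the square-sinusoidal stimulus profile
#'
#' Builds the session stimulus: per repetition, each DOF in turn is driven
#' from 0 to 1 through a raised-cosine ramp, held at 1, ramped back down and
#' followed by rest; exactly one DOF is nonzero at any frame. Frames are
#' sampled at frame centers, `t_k = (k - 0.5) / fps`, so the count of frames
#' exactly at 1 per activation equals
#' `round(fps * (flexion_s - 2 * ramp_s))`.
#'
#' @param config A [protocol_config()].
#' @return A stimulus tibble with columns `frame_id`, `timestamp` and one
#'   activation column in `[0, 1]` per DOF.
#' @export
#' @examples
#' stim <- generate_stimulus(protocol_config(repetitions = 1))
#' range(stim$thumb_rotation)
generate_stimulus <- function(config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  d <- length(config$dof_names)
  slot_s <- config$flexion_s + config$rest_s
  total_s <- config$repetitions * d * slot_s
  n <- round(config$fps * total_s)
  t <- (seq_len(n) - 0.5) / config$fps
  cols <- lapply(seq_len(d) - 1L, function(di) {
    onsets <- (rep(seq_len(config$repetitions) - 1L, each = 1L) * d + di) *
      slot_s
    v <- numeric(n)
    for (s0 in onsets) {
      v <- v + activation_value(t - s0, config$flexion_s, config$ramp_s)
    }
    v
  })
  names(cols) <- config$dof_names
  df <- tibble(frame_id = seq_len(n), timestamp = t)
  df <- dplyr::bind_cols(df, as_tibble(cols))
  new_stimulus(df, config$dof_names, config$fps)
}

#' Default sparse mixing gains
#'
#' Each DOF drives the position channels of a disjoint set of dominant
#' markers (assigned round-robin over marker ids, so every DOF keeps a
#' dominant marker in the proximal rows) with gains around 5 mm per unit
#' activation, plus 10%-magnitude cross-talk on a few other channels.
#'
#' @param n_markers Number of markers.
#' @param dofs Character vector of DOF names (columns of the gain matrix).
#' @param seed Integer seed for the gain draw.
#' @return A `(6 * n_markers) x length(dofs)` matrix; rows are marker-major
#'   channels (`x, y, z, yaw, pitch, roll` per marker).
#' @export
default_mixing_gain <- function(n_markers = 10,
                                dofs = c("thumb_rotation", "thumb_flexion",
                                         "index_flexion", "combo_flexion"),
                                seed = 0L) {
  d <- length(dofs)
  p <- 6L * n_markers
  with_seed(seed + 1000L, {
    gain <- matrix(0, p, d,
                   dimnames = list(NULL, dofs))
    for (di in seq_len(d)) {
      markers <- seq(di - 1L, n_markers - 1L, by = d)  # round-robin, 0-based
      for (m in markers) {
        idx <- m * 6L + 1:3  # x, y, z of marker m
        gain[idx, di] <- 0.005 * (1 + 0.2 * rnorm(3)) *
          sample(c(-1, 1), 3, replace = TRUE)
      }
      # small cross-talk on a few random other channels
      others <- setdiff(seq_len(p), unlist(lapply(markers, function(m) m * 6L + 1:6)))
      ct <- sample(others, min(4L, length(others)))
      gain[ct, di] <- 0.0005 * rnorm(length(ct))
    }
    gain
  })
}

#' Simulate forearm marker trajectories from a stimulus
#'
#' Generates a full 6-DOF pose time series per marker: channel `c` at frame
#' `t` is `baseline_c + sum_d gain[c, d] * stimulus[t, d] + drift + noise`.
#' Drift is a slow sinusoid with per-channel random phase; noise is white
#' Gaussian. A fraction `dropout_rate` of (frame, marker) samples is flagged
#' undetected and its pose set to `NA` (to be filled by
#' [impute_last_known()]). Identical seeds produce bit-identical output.
#'
#' @param stimulus Stimulus tibble from [generate_stimulus()].
#' @param config A [deformation_config()].
#' @return A pose tibble with columns `frame_id`, `timestamp`, `tag_id`,
#'   `x`, `y`, `z`, `yaw`, `pitch`, `roll`, `detected`; the gain matrix used
#'   is attached as attribute `mixing_gain`.
#' @export
simulate_forearm <- function(stimulus, config = deformation_config()) {
  stopifnot(inherits(config, "deformation_config"))
  dofs <- dof_names(stimulus)
  s <- as.matrix(stimulus[, dofs, drop = FALSE])
  n <- nrow(s)
  m <- config$n_markers
  p <- 6L * m
  gain <- config$mixing_gain %||%
    default_mixing_gain(m, dofs, seed = config$seed)
  if (ncol(gain) != length(dofs)) {
    abort("`mixing_gain` column count must match the number of DOFs.")
  }
  # baseline layout: rows of two markers, 3 cm spacing, 25 cm from the camera
  ids <- seq_len(m) - 1L
  baseline <- matrix(0, p, 1)
  baseline[ids * 6L + 1L] <- (ids %% 2L) * 0.03 - 0.015          # x
  baseline[ids * 6L + 2L] <- (ids %/% 2L) * 0.03 - 0.06          # y
  baseline[ids * 6L + 3L] <- 0.25                                # z
  noise_sd <- rep_len(config$noise_sd, p)
  drift_amp <- rep_len(config$drift_amplitude, p)
  t <- stimulus$timestamp
  signal_mat <- s %*% t(gain)  # n x p
  with_seed(config$seed, {
    phases <- runif(p, -pi, pi)
    drift <- outer(2 * pi * t / config$drift_period_s, phases, `+`)
    drift <- sin(drift) %*% diag(drift_amp, p)
    noise <- matrix(rnorm(n * p), n, p) %*% diag(noise_sd, p)
    chan <- signal_mat + drift + noise +
      matrix(baseline, n, p, byrow = TRUE)
    detected <- matrix(runif(n * m) >= config$dropout_rate, n, m)
    rows <- lapply(ids, function(id) {
      pose <- chan[, id * 6L + 1:6, drop = FALSE]
      colnames(pose) <- pose_channels
      det <- detected[, id + 1L]
      pose[!det, ] <- NA_real_
      dplyr::bind_cols(
        tibble(frame_id = stimulus$frame_id, timestamp = t,
               tag_id = id),
        as_tibble(pose),
        tibble(detected = det)
      )
    })
    out <- arrange(bind_rows(rows), .data$frame_id, .data$tag_id)
    out <- new_poses(out, ids,
                     attr(stimulus, "fps") %||% (1 / stats::median(diff(t))))
    attr(out, "mixing_gain") <- gain
    out
  })
}

#' Simulate one synthetic subject
#'
#' Convenience wrapper: generates the stimulus for `protocol` and the marker
#' trajectories for `deformation`, with the deformation seed offset by
#' `subject` so each subject is an independent draw.
#'
#' @param protocol A [protocol_config()].
#' @param deformation A [deformation_config()].
#' @param subject Integer subject index added to the deformation seed.
#' @return A list with elements `stimulus` and `poses`.
#' @export
simulate_subject <- function(protocol = protocol_config(),
                             deformation = deformation_config(),
                             subject = 0L) {
  deformation$seed <- deformation$seed + as.integer(subject)
  stimulus <- generate_stimulus(protocol)
  list(stimulus = stimulus,
       poses = simulate_forearm(stimulus, deformation))
}
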