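pose_channels <- c("x", "y", "z", "yaw", "pitch", "roll")

#' Stimulation protocol configuration
#'
#' Describes the visual-stimulus session: each degree of freedom (DOF) in turn
#' is driven from rest (0) to full activation (1) through a raised-cosine
#' ramped plateau ("square-sinusoidal" profile), held, and released, followed
#' by a rest period; the whole DOF sequence is repeated `repetitions` times.
#' Defaults reproduce the reference protocol: four movements (thumb rotation,
#' thumb flexion, index flexion, combined little/ring/middle flexion), 5 s
#' flexion with 3 s rest, five repetitions, sampled at 15 frames/s.
#'
#' @param dof_names Character vector of movement names, stimulated in order.
#' @param flexion_s Duration of one activation (ramp up + hold + ramp down),
#'   seconds. Must exceed `2 * ramp_s`.
#' @param rest_s Rest duration after each activation, seconds.
#' @param repetitions Number of times the DOF sequence is repeated.
#' @param fps Sampling rate, frames per second. Must exceed 1 (and twice the
#'   bandpass high cutoff used downstream).
#' @param ramp_s Raised-cosine ramp duration, seconds; `0` gives a square wave.
#' @return A `protocol_config` list.
#' @export
#' @examples
#' protocol_config(repetitions = 1)
protocol_config <- function(dof_names = c("thumb_rotation", "thumb_flexion",
                                          "index_flexion", "combo_flexion"),
                            flexion_s = 5, rest_s = 3, repetitions = 5,
                            fps = 15, ramp_s = 1.0) {
  if (!is.character(dof_names) || length(dof_names) < 1L ||
      anyDuplicated(dof_names)) {
    abort("`dof_names` must be distinct movement names.")
  }
  check_scalar_number(flexion_s, "flexion_s", lower = 0, strict_lower = TRUE)
  check_scalar_number(rest_s, "rest_s", lower = 0)
  check_scalar_number(repetitions, "repetitions", lower = 1)
  check_scalar_number(fps, "fps", lower = 1, strict_lower = TRUE)
  check_scalar_number(ramp_s, "ramp_s", lower = 0)
  if (flexion_s <= 2 * ramp_s && ramp_s > 0) {
    abort("`flexion_s` must exceed 2 * ramp_s (no room for a plateau).")
  }
  structure(
    list(dof_names = dof_names, flexion_s = flexion_s, rest_s = rest_s,
         repetitions = as.integer(repetitions), fps = fps, ramp_s = ramp_s),
    class = "protocol_config"
  )
}

#' Forearm-deformation simulator configuration
#'
#' Parameters of the synthetic marker-trajectory generator: each of the
#' `6 * n_markers` pose channels responds linearly to the DOF activations
#' through `mixing_gain`, on top of a static baseline, a slow sinusoidal
#' drift (period below the bandpass low cutoff, so filtering removes it) and
#' white Gaussian tracking noise. Markers drop out (undetected) independently
#' per frame with probability `dropout_rate`.
#'
#' @param n_markers Number of fiducial markers, laid out as
#'   `ceiling(n_markers / 2)` rows of two; marker ids `0, 1` form the most
#'   proximal row, `2, 3` the next, and so on.
#' @param mixing_gain Optional `(6 * n_markers) x D` gain matrix (meters or
#'   radians per unit activation). `NULL` draws the default sparse gains (per
#'   DOF, disjoint dominant markers at ~5 mm plus 10% cross-talk) from `seed`.
#' @param noise_sd Tracking-noise standard deviation per channel (scalar or
#'   length `6 * n_markers`), meters/radians. Default 2e-4.
#' @param drift_amplitude Amplitude of the slow drift per channel (scalar or
#'   vector), meters/radians. Default 5e-4.
#' @param drift_period_s Drift period, seconds; defaults to 200 s, below the
#'   0.01 Hz high-pass cutoff so the bandpass rejects it.
#' @param dropout_rate Per-(frame, marker) probability of an undetected
#'   sample, in `[0, 1)`.
#' @param seed Integer seed; identical seeds give bit-identical trajectories.
#' @return A `deformation_config` list.
#' @export
deformation_config <- function(n_markers = 10, mixing_gain = NULL,
                               noise_sd = 2e-4, drift_amplitude = 5e-4,
                               drift_period_s = 200, dropout_rate = 0.02,
                               seed = 0L) {
  check_scalar_number(n_markers, "n_markers", lower = 1)
  n_markers <- as.integer(n_markers)
  if (!is.null(mixing_gain)) {
    if (!is.matrix(mixing_gain) || nrow(mixing_gain) != 6L * n_markers) {
      abort(sprintf("`mixing_gain` must have %d rows (6 channels per marker).",
                    6L * n_markers))
    }
  }
  if (!is.numeric(noise_sd) || any(noise_sd < 0)) {
    abort("`noise_sd` must be >= 0.")
  }
  if (!is.numeric(drift_amplitude) || any(drift_amplitude < 0)) {
    abort("`drift_amplitude` must be >= 0.")
  }
  check_scalar_number(drift_period_s, "drift_period_s", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(dropout_rate, "dropout_rate", lower = 0)
  if (dropout_rate >= 1) abort("`dropout_rate` must be < 1.")
  structure(
    list(n_markers = n_markers, mixing_gain = mixing_gain,
         noise_sd = noise_sd, drift_amplitude = drift_amplitude,
         drift_period_s = drift_period_s, dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "deformation_config"
  )
}

#' Pipeline configuration
#'
#' Filtering, regression and validation settings. Defaults are the reference
#' values: second-order Butterworth bandpass 0.01-0.5 Hz, zero-phase; RFF
#' dimensionality `D = 500`; regularization grid of ten log-spaced values with
#' exponents in `[-6, 0]` and bandwidth grid with exponents in `[-3, 3]`.
#'
#' @param low_hz,high_hz Bandpass cutoff frequencies, Hz.
#' @param filter_order Butterworth design order (2 gives a 4th-order bandpass).
#' @param causal Use a single forward filter pass instead of the zero-phase
#'   forward-backward default.
#' @param D Random-Fourier-feature dimensionality.
#' @param lambda_exponents,sigma_exponents Length-2 exponent ranges of the
#'   log-spaced hyperparameter grids.
#' @param n_lambda,n_sigma Number of grid points per hyperparameter.
#' @param schemes Validation scheme ids to run, subset of `1:5`.
#' @param methods Regression methods, subset of `c("rr", "rrff")`.
#' @param seed Seed for fold shuffling and RFF draws.
#' @param marker_subset Optional integer marker ids restricting the features.
#' @param paired Use a paired t-test when comparing methods.
#' @param out_dir Output directory for the command-line tools.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(low_hz = 0.01, high_hz = 0.5, filter_order = 2,
                            causal = FALSE, D = 500,
                            lambda_exponents = c(-6, 0),
                            sigma_exponents = c(-3, 3),
                            n_lambda = 10, n_sigma = 10,
                            schemes = 1:5, methods = c("rr", "rrff"),
                            seed = 0L, marker_subset = NULL,
                            paired = FALSE, out_dir = ".") {
  check_scalar_number(low_hz, "low_hz", lower = 0, strict_lower = TRUE)
  check_scalar_number(high_hz, "high_hz", lower = low_hz, strict_lower = TRUE)
  check_scalar_number(filter_order, "filter_order", lower = 1)
  check_scalar_number(D, "D", lower = 1)
  if (length(lambda_exponents) != 2L || length(sigma_exponents) != 2L) {
    abort("exponent ranges must have length 2.")
  }
  if (!all(schemes %in% 1:5)) abort("`schemes` must be a subset of 1:5.")
  methods <- match.arg(methods, c("rr", "rrff"), several.ok = TRUE)
  structure(
    list(low_hz = low_hz, high_hz = high_hz,
         filter_order = as.integer(filter_order), causal = isTRUE(causal),
         D = as.integer(D), lambda_exponents = as.numeric(lambda_exponents),
         sigma_exponents = as.numeric(sigma_exponents),
         n_lambda = as.integer(n_lambda), n_sigma = as.integer(n_sigma),
         schemes = as.integer(schemes), methods = methods,
         seed = as.integer(seed), marker_subset = marker_subset,
         paired = isTRUE(paired), out_dir = out_dir),
    class = "pipeline_config"
  )
}

config_keys <- list(
  protocol = c("dof_names", "flexion_s", "rest_s", "repetitions", "fps",
               "ramp_s"),
  deformation = c("n_markers", "noise_sd", "drift_amplitude",
                  "drift_period_s", "dropout_rate", "sim_seed"),
  pipeline = c("low_hz", "high_hz", "filter_order", "causal", "D",
               "lambda_exponents", "sigma_exponents", "n_lambda", "n_sigma",
               "schemes", "methods", "seed", "marker_subset", "paired",
               "out_dir")
)

#' Load a flat key-value configuration file
#'
#' Reads a flat YAML key-value file and returns the three configuration
#' objects. Keys not present take the package defaults; unknown keys are
#' rejected (typo protection). An empty (or missing-keys) file yields the full
#' default configuration. The deformation seed key is `sim_seed` to keep it
#' distinct from the pipeline `seed`.
#'
#' @param path Path to the configuration file.
#' @param quiet Suppress the startup log of effective settings.
#' @return A list with elements `protocol`, `deformation` and `pipeline`.
#' @export
load_config <- function(path, quiet = TRUE) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config file must be a flat key-value mapping.")
  known <- unlist(config_keys, use.names = FALSE)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  pick <- function(keys) raw[intersect(names(raw), keys)]
  prot_args <- pick(config_keys$protocol)
  def_args <- pick(config_keys$deformation)
  names(def_args)[names(def_args) == "sim_seed"] <- "seed"
  pipe_args <- pick(config_keys$pipeline)
  if (!is.null(pipe_args$lambda_exponents)) {
    pipe_args$lambda_exponents <- as.numeric(pipe_args$lambda_exponents)
  }
  if (!is.null(pipe_args$sigma_exponents)) {
    pipe_args$sigma_exponents <- as.numeric(pipe_args$sigma_exponents)
  }
  cfg <- list(
    protocol = do.call(protocol_config, prot_args),
    deformation = do.call(deformation_config, def_args),
    pipeline = do.call(pipeline_config, pipe_args)
  )
  if (!quiet) {
    msg <- c(
      sprintf("protocol: %d DOFs, %g s flexion + %g s rest x %d reps @ %g fps",
              length(cfg$protocol$dof_names), cfg$protocol$flexion_s,
              cfg$protocol$rest_s, cfg$protocol$repetitions,
              cfg$protocol$fps),
      sprintf("filter: order %d bandpass %g-%g Hz (%s)",
              cfg$pipeline$filter_order, cfg$pipeline$low_hz,
              cfg$pipeline$high_hz,
              if (cfg$pipeline$causal) "causal" else "zero-phase"),
      sprintf("regression: D = %d, lambda 10^[%g, %g] x %d, sigma 10^[%g, %g] x %d",
              cfg$pipeline$D, cfg$pipeline$lambda_exponents[1],
              cfg$pipeline$lambda_exponents[2], cfg$pipeline$n_lambda,
              cfg$pipeline$sigma_exponents[1], cfg$pipeline$sigma_exponents[2],
              cfg$pipeline$n_sigma)
    )
    message(paste(msg, collapse = "\n"))
  }
  cfg
}
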