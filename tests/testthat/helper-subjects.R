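# Small synthetic subjects used across tests. Sizes are kept modest; the
# statistical structure (sequential square-sinusoidal stimulation, linear
# marker response, drift/noise/dropout) matches the full-size generator.

tiny_protocol <- function(dofs = c("thumb_rotation", "thumb_flexion"),
                          repetitions = 2, fps = 15, ramp_s = 1) {
  protocol_config(dof_names = dofs, flexion_s = 5, rest_s = 3,
                  repetitions = repetitions, fps = fps, ramp_s = ramp_s)
}

tiny_subject <- function(protocol = tiny_protocol(), n_markers = 4,
                         noise_sd = 0, drift_amplitude = 0,
                         dropout_rate = 0, seed = 1L) {
  def <- deformation_config(n_markers = n_markers, noise_sd = noise_sd,
                            drift_amplitude = drift_amplitude,
                            dropout_rate = dropout_rate, seed = seed)
  stim <- generate_stimulus(protocol)
  list(stimulus = stim, poses = simulate_forearm(stim, def))
}

mean_nrmse_by_dof <- function(report) {
  agg <- dplyr::summarise(dplyr::group_by(report, dof),
                          m = mean(nrmse), .groups = "drop")
  stats::setNames(agg$m, agg$dof)
}

# Transfer function |H(f)| of the Butterworth bandpass, evaluated directly
# from the design polynomials (independent of the time-domain filter path).
oracle_gain <- function(f, fps, low_hz = 0.01, high_hz = 0.5, order = 2) {
  bf <- signal::butter(order, c(low_hz, high_hz) / (fps / 2), type = "pass")
  z <- exp(-1i * 2 * pi * f / fps)
  Mod(sum(bf$b * z^(seq_along(bf$b) - 1)) /
        sum(bf$a * z^(seq_along(bf$a) - 1)))
}

# Steady-state amplitude of a filtered unit sinusoid, by sin/cos regression
# on the central part of the record.
measured_amplitude <- function(f, fps, duration_s = 600, ...) {
  t <- (seq_len(round(duration_s * fps)) - 0.5) / fps
  y <- bandpass_filter(sin(2 * pi * f * t), fps, ...)
  mid <- seq.int(round(length(t) * 0.25), round(length(t) * 0.75))
  fit <- stats::lm(y[mid] ~ sin(2 * pi * f * t[mid]) + cos(2 * pi * f * t[mid]))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
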