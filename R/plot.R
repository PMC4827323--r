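#' Plot a stimulus profile
#'
#' One panel per degree of freedom, activation against time.
#'
#' @param object A stimulus tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.omg_stimulus <- function(object, ...) {
  dofs <- dof_names(object)
  long <- tidyr::pivot_longer(as_tibble(object), all_of(dofs),
                              names_to = "dof", values_to = "activation")
  long$dof <- factor(long$dof, levels = dofs)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timestamp,
                                     y = .data$activation)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$dof), ncol = 1) +
    ggplot2::labs(x = "time [s]", y = "activation") +
    ggplot2::theme_minimal()
}

#' Plot a validation report
#'
#' Fold-mean NRMSE per scheme, faceted by DOF, colored by method; with a
#' `subject` column the bar is the cross-subject mean and the error bar the
#' SEM.
#'
#' @param object An `omg_report` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.omg_report <- function(object, ...) {
  df <- as_tibble(object)
  if ("subject" %in% names(df)) {
    agg <- aggregate_report(df)
  } else {
    agg <- df |>
      group_by(.data$scheme, .data$method, .data$dof) |>
      summarise(mean_nrmse = mean(.data$nrmse), sem_nrmse = NA_real_,
                .groups = "drop")
  }
  ggplot2::ggplot(agg, ggplot2::aes(x = factor(.data$scheme),
                                    y = .data$mean_nrmse,
                                    fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_nrmse - .data$sem_nrmse,
                   ymax = .data$mean_nrmse + .data$sem_nrmse),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25,
      na.rm = TRUE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$dof)) +
    ggplot2::labs(x = "validation scheme", y = "NRMSE", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a robustness sweep
#'
#' NRMSE per sweep setting, colored by DOF.
#'
#' @param object An `omg_sweep` tibble from [robustness_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.omg_sweep <- function(object, ...) {
  df <- as_tibble(object)
  df$setting <- factor(df$setting, levels = unique(df$setting))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$setting, y = .data$nrmse,
                                   colour = .data$dof,
                                   group = .data$dof)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "setting", y = "NRMSE", colour = NULL) +
    ggplot2::theme_minimal()
}
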