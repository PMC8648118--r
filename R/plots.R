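#' Histogram of arm preferences per phase
#'
#' @param metrics Tibble from [unit_phase_metrics()].
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_arm_preference <- function(metrics, bins = 30) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$arm_pref)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(
      x = "arm preference (ipsi  ←  →  contra)", y = "units",
      title = "Distribution of single-unit arm preferences"
    ) +
    ggplot2::theme_minimal()
}

#' Modulation against arm preference with the log-linear fit
#'
#' @param object A `slope_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot slope_fit
#' @export
autoplot.slope_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_ap, y = .data$log_m)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "red") +
    ggplot2::labs(
      x = "|arm preference|", y = "log10 preferred-arm modulation",
      title = sprintf("%s-preferring units: slope %.2f",
                      object$subgroup, object$slope)
    ) +
    ggplot2::theme_minimal()
}

#' Cumulative modulation curve across the arm-preference spectrum
#'
#' @param object A `cumulative_modulation` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cumulative_modulation
#' @export
autoplot.cumulative_modulation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$arm_pref,
                                       y = .data$cum_prop,
                                       colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$cum_prop - .data$se, 0),
                   ymax = pmin(.data$cum_prop + .data$se, 1),
                   fill = .data$arm),
      alpha = 0.2, colour = NA, na.rm = TRUE
    ) +
    ggplot2::labs(x = "arm preference", y = "cumulative modulation",
                  title = "Cumulative modulation by arm preference") +
    ggplot2::theme_minimal()
}

#' PRESS curve of a dimensionality estimate
#'
#' @param object A `dimensionality_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dimensionality_estimate
#' @export
autoplot.dimensionality_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$press)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red",
                                            `FALSE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = "components", y = "PRESS",
                  title = sprintf("Cross-validated dimensionality: p = %d",
                                  object$selected)) +
    ggplot2::theme_minimal()
}

matrix_to_long <- function(m, value_name) {
  rn <- as.numeric(rownames(m) %||% seq_len(nrow(m)))
  cn <- as.numeric(colnames(m) %||% seq_len(ncol(m)))
  tibble(
    train = rep(rn, times = ncol(m)),
    test = rep(cn, each = nrow(m)),
    !!value_name := as.numeric(m)
  )
}

#' Heatmap of a timepoint-pair covariance-alignment matrix
#'
#' @param object An `alignment_matrix` from [alignment_timecourse()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot alignment_matrix
#' @export
autoplot.alignment_matrix <- function(object, ...) {
  df <- matrix_to_long(unclass(object), "ca")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$train,
                                   fill = .data$ca)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "test time (s)", y = "train time (s)",
                  fill = "alignment",
                  title = "Covariance alignment across timepoints") +
    ggplot2::theme_minimal()
}

#' Heatmap of a cross-temporal decoding accuracy matrix
#'
#' @param object A `cross_temporal_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cross_temporal_matrix
#' @export
autoplot.cross_temporal_matrix <- function(object, ...) {
  df <- matrix_to_long(unclass(object), "accuracy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$train,
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "test time (s)", y = "train time (s)",
                  fill = "accuracy",
                  title = sprintf("Cross-temporal decoding (chance %.2f)",
                                  attr(object, "chance"))) +
    ggplot2::theme_minimal()
}

#' Native vs cross alignment summary
#'
#' @param object An `alignment_result` from [native_cross_alignment()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot alignment_result
#' @export
autoplot.alignment_result <- function(object, ...) {
  s <- alignment_summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$kind, y = .data$mean_ca)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_ca - .data$sd_ca,
                   ymax = .data$mean_ca + .data$sd_ca),
      width = 0.2
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "covariance alignment") +
    ggplot2::theme_minimal()
}
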