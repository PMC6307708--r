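#' Plot a rate-fidelity trade-off sweep
#'
#' Dual-axis view of a [tradeoff_sweep()]: maximum mutual information (left
#' axis) and information rate (right axis, rescaled) against activator
#' half-life on a log axis.
#'
#' @param object A `tradeoff_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tradeoff_sweep <- function(object, ...) {
  ratio <- max(object$mi_nats) / max(object$rate_nats_per_min)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$half_life_x)) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$mi_nats, colour = "mutual information")
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$rate_nats_per_min * ratio, colour = "information rate")
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_continuous(
      name = "maximum mutual information (nats)",
      sec.axis = ggplot2::sec_axis(~ . / ratio, name = "information rate (nats/min)")
    ) +
    ggplot2::labs(
      x = "activator half-life (min)", colour = NULL,
      title = "Rate-fidelity trade-off across activator half-lives"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a colony variance curve against its no-division bound
#'
#' @param curve A `colony_variance_curve` tibble from
#'   [population_variance_curve()].
#' @return A ggplot object.
#' @export
plot_variance_curve <- function(curve) {
  ok <- !is.na(curve$mean_var)
  ggplot2::ggplot(curve[ok, ], ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_var - .data$se, ymax = .data$mean_var + .data$se
      ),
      fill = "steelblue", alpha = 0.3
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$mean_var, colour = "within-colony (simulated)")
    ) +
    ggplot2::geom_line(
      data = curve,
      ggplot2::aes(y = .data$var_bound, colour = "no-division bound")
    ) +
    ggplot2::scale_colour_manual(
      values = c(
        "within-colony (simulated)" = "steelblue",
        "no-division bound" = "grey40"
      )
    ) +
    ggplot2::labs(
      x = "time (min)", y = "activator variance (deviation-units²)",
      colour = NULL,
      title = "Diversity in growing microcolonies vs. the no-division limit"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_variance_curve
#' @param object A `colony_variance_curve`.
#' @param ... Unused.
#' @export
autoplot.colony_variance_curve <- function(object, ...) {
  plot_variance_curve(object)
}

#' Plot binned colony-size statistics
#'
#' @param object A `binned_stat` tibble from [bin_by_colony_size()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_stat <- function(object, ...) {
  stat_name <- switch(attr(object, "statistic") %||% "cv",
    cv = "coefficient of variation",
    mi = "mutual information (nats)"
  )
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$bin_lo, y = .data$value)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(
      trans = "log2", breaks = object$bin_lo,
      labels = object$bin_label
    ) +
    ggplot2::labs(
      x = "microcolony size (cells)", y = stat_name
    ) +
    ggplot2::theme_minimal()
  if (any(is.finite(object$se))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$value - .data$se, ymax = .data$value + .data$se
      ),
      width = 0.1, na.rm = TRUE
    )
  }
  p
}
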