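#' Tidy a trade-off sweep
#'
#' @param x A `tradeoff_sweep` tibble.
#' @param ... Unused.
#' @return A plain tibble with one row per grid point.
#' @export
tidy.tradeoff_sweep <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c(
    "tau_x", "half_life_x", "mi_nats", "rate_nats_per_min"
  )])
}

#' Glance at a trade-off sweep
#'
#' One-row summary: grid size and span, whether the maximum information is
#' monotone in the half-life, and the location and height of the
#' information-rate optimum.
#'
#' @inheritParams tidy.tradeoff_sweep
#' @return A one-row tibble.
#' @export
glance.tradeoff_sweep <- function(x, ...) {
  i <- which.max(x$rate_nats_per_min)
  tibble::tibble(
    n_points = nrow(x),
    decades = log10(max(x$tau_x) / min(x$tau_x)),
    mi_monotone = all(diff(x$mi_nats) > 0),
    rate_max = x$rate_nats_per_min[i],
    tau_x_at_rate_max = x$tau_x[i],
    half_life_at_rate_max = x$half_life_x[i],
    rate_max_interior = i > 1L && i < nrow(x),
    sigma_mode = attr(x, "sigma_mode") %||% NA_character_
  )
}

#' Tidy a steady-state information summary
#'
#' @param x A `cascade_info` object from [cascade_information()].
#' @param ... Unused.
#' @return A tibble with one row per quantity (`estimate`, `unit`).
#' @export
tidy.cascade_info <- function(x, ...) {
  tibble::tibble(
    quantity = c("corr_yz", "mutual_information", "information_rate"),
    estimate = c(x$corr_yz, x$mi_nats, x$rate_nats_per_min),
    unit = c("dimensionless", "nats", "nats/min")
  )
}

#' Glance at a steady-state information summary
#'
#' @inheritParams tidy.cascade_info
#' @return A one-row tibble with the parameters and the information metrics.
#' @export
glance.cascade_info <- function(x, ...) {
  tibble::tibble(
    tau_x = x$params$tau_x,
    half_life_x = tau_to_half_life(x$params$tau_x),
    sigma_mode = x$params$sigma_mode,
    corr_yz = x$corr_yz,
    mi_nats = x$mi_nats,
    rate_nats_per_min = x$rate_nats_per_min
  )
}
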