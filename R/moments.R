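#' Activator variance over time
#'
#' Closed-form variance of the Ornstein-Uhlenbeck activator started from a
#' deterministic equilibrium point:
#' \deqn{Var\{X(t)\} = \sigma^2 \frac{\tau_x}{2}\left(1 - e^{-2t/\tau_x}\right).}
#' With the constrained amplitude `sigma = sqrt(2/tau_x)` this reduces to
#' `1 - exp(-2 t / tau_x)`, which saturates at 1 for every half-life.
#'
#' @param t Time(s) in minutes, non-negative (vectorised).
#' @param tau_x Activator correlation time in minutes.
#' @param sigma Noise amplitude (default 1).
#' @return Variance in deviation-units^2, same length as `t`.
#' @examples
#' variance_x(Inf, tau_x = 10)                       # 5
#' variance_x(5, 10, sigma = constrained_sigma(10))  # 1 - exp(-1)
#' @export
variance_x <- function(t, tau_x, sigma = 1) {
  if (!is.numeric(t) || any(is.nan(t)) || any(t < 0)) {
    rlang::abort("`t` must be non-negative.")
  }
  check_positive_scalar(tau_x, "tau_x")
  check_positive_scalar(sigma, "sigma")
  sigma^2 * (tau_x / 2) * (1 - exp(-2 * t / tau_x))
}

# Drift matrix of the (x, y, z) deviation dynamics.
drift_matrix <- function(params) {
  with(params, matrix(
    c(
      -1 / tau_x, 0, 0,
      g_y / tau_y, -1 / tau_y, 0,
      g_z / tau_z, 0, -1 / tau_z
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("x", "y", "z"), c("x", "y", "z"))
  ))
}

diffusion_matrix <- function(params) {
  s <- noise_amplitudes(params)
  diag(s^2)
}

#' Stationary second moments of the cascade
#'
#' Solves the continuous-time Lyapunov equation `M C + C M' + D = 0` for the
#' unique stationary covariance of the linear cascade, where `M` is the
#' drift matrix and `D` the (diagonal) diffusion matrix.
#'
#' @param params A [cascade_params()] object.
#' @return A one-row tibble with columns `t` (`Inf`), `var_x`, `var_y`,
#'   `var_z`, `cov_xy`, `cov_xz`, `cov_yz`, `corr_yz`, `mi_nats`.
#' @seealso [transient_moments()] for the time-resolved moments,
#'   [stationary_cov()] for the raw 3x3 matrix.
#' @export
stationary_moments <- function(params) {
  C <- stationary_cov(params)
  moment_row(Inf, C)
}

#' @rdname stationary_moments
#' @return `stationary_cov()` returns the 3x3 covariance matrix with
#'   dimnames `x`, `y`, `z`.
#' @export
stationary_cov <- function(params) {
  stopifnot(inherits(params, "cascade_params"))
  M <- drift_matrix(params)
  D <- diffusion_matrix(params)
  K <- kronecker(diag(3), M) + kronecker(M, diag(3))
  C <- matrix(solve(K, -as.vector(D)), 3, 3)
  C <- (C + t(C)) / 2
  dimnames(C) <- dimnames(M)
  C
}

moment_row <- function(t, C) {
  tibble::tibble(
    t = t,
    var_x = C[1, 1], var_y = C[2, 2], var_z = C[3, 3],
    cov_xy = C[1, 2], cov_xz = C[1, 3], cov_yz = C[2, 3],
    corr_yz = safe_corr(C[2, 3], C[2, 2], C[3, 3])
  ) |>
    dplyr::mutate(mi_nats = ifelse(abs(.data$corr_yz) < 1,
      -0.5 * log1p(-.data$corr_yz^2), NA_real_
    ))
}

safe_corr <- function(cov, v1, v2) {
  denom <- sqrt(v1 * v2)
  ifelse(denom > 0, cov / denom, 0)
}

#' Time-resolved second moments of the cascade
#'
#' Integrates the closed six-dimensional linear ODE system for the second
#' moments of `(x, y, z)` from the deterministic start (all moments zero,
#' the system sitting exactly at its equilibrium point at `t = 0`):
#' \deqn{\dot C = M C + C M^\top + D.}
#' Integration uses `deSolve::ode` (lsoda) at absolute and relative
#' tolerance `1e-10`.
#'
#' @param params A [cascade_params()] object.
#' @param t_grid Sorted, non-negative times (minutes).
#' @param tol Integration tolerance (both `atol` and `rtol`).
#' @return A tibble with one row per time and columns `t`, `var_x`, `var_y`,
#'   `var_z`, `cov_xy`, `cov_xz`, `cov_yz`, `corr_yz`, `mi_nats`.
#' @export
transient_moments <- function(params, t_grid, tol = 1e-10) {
  stopifnot(inherits(params, "cascade_params"))
  check_time_grid(t_grid)
  M <- drift_matrix(params)
  D <- diffusion_matrix(params)
  ty <- params$tau_y
  tz <- params$tau_z
  tx <- params$tau_x
  gy <- params$g_y
  gz <- params$g_z
  d2 <- diag(D)

  rhs <- function(t, state, parms) {
    vx <- state[1]; vy <- state[2]; vz <- state[3]
    cxy <- state[4]; cxz <- state[5]; cyz <- state[6]
    list(c(
      -2 * vx / tx + d2[1],
      2 * (gy * cxy - vy) / ty + d2[2],
      2 * (gz * cxz - vz) / tz + d2[3],
      gy * vx / ty - cxy * (1 / tx + 1 / ty),
      gz * vx / tz - cxz * (1 / tx + 1 / tz),
      gy * cxz / ty + gz * cxy / tz - cyz * (1 / ty + 1 / tz)
    ))
  }

  times <- t_grid
  prepend <- times[1] > 0
  if (prepend) times <- c(0, times)
  sol <- deSolve::ode(
    y = rep(0, 6), times = times, func = rhs, parms = NULL,
    method = "lsoda", atol = tol, rtol = tol
  )
  sol <- as.data.frame(sol)
  if (prepend) sol <- sol[-1, , drop = FALSE]
  out <- tibble::tibble(
    t = t_grid,
    var_x = pmax(sol[[2]], 0),
    var_y = pmax(sol[[3]], 0),
    var_z = pmax(sol[[4]], 0),
    cov_xy = sol[[5]],
    cov_xz = sol[[6]],
    cov_yz = sol[[7]]
  )
  out |>
    dplyr::mutate(
      corr_yz = safe_corr(.data$cov_yz, .data$var_y, .data$var_z),
      corr_yz = pmin(pmax(.data$corr_yz, -1), 1),
      mi_nats = ifelse(abs(.data$corr_yz) < 1,
        -0.5 * log1p(-.data$corr_yz^2), NA_real_
      )
    )
}

#' Mutual information of two jointly Gaussian variables
#'
#' For a bivariate Gaussian with correlation `corr`,
#' \deqn{I = -\tfrac{1}{2}\ln(1 - \rho^2)} nats.  An absolute correlation of
#' 1 carries infinite information and is an error.
#'
#' @param corr Correlation coefficient(s), strictly inside (-1, 1).
#' @param units `"nats"` (natural log, default) or `"bits"`.
#' @return Mutual information, non-negative, same length as `corr`.
#' @examples
#' gaussian_mi(0.8) # ~0.5108
#' @export
gaussian_mi <- function(corr, units = c("nats", "bits")) {
  units <- match.arg(units)
  if (!is.numeric(corr) || any(!is.finite(corr))) {
    rlang::abort("`corr` must be finite numeric.")
  }
  if (any(abs(corr) >= 1)) {
    rlang::abort("|corr| must be < 1 (|corr| = 1 carries infinite information).")
  }
  mi <- -0.5 * log1p(-corr^2)
  if (units == "bits") mi <- mi / log(2)
  mi
}

#' Mutual information between the downstream genes over time
#'
#' Evaluates `gaussian_mi()` on the transient correlation between Y and Z
#' computed from [transient_moments()].  Before any correlation has built up
#' (in particular at `t = 0`) the mutual information is zero.
#'
#' @inheritParams transient_moments
#' @param units `"nats"` or `"bits"`.
#' @return A tibble with columns `t` and `mi` (in the requested units).
#' @export
mi_over_time <- function(params, t_grid, units = c("nats", "bits"), tol = 1e-10) {
  units <- match.arg(units)
  mom <- transient_moments(params, t_grid, tol = tol)
  mi <- mom$mi_nats
  mi[is.na(mi)] <- 0
  if (units == "bits") mi <- mi / log(2)
  tibble::tibble(t = mom$t, mi = mi)
}

#' Steady-state mutual information between the downstream genes
#'
#' The stationary correlation between Y and Z is taken from the Lyapunov
#' solution ([stationary_moments()]) and converted with [gaussian_mi()].
#'
#' @inheritParams mi_over_time
#' @return Scalar mutual information.
#' @export
steady_state_mi <- function(params, units = c("nats", "bits")) {
  units <- match.arg(units)
  C <- stationary_cov(params)
  corr <- safe_corr(C[2, 3], C[2, 2], C[3, 3])
  if (abs(corr) >= 1) {
    rlang::abort("Degenerate parameters: |corr_yz| = 1, information diverges.")
  }
  gaussian_mi(corr, units = units)
}

#' Steady-state information summary of a cascade
#'
#' Bundles the stationary correlation, mutual information and information
#' rate of a parameter set into a single object with `print()`, `tidy()` and
#' `glance()` methods.
#'
#' @param params A [cascade_params()] object.
#' @return An object of class `cascade_info`.
#' @export
cascade_information <- function(params) {
  C <- stationary_cov(params)
  corr <- safe_corr(C[2, 3], C[2, 2], C[3, 3])
  structure(
    list(
      params = params,
      corr_yz = corr,
      mi_nats = gaussian_mi(corr),
      rate_nats_per_min = info_rate_closed(params)
    ),
    class = "cascade_info"
  )
}

#' @export
print.cascade_info <- function(x, ...) {
  cat("<cascade_info>\n")
  cat(sprintf(
    "  activator half-life %.4g min (tau_x = %.4g), mode %s\n",
    tau_to_half_life(x$params$tau_x), x$params$tau_x, x$params$sigma_mode
  ))
  cat(sprintf("  stationary corr(Y,Z):   %.5f\n", x$corr_yz))
  cat(sprintf("  mutual information:     %.5f nats\n", x$mi_nats))
  cat(sprintf("  information rate:       %.6f nats/min\n", x$rate_nats_per_min))
  invisible(x)
}
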