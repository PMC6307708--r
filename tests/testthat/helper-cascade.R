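# Shared fixtures: parameter generators and independent oracles.

params_default <- function(...) {
  cascade_params(tau_x = half_life_to_tau(30), tau_y = 20, tau_z = 20, ...)
}

# Random valid parameter set drawn reproducibly from a seed.
random_params <- function(seed, sigma_mode = c("free", "constrained")) {
  sigma_mode <- match.arg(sigma_mode)
  withr::with_seed(seed, {
    tau_x <- stats::runif(1, 0.5, 40)
    cascade_params(
      tau_x = tau_x,
      tau_y = stats::runif(1, 2, 40),
      tau_z = stats::runif(1, 2, 40),
      g_y = stats::runif(1, 0.2, 2.5),
      g_z = stats::runif(1, 0.2, 2.5),
      sigma = if (sigma_mode == "free") stats::runif(1, 0.3, 2),
      sigma_mode = sigma_mode
    )
  })
}

# Independent closed-form oracle for the transient second moments of a
# linear SDE started at zero covariance:
#   C(t) = S - e^{Mt} S e^{M't},  S the stationary covariance.
# Uses Matrix::expm, which the package implementation does not.
moment_oracle <- function(params, t) {
  M <- infocascade:::drift_matrix(params)
  S <- stationary_cov(params)
  A <- as.matrix(Matrix::expm(M * t))
  S - A %*% S %*% t(A)
}

cov_row_to_matrix <- function(row) {
  matrix(
    c(
      row$var_x, row$cov_xy, row$cov_xz,
      row$cov_xy, row$var_y, row$cov_yz,
      row$cov_xz, row$cov_yz, row$var_z
    ),
    3, 3
  )
}

# Gaussian-theory Monte Carlo SE of a sample covariance entry.
se_cov <- function(v1, v2, c12, n) sqrt((v1 * v2 + c12^2) / n)

default_dt_for_test <- function(p) min(p$tau_x, p$tau_y, p$tau_z) / 100

correlated_gaussian <- function(n, rho, seed) {
  withr::with_seed(seed, {
    u <- stats::rnorm(n)
    v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n)
    list(u = u, v = v)
  })
}
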