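# Deterministic substream derivation: one root seed spawns per-unit seeds so
# ensembles and colonies are reproducible and order-independent.  All
# arithmetic stays below 2^53 so the modulus is exact in doubles.
derive_seed <- function(seed, index) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + as.numeric(index) * 2654435) %% 2147483646 + 1)
}

default_dt <- function(params) {
  min(params$tau_x, params$tau_y, params$tau_z) / 100
}

check_euler_dt <- function(params, dt) {
  taus <- c(tau_x = params$tau_x, tau_y = params$tau_y, tau_z = params$tau_z)
  bound <- min(taus) / 50
  if (dt > bound + 1e-12) {
    binding <- names(taus)[which.min(taus)]
    rlang::abort(sprintf(
      "Euler step dt = %g exceeds min(tau)/50 = %g; the binding correlation time is %s = %g min.",
      dt, bound, binding, min(taus)
    ))
  }
  invisible(dt)
}

# Dense matrix exponential for the small drift matrices used here
# (Pade order 6 with scaling and squaring).  Matrix::expm is deliberately
# not used so that it can serve as an independent oracle in the tests.
expm_small <- function(M) {
  n <- nrow(M)
  nrm <- max(rowSums(abs(M)))
  j <- max(0L, ceiling(log2(max(nrm, 2^-52))) + 1L)
  A <- M / 2^j
  q <- 6L
  I <- diag(n)
  N <- I
  Dn <- I
  X <- I
  c_ <- 1
  for (k in seq_len(q)) {
    c_ <- c_ * (q - k + 1) / (k * (2 * q - k + 1))
    X <- A %*% X
    N <- N + c_ * X
    Dn <- Dn + (-1)^k * c_ * X
  }
  E <- solve(Dn, N)
  for (k in seq_len(j)) E <- E %*% E
  E
}

# One-step transition of the exact linear-Gaussian update: state mean A v,
# innovation covariance Q = S - A S A' where S is the stationary covariance.
exact_update_mats <- function(params, dt) {
  M <- drift_matrix(params)
  S <- stationary_cov(params)
  A <- expm_small(M * dt)
  Q <- S - A %*% S %*% t(A)
  Q <- (Q + t(Q)) / 2
  U <- tryCatch(chol(Q), error = function(e) {
    chol(Q + diag(3) * max(diag(Q)) * 1e-12)
  })
  list(A = A, U = U)
}

#' Simulate one realisation of the cascade
#'
#' Integrates the three-species Langevin system from the deterministic start
#' `x = y = z = 0`.  Two schemes are available: the Euler-Maruyama scheme
#' (`x <- x + drift * dt + sigma * sqrt(dt) * N(0,1)`, default step
#' `min(tau)/100`, refused above `min(tau)/50`), and the exact
#' linear-Gaussian transition sampler, which is exact at any step size
#' because the system is linear.
#'
#' Identical `(params, t_end, dt, seed, method)` give bit-identical output.
#'
#' @param params A [cascade_params()] object.
#' @param t_end Final time in minutes (> 0).  Snapped to a whole number of
#'   steps.
#' @param dt Time step in minutes; defaults to `min(tau)/100`.
#' @param seed Integer seed (required).
#' @param method `"euler"` or `"exact"`.
#' @return A tibble with columns `t`, `x`, `y`, `z` and attributes `dt`,
#'   `seed` and `method`.
#' @export
simulate_trajectory <- function(params, t_end, dt = NULL, seed,
                                method = c("euler", "exact")) {
  stopifnot(inherits(params, "cascade_params"))
  method <- match.arg(method)
  check_positive_scalar(t_end, "t_end")
  if (missing(seed)) rlang::abort("A `seed` is required for simulation.")
  dt <- dt %||% default_dt(params)
  check_positive_scalar(dt, "dt")
  if (method == "euler") check_euler_dt(params, dt)
  n <- max(1L, as.integer(round(t_end / dt)))

  noise <- withr::with_seed(seed, matrix(stats::rnorm(n * 3L), n, 3L))
  path <- if (method == "euler") {
    euler_path(params, noise, dt)
  } else {
    exact_path(params, noise, dt)
  }
  out <- tibble::tibble(
    t = seq(0, by = dt, length.out = n + 1L),
    x = path[, 1], y = path[, 2], z = path[, 3]
  )
  attr(out, "dt") <- dt
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  out
}

# Euler-Maruyama path from standard-normal increments (rows = steps).
euler_path <- function(params, noise, dt, v0 = c(0, 0, 0)) {
  s <- noise_amplitudes(params)
  n <- nrow(noise)
  out <- matrix(0, n + 1L, 3L)
  out[1L, ] <- v0
  x <- v0[1]; y <- v0[2]; z <- v0[3]
  sq <- sqrt(dt)
  tx <- params$tau_x; ty <- params$tau_y; tz <- params$tau_z
  gy <- params$g_y; gz <- params$g_z
  for (i in seq_len(n)) {
    x_new <- x - x / tx * dt + s[[1]] * sq * noise[i, 1]
    y_new <- y + (gy * x - y) / ty * dt + s[[2]] * sq * noise[i, 2]
    z_new <- z + (gz * x - z) / tz * dt + s[[3]] * sq * noise[i, 3]
    x <- x_new; y <- y_new; z <- z_new
    out[i + 1L, ] <- c(x, y, z)
  }
  out
}

exact_path <- function(params, noise, dt) {
  mats <- exact_update_mats(params, dt)
  A <- mats$A
  U <- mats$U
  n <- nrow(noise)
  out <- matrix(0, n + 1L, 3L)
  v <- c(0, 0, 0)
  for (i in seq_len(n)) {
    v <- drop(A %*% v) + drop(noise[i, , drop = FALSE] %*% U)
    out[i + 1L, ] <- v
  }
  out
}

#' Cross-sectional moments of an ensemble of trajectories
#'
#' Simulates `n` independent realisations (per-trajectory seeds derived
#' deterministically from the root `seed`, so trajectory `j` is identical to
#' `simulate_trajectory(..., seed = derive_seed(seed, j))`) and summarises
#' the cross-sectional distribution at each saved time.
#'
#' @inheritParams simulate_trajectory
#' @param n Ensemble size (>= 2; >= 100 recommended for variance summaries).
#' @param save_every Thin the time grid: save every `save_every`-th step.
#' @return A tibble with columns `t`, `n`, `mean_x`, `mean_y`, `mean_z`,
#'   `var_x`, `var_y`, `var_z`, `cov_yz`, `se_var_x` (Gaussian Monte-Carlo
#'   standard error of `var_x`, `var_x * sqrt(2/(n-1))`).
#' @export
simulate_ensemble <- function(params, n, t_end, dt = NULL, seed,
                              method = c("euler", "exact"), save_every = 1L) {
  stopifnot(inherits(params, "cascade_params"))
  method <- match.arg(method)
  if (!is.numeric(n) || n < 2) rlang::abort("`n` must be >= 2.")
  n <- as.integer(n)
  if (missing(seed)) rlang::abort("A `seed` is required for simulation.")
  dt <- dt %||% default_dt(params)
  if (method == "euler") check_euler_dt(params, dt)
  n_steps <- max(1L, as.integer(round(t_end / dt)))

  # Per-trajectory substreams, laid out exactly as simulate_trajectory draws
  # them (matrix(rnorm(n_steps * 3), n_steps, 3): column 1 = x noise, ...).
  NX <- matrix(0, n_steps, n)
  NY <- matrix(0, n_steps, n)
  NZ <- matrix(0, n_steps, n)
  for (j in seq_len(n)) {
    m <- withr::with_seed(
      derive_seed(seed, j),
      matrix(stats::rnorm(n_steps * 3L), n_steps, 3L)
    )
    NX[, j] <- m[, 1]; NY[, j] <- m[, 2]; NZ[, j] <- m[, 3]
  }

  s <- noise_amplitudes(params)
  tx <- params$tau_x; ty <- params$tau_y; tz <- params$tau_z
  gy <- params$g_y; gz <- params$g_z
  if (method == "exact") {
    mats <- exact_update_mats(params, dt)
    A <- mats$A; U <- mats$U
  }
  sq <- sqrt(dt)

  save_idx <- unique(c(seq(0L, n_steps, by = as.integer(save_every)), n_steps))
  keep <- logical(n_steps + 1L)
  keep[save_idx + 1L] <- TRUE
  rows <- vector("list", sum(keep))
  ri <- 0L

  summarise_state <- function(t, x, y, z) {
    vx <- stats::var(x)
    tibble::tibble(
      t = t, n = n,
      mean_x = mean(x), mean_y = mean(y), mean_z = mean(z),
      var_x = vx, var_y = stats::var(y), var_z = stats::var(z),
      cov_yz = stats::cov(y, z),
      se_var_x = vx * sqrt(2 / (n - 1))
    )
  }

  x <- y <- z <- numeric(n)
  if (keep[1L]) {
    ri <- ri + 1L
    rows[[ri]] <- summarise_state(0, x, y, z)
  }
  for (i in seq_len(n_steps)) {
    if (method == "euler") {
      x_new <- x - x / tx * dt + s[[1]] * sq * NX[i, ]
      y_new <- y + (gy * x - y) / ty * dt + s[[2]] * sq * NY[i, ]
      z_new <- z + (gz * x - z) / tz * dt + s[[3]] * sq * NZ[i, ]
      x <- x_new; y <- y_new; z <- z_new
    } else {
      E <- cbind(NX[i, ], NY[i, ], NZ[i, ]) %*% U
      x_new <- A[1, 1] * x + E[, 1]
      y_new <- A[2, 1] * x + A[2, 2] * y + A[2, 3] * z + E[, 2]
      z_new <- A[3, 1] * x + A[3, 2] * y + A[3, 3] * z + E[, 3]
      x <- x_new; y <- y_new; z <- z_new
    }
    if (keep[i + 1L]) {
      ri <- ri + 1L
      rows[[ri]] <- summarise_state(i * dt, x, y, z)
    }
  }
  dplyr::bind_rows(rows[seq_len(ri)])
}

#' Exact draws from the stationary distribution
#'
#' Samples i.i.d. vectors from the zero-mean Gaussian whose covariance is
#' the stationary Lyapunov solution ([stationary_cov()]).  Used to calibrate
#' estimators against a known joint distribution.
#'
#' @inheritParams simulate_ensemble
#' @return A tibble with `n` rows and columns `x`, `y`, `z`.
#' @export
sample_stationary <- function(params, n, seed) {
  stopifnot(inherits(params, "cascade_params"))
  if (!is.numeric(n) || n < 1) rlang::abort("`n` must be >= 1.")
  if (missing(seed)) rlang::abort("A `seed` is required for sampling.")
  U <- chol(stationary_cov(params))
  Z <- withr::with_seed(seed, matrix(stats::rnorm(n * 3L), n, 3L))
  V <- Z %*% U
  tibble::tibble(x = V[, 1], y = V[, 2], z = V[, 3])
}
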