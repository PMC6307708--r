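test_that("activator variance follows the Ornstein-Uhlenbeck closed form", {
  expect_equal(variance_x(0, 10), 0)
  expect_equal(variance_x(Inf, 10, sigma = 1), 5)
  expect_equal(
    variance_x(5, 10, sigma = constrained_sigma(10)),
    1 - exp(-1)
  )
  # monotone non-decreasing in t and in tau at fixed sigma
  t <- seq(0, 50, by = 1)
  expect_true(all(diff(variance_x(t, 7)) >= 0))
  taus <- c(1, 2, 5, 10, 20)
  at_t <- vapply(taus, function(tau) variance_x(8, tau), numeric(1))
  expect_true(all(diff(at_t) > 0))
  expect_error(variance_x(-1, 10), "non-negative")
})

test_that("transient moments match the matrix-exponential oracle", {
  for (seed in 1:4) {
    p <- random_params(seed)
    t_grid <- c(0, 0.5, 2, 5, 20, 60)
    mom <- transient_moments(p, t_grid)
    expect_equal(unlist(mom[1, 2:7]), rep(0, 6), ignore_attr = TRUE)
    for (i in seq_along(t_grid)) {
      oracle <- moment_oracle(p, t_grid[i])
      got <- cov_row_to_matrix(mom[i, ])
      expect_lt(max(abs(got - oracle)), 1e-8 * max(1, max(abs(oracle))))
    }
    # var_x trace equals the scalar closed form pointwise
    s <- noise_amplitudes(p)
    expect_equal(
      mom$var_x, variance_x(t_grid, p$tau_x, s[["x"]]),
      tolerance = 1e-10
    )
  }
  expect_error(transient_moments(random_params(1), c(3, 1)), "sorted")
  expect_error(transient_moments(random_params(1), c(-1, 2)), "non-negative")
})

test_that("transient moments relax to the stationary Lyapunov solution", {
  for (seed in c(2, 11, 23)) {
    for (mode in c("free", "constrained")) {
      p <- random_params(seed, sigma_mode = mode)
      t_star <- 20 * max(p$tau_x, p$tau_y, p$tau_z)
      mom <- transient_moments(p, c(0, t_star))
      Ct <- cov_row_to_matrix(mom[2, ])
      S <- stationary_cov(p)
      expect_lt(max(abs(Ct - S)) / max(abs(S)), 1e-6)
    }
  }
})

test_that("stationary moments satisfy decoupling, symmetry and Cauchy-Schwarz", {
  # zero gains decouple the species into independent OU processes
  p0 <- cascade_params(tau_x = 5, tau_y = 12, tau_z = 30, g_y = 0, g_z = 0,
                       sigma = 1.3)
  m0 <- stationary_moments(p0)
  expect_equal(m0$cov_xy, 0, tolerance = 1e-12)
  expect_equal(m0$cov_xz, 0, tolerance = 1e-12)
  expect_equal(m0$cov_yz, 0, tolerance = 1e-12)
  expect_equal(m0$var_y, 1.3^2 * 12 / 2, tolerance = 1e-10)

  # exchange symmetry of the two branches
  ps <- cascade_params(tau_x = 5, tau_y = 14, tau_z = 14, g_y = 0.8, g_z = 0.8)
  ms <- stationary_moments(ps)
  expect_equal(ms$var_y, ms$var_z, tolerance = 1e-12)
  expect_equal(ms$cov_xy, ms$cov_xz, tolerance = 1e-12)

  for (seed in 1:8) {
    m <- stationary_moments(random_params(seed))
    expect_true(all(c(m$var_x, m$var_y, m$var_z) >= 0))
    expect_lte(abs(m$cov_xy), sqrt(m$var_x * m$var_y) + 1e-12)
    expect_lte(abs(m$cov_xz), sqrt(m$var_x * m$var_z) + 1e-12)
    expect_lte(abs(m$cov_yz), sqrt(m$var_y * m$var_z) + 1e-12)
    expect_lte(abs(m$corr_yz), 1)
  }
})

test_that("stationary covariance agrees with a dynamically simulated ensemble", {
  p <- cascade_params(tau_x = 1, tau_y = 1, tau_z = 1, g_y = 1, g_z = 1)
  n <- 5000
  ens <- simulate_ensemble(p, n = n, t_end = 12, dt = 0.05, seed = 99,
                           method = "exact", save_every = 1000)
  S <- stationary_cov(p)
  last <- ens[nrow(ens), ]
  expect_lt(
    abs(last$cov_yz - S[2, 3]), 3 * se_cov(S[2, 2], S[3, 3], S[2, 3], n)
  )
  expect_lt(abs(last$var_x - S[1, 1]), 3 * last$se_var_x)
})

test_that("Gaussian mutual information formula and units behave", {
  expect_equal(gaussian_mi(0), 0)
  expect_equal(gaussian_mi(0.8), -0.5 * log(1 - 0.64))
  expect_equal(gaussian_mi(-0.8), gaussian_mi(0.8))
  expect_equal(gaussian_mi(0.8, units = "bits"), gaussian_mi(0.8) / log(2))
  rho <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(gaussian_mi(rho)) > 0))
  expect_true(all(gaussian_mi(seq(-0.9, 0.9, by = 0.1)) >= 0))
  expect_error(gaussian_mi(1), "< 1")
  expect_error(gaussian_mi(-1.2), "< 1")
})

test_that("downstream mutual information grows from zero to its steady state", {
  p <- params_default()
  t_grid <- c(0, 2^(0:9))
  mi <- mi_over_time(p, t_grid)
  expect_equal(mi$mi[1], 0)
  expect_true(all(diff(mi$mi) >= -1e-12))
  t_star <- 10 * max(p$tau_x, p$tau_y, p$tau_z)
  mi_end <- mi_over_time(p, c(0, t_star))$mi[2]
  expect_equal(mi_end, steady_state_mi(p), tolerance = 1e-6)

  # a disconnected branch transmits nothing at any time
  p0 <- cascade_params(tau_x = 10, tau_y = 20, tau_z = 20, g_y = 0)
  expect_equal(mi_over_time(p0, t_grid)$mi, rep(0, length(t_grid)),
               tolerance = 1e-12)
  expect_equal(steady_state_mi(p0), 0, tolerance = 1e-12)
})

test_that("steady-state information is symmetric and monotone in tau_x", {
  a <- cascade_params(tau_x = 6, tau_y = 9, tau_z = 31, g_y = 0.5, g_z = 1.7)
  b <- cascade_params(tau_x = 6, tau_y = 31, tau_z = 9, g_y = 1.7, g_z = 0.5)
  expect_equal(steady_state_mi(a), steady_state_mi(b), tolerance = 1e-12)

  taus <- 10^seq(-1, 2, length.out = 13)
  for (mode in c("free", "constrained")) {
    mi <- vapply(taus, function(tx) {
      steady_state_mi(cascade_params(
        tau_x = tx, tau_y = 20, tau_z = 20, sigma_mode = mode
      ))
    }, numeric(1))
    expect_true(all(diff(mi) > 0))
  }
})

test_that("cascade_information bundles tidy and glance summaries", {
  info <- cascade_information(params_default(sigma_mode = "constrained"))
  td <- tidy(info)
  expect_equal(nrow(td), 3)
  expect_true(all(td$estimate >= 0 | td$quantity == "corr_yz"))
  gl <- glance(info)
  expect_equal(gl$mi_nats, steady_state_mi(info$params))
  expect_equal(gl$sigma_mode, "constrained")
})
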