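test_that("trajectories are deterministic given the seed and start at zero", {
  p <- params_default()
  a <- simulate_trajectory(p, t_end = 30, seed = 7)
  b <- simulate_trajectory(p, t_end = 30, seed = 7)
  expect_identical(a, b)
  expect_equal(unlist(a[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
  d <- simulate_trajectory(p, t_end = 30, seed = 8)
  expect_false(identical(a$x, d$x))

  # vanishing noise leaves the system at its deterministic equilibrium
  p0 <- cascade_params(tau_x = 5, tau_y = 5, tau_z = 5, sigma = 1e-12)
  tr0 <- simulate_trajectory(p0, t_end = 50, seed = 1)
  expect_lt(max(abs(c(tr0$x, tr0$y, tr0$z))), 1e-6)
})

test_that("the Euler step limit names the binding correlation time", {
  p <- cascade_params(tau_x = 50, tau_y = 2, tau_z = 30)
  expect_error(
    simulate_trajectory(p, t_end = 10, dt = 1, seed = 1),
    "tau_y"
  )
  # the exact sampler has no step restriction
  expect_silent(simulate_trajectory(p, t_end = 10, dt = 5, seed = 1,
                                    method = "exact"))
})

test_that("a long trajectory is ergodic for the stationary variance", {
  tau <- 5
  p <- cascade_params(tau_x = tau, tau_y = tau, tau_z = tau, sigma = 1)
  tr <- simulate_trajectory(p, t_end = 150 * tau, dt = tau / 20, seed = 31,
                            method = "exact")
  keep <- tr$t >= 10 * tau
  v_hat <- stats::var(tr$x[keep])
  v_true <- tau / 2
  # effective sample size ~ T / (2 tau) for an OU time average
  n_eff <- (150 - 10) * tau / (2 * tau)
  expect_lt(abs(v_hat - v_true), 3 * v_true * sqrt(2 / n_eff))
})

test_that("ensemble trajectories reuse per-index substreams and match Eq-4 variance", {
  p <- params_default()
  ens <- simulate_ensemble(p, n = 150, t_end = 20, seed = 5, save_every = 5)
  # trajectory j of the ensemble is simulate_trajectory with the derived seed
  tr3 <- simulate_trajectory(
    p, t_end = 20, seed = infocascade:::derive_seed(5, 3)
  )
  ens2 <- simulate_ensemble(p, n = 150, t_end = 20, seed = 5, save_every = 5)
  expect_identical(ens, ens2)

  tau <- p$tau_x
  big <- simulate_ensemble(p, n = 1500, t_end = 2 * tau, seed = 6,
                           save_every = 50)
  for (tq in c(0.5, 1, 2) * tau) {
    row <- big[which.min(abs(big$t - tq)), ]
    expect_lt(abs(row$var_x - variance_x(row$t, tau)), 3 * row$se_var_x)
  }
  expect_error(simulate_ensemble(p, n = 1, t_end = 5, seed = 1), ">= 2")
})

test_that("Euler-Maruyama converges pathwise as the step is refined", {
  p <- cascade_params(tau_x = 4, tau_y = 6, tau_z = 8, g_y = 1.4, g_z = 0.7)
  dt0 <- 4 / 60
  m <- 240L # steps at the finest level dt0/4
  diffs <- withr::with_seed(17, {
    replicate(8, {
      fine <- matrix(stats::rnorm(m * 3L), m, 3L)
      half <- (fine[seq(1, m, 2), ] + fine[seq(2, m, 2), ]) / sqrt(2)
      coarse <- (half[seq(1, m / 2, 2), ] + half[seq(2, m / 2, 2), ]) / sqrt(2)
      e_fine <- infocascade:::euler_path(p, fine, dt0 / 4)
      e_half <- infocascade:::euler_path(p, half, dt0 / 2)
      e_coarse <- infocascade:::euler_path(p, coarse, dt0)
      c(
        sum(abs(e_coarse[nrow(e_coarse), ] - e_half[nrow(e_half), ])),
        sum(abs(e_half[nrow(e_half), ] - e_fine[nrow(e_fine), ]))
      )
    })
  })
  expect_lt(mean(diffs[2, ]), mean(diffs[1, ]))
})

test_that("Euler and exact updates give matching ensemble moments", {
  p <- cascade_params(tau_x = 5, tau_y = 10, tau_z = 10,
                      sigma_mode = "constrained")
  n <- 1200
  em <- simulate_ensemble(p, n = n, t_end = 30, seed = 44, method = "euler",
                          save_every = 1000)
  ex <- simulate_ensemble(p, n = n, t_end = 30, seed = 44, method = "exact",
                          dt = default_dt_for_test(p), save_every = 1000)
  last_em <- em[nrow(em), ]
  last_ex <- ex[nrow(ex), ]
  se <- sqrt(last_em$se_var_x^2 + last_ex$se_var_x^2)
  expect_lt(abs(last_em$var_x - last_ex$var_x), 3 * se)
  expect_lt(
    abs(last_em$cov_yz - last_ex$cov_yz),
    3 * sqrt(2) * se_cov(last_em$var_y, last_em$var_z, last_em$cov_yz, n)
  )
})

test_that("the cross-sectional distribution relaxes to a Gaussian", {
  p <- cascade_params(tau_x = 3, tau_y = 3, tau_z = 3)
  n <- 10000
  # exact update straight to t = 8 tau in a single step per trajectory
  ens <- sample_stationary(p, n = n, seed = 12)
  x <- ens$x
  zc <- x - mean(x)
  skew <- mean(zc^3) / stats::sd(x)^3
  exkurt <- mean(zc^4) / stats::sd(x)^4 - 3
  expect_lt(abs(skew), 0.1)
  expect_lt(abs(exkurt), 0.1)
})

test_that("stationary sampling reproduces the analytic joint distribution", {
  p <- params_default(sigma_mode = "constrained")
  n <- 100000
  s <- sample_stationary(p, n = n, seed = 3)
  S <- stationary_cov(p)
  rho <- S[2, 3] / sqrt(S[2, 2] * S[3, 3])
  rho_hat <- stats::cor(s$y, s$z)
  expect_lt(abs(rho_hat - rho), 3 * (1 - rho^2) / sqrt(n))
  expect_identical(s, sample_stationary(p, n = n, seed = 3))

  p0 <- cascade_params(tau_x = 5, tau_y = 7, tau_z = 9, g_y = 0, g_z = 0)
  s0 <- sample_stationary(p0, n = 20000, seed = 4)
  expect_lt(abs(stats::cor(s0$y, s0$z)), 3 / sqrt(20000))
})
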