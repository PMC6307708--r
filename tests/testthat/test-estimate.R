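test_that("coefficient of variation is the scale-free sd/mean", {
  expect_equal(coefficient_of_variation(c(5, 5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), sqrt(2) / 3)
  s <- c(3.2, 7.1, 4.4, 9.0, 5.5)
  expect_equal(
    coefficient_of_variation(7 * s), coefficient_of_variation(s)
  )
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-3, 1)), "positive")
})

test_that("KSG estimator is calibrated against the Gaussian closed form", {
  n <- 2000
  seeds <- 1:10
  for (rho in c(0, 0.6)) {
    est <- vapply(seeds, function(s) {
      g <- correlated_gaussian(n, rho, seed = s)
      ksg_mi(g$u, g$v, k = 3)
    }, numeric(1))
    expect_lt(abs(mean(est) - gaussian_mi(rho)), 0.03)
  }
})

test_that("KSG estimates are invariant under monotone marginal transforms", {
  g <- correlated_gaussian(2000, 0.6, seed = 42)
  base <- ksg_mi(g$u, g$v)
  warped <- ksg_mi(exp(g$u), g$v^3)
  expect_lt(abs(base - warped), 0.03)
})

test_that("KSG input contracts: size, degeneracy, tie handling, determinism", {
  expect_error(ksg_mi(1:4, 1:4, k = 3), "n > k")
  expect_error(ksg_mi(rep(1, 50), rnorm(50)), "constant")
  g <- correlated_gaussian(500, 0.5, seed = 1)
  expect_identical(ksg_mi(g$u, g$v), ksg_mi(g$u, g$v))
  # heavy ties are broken deterministically, not fatally
  u_tied <- round(g$u, 1)
  expect_identical(ksg_mi(u_tied, g$v), ksg_mi(u_tied, g$v))
  expect_lt(abs(ksg_mi(u_tied, g$v) - ksg_mi(g$u, g$v)), 0.1)
})

# deterministic snapshot fixture: two colonies, sizes 2 and 4, handmade values
fixture_snapshots <- function() {
  tibble::tibble(
    colony_id = c(1L, 1L, 2L, 2L, 2L, 2L),
    cell_id = c(1L, 2L, 1L, 2L, 3L, 4L),
    t_min = c(10, 10, 10, 10, 10, 10),
    colony_size = c(2L, 2L, 4L, 4L, 4L, 4L),
    ch_cfp = c(100, 300, 200, 200, 200, 200),
    ch_yfp = c(50, 150, 80, 120, 90, 110),
    ch_rfp = c(55, 145, 70, 130, 85, 115)
  )
}

test_that("binned CV reproduces hand-computed values and pooling semantics", {
  sn <- fixture_snapshots()
  b <- bin_by_colony_size(sn, statistic = "cv", channel = "ch_cfp",
                          bin_edges = c(2, 4, 8))
  expect_s3_class(b, "binned_stat")
  # colony 1 (size 2): sd(100,300)/200; colony 2 (size 4): constant -> 0
  expect_equal(b$value[b$bin_lo == 2], stats::sd(c(100, 300)) / 200)
  expect_equal(b$value[b$bin_lo == 4], 0)
  expect_equal(b$n_contrib, c(1L, 1L))

  # two identical replicates: same means, doubled contribution counts
  b2 <- bin_by_colony_size(list(sn, sn), statistic = "cv",
                           channel = "ch_cfp", bin_edges = c(2, 4, 8))
  expect_equal(b2$value, b$value)
  expect_equal(b2$n_contrib, 2L * b$n_contrib)

  # invariance to record order and channel rescaling
  shuffled <- sn[sample(nrow(sn)), ]
  b3 <- bin_by_colony_size(shuffled, statistic = "cv", channel = "ch_cfp",
                           bin_edges = c(2, 4, 8))
  expect_equal(b3$value, b$value)
  scaled <- dplyr::mutate(sn, ch_cfp = ch_cfp * 13.7)
  b4 <- bin_by_colony_size(scaled, statistic = "cv", channel = "ch_cfp",
                           bin_edges = c(2, 4, 8))
  expect_equal(b4$value, b$value)
})

test_that("binning skips undersized observations with a logged count", {
  sn <- dplyr::bind_rows(
    fixture_snapshots(),
    tibble::tibble(
      colony_id = 3L, cell_id = 1L, t_min = 0, colony_size = 1L,
      ch_cfp = 100, ch_yfp = 100, ch_rfp = 100
    )
  )
  expect_message(
    b <- bin_by_colony_size(sn, statistic = "cv", channel = "ch_cfp",
                            bin_edges = c(2, 4, 8)),
    "skipped"
  )
  expect_equal(attr(b, "skipped"), 1L)
  expect_equal(nrow(b), 2)
})

test_that("pooled MI by colony size recovers dependence strength", {
  # synthetic bins: small colonies carry independent channels, large ones
  # strongly correlated channels
  make_obs <- function(colony, t, size, rho, seed) {
    g <- correlated_gaussian(size, rho, seed = seed)
    tibble::tibble(
      colony_id = colony, cell_id = seq_len(size), t_min = t,
      colony_size = size,
      ch_cfp = 100, ch_yfp = 100 + 10 * g$u, ch_rfp = 100 + 10 * g$v
    )
  }
  sn <- dplyr::bind_rows(
    purrr::map(1:100, function(i) make_obs(i, 0, 6L, 0, seed = i)),
    purrr::map(1:40, function(i) make_obs(i, 10, 24L, 0.8, seed = 100 + i))
  )
  b <- bin_by_colony_size(sn, statistic = "mi", bin_edges = c(4, 16, 64))
  expect_equal(nrow(b), 2)
  mi_small <- b$value[b$bin_lo == 4]
  mi_large <- b$value[b$bin_lo == 16]
  expect_lt(abs(mi_small), 0.08)
  expect_gt(mi_large, gaussian_mi(0.8) - 0.1)
})

test_that("a short half-life coordinates sooner, a long one higher", {
  run_condition <- function(half_life, seed) {
    cfg <- colony_config(
      cascade_params(
        tau_x = half_life_to_tau(half_life),
        tau_y = 15 / log(2), tau_z = 15 / log(2),
        sigma_mode = "constrained"
      ),
      division_time = 15, t_end = 117, n_colonies = 5, seed = seed
    )
    sn <- simulate_microcolonies(cfg)
    suppressMessages(bin_by_colony_size(
      sn, statistic = "mi", bin_edges = 2^(1:8)
    ))
  }
  curves_2 <- sapply(1:4, function(r) run_condition(2, seed = 1000 + r)$value)
  curves_30 <- sapply(1:4, function(r) run_condition(30, seed = 2000 + r)$value)
  bins <- run_condition(2, seed = 1001)$bin_lo
  mean_2 <- rowMeans(curves_2)
  mean_30 <- rowMeans(curves_30)
  expect_gt(mean_30[length(mean_30)], mean_2[length(mean_2)])
  half_size <- function(v) bins[which(v >= v[length(v)] / 2)[1]]
  expect_lte(half_size(mean_2), half_size(mean_30))
})
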