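#' Configuration of a simulated growing microcolony experiment
#'
#' Describes the synthetic time-lapse experiment: a single founder cell at
#' its expression equilibrium grows into a microcolony by synchronous binary
#' fission every `division_time` minutes; every cell carries an independent
#' realisation of the latent cascade, daughters inherit the mother's
#' concentrations exactly at division (the model is in concentration units,
#' so no partitioning noise is added), and reporter fluorescence is observed
#' as `mean + gain * deviation` per channel so that fluorescence has a
#' non-zero mean and a coefficient of variation is defined.
#'
#' Default reporter means (500 AU) and gains (50 AU per deviation-unit) keep
#' mean/sd of fluorescence at or above 5 in the constrained noise mode, so
#' fluorescence is effectively positive.
#'
#' @param params A [cascade_params()] object for the latent dynamics.
#' @param division_time Cell division time in minutes (default 15).
#' @param t_end Duration of the experiment in minutes.  `t_end /
#'   division_time` must not exceed 20 (a population above 2^20 cells is
#'   refused).
#' @param n_colonies Number of replicate microcolonies.
#' @param reporter_means,reporter_gains Named numeric vectors over channels
#'   `cfp` (reports x), `yfp` (y), `rfp` (z).
#' @param division_jitter_sd Standard deviation (minutes) of optional
#'   per-cell division-time jitter; 0 (the default) gives the deterministic
#'   synchronous schedule in which the colony holds `2^floor(t /
#'   division_time)` cells at time `t`.
#' @param seed Default root seed used by [simulate_microcolonies()].
#' @return An object of class `colony_config`.
#' @export
colony_config <- function(params,
                          division_time = 15,
                          t_end = 60,
                          n_colonies = 1L,
                          reporter_means = c(cfp = 500, yfp = 500, rfp = 500),
                          reporter_gains = c(cfp = 50, yfp = 50, rfp = 50),
                          division_jitter_sd = 0,
                          seed = NULL) {
  stopifnot(inherits(params, "cascade_params"))
  check_positive_scalar(division_time, "division_time")
  check_positive_scalar(t_end, "t_end")
  if (!is.numeric(n_colonies) || n_colonies < 1) {
    rlang::abort("`n_colonies` must be >= 1.")
  }
  for (v in list(reporter_means, reporter_gains)) {
    if (!is.numeric(v) || !all(c("cfp", "yfp", "rfp") %in% names(v))) {
      rlang::abort("Reporter means/gains must be named over cfp, yfp, rfp.")
    }
  }
  if (any(reporter_means[c("cfp", "yfp", "rfp")] <= 0)) {
    rlang::abort("`reporter_means` must be strictly positive.")
  }
  if (division_jitter_sd < 0) rlang::abort("`division_jitter_sd` must be >= 0.")
  structure(
    list(
      params = params, division_time = division_time, t_end = t_end,
      n_colonies = as.integer(n_colonies),
      reporter_means = reporter_means[c("cfp", "yfp", "rfp")],
      reporter_gains = reporter_gains[c("cfp", "yfp", "rfp")],
      division_jitter_sd = division_jitter_sd,
      seed = seed
    ),
    class = "colony_config"
  )
}

#' Grow one microcolony as a lineage tree
#'
#' Simulates a founder cell starting at `(x, y, z) = (0, 0, 0)` at `t = 0`
#' and its descendants.  Each cell's latent dynamics follow the cascade SDE
#' over its lifetime (exact linear-Gaussian update by default, recorded at
#' `save_dt` resolution); at division the two daughters start from the
#' mother's final state exactly and receive independent noise streams
#' (seeds derived deterministically from `colony_seed` and the cell id, so
#' the result is reproducible and independent of traversal order).
#'
#' @param config A [colony_config()] object.
#' @param colony_seed Integer seed for this colony.
#' @param method `"exact"` (default; exact at any step) or `"euler"`.
#' @param dt Integration step for the Euler method (default `min(tau)/100`).
#' @param save_dt Recording resolution in minutes (default 3, emulating a
#'   3-minute imaging interval).
#' @return An object of class `lineage_tree`: a list with tibbles `cells`
#'   (`cell_id`, `parent_id`, `generation`, `birth_time`, `end_time`,
#'   `divided`) and `trajectories` (`cell_id`, `t`, `x`, `y`, `z`).
#' @export
grow_colony <- function(config, colony_seed, method = c("exact", "euler"),
                        dt = NULL, save_dt = 3) {
  stopifnot(inherits(config, "colony_config"))
  method <- match.arg(method)
  if (missing(colony_seed)) rlang::abort("A `colony_seed` is required.")
  if (config$t_end / config$division_time > 20) {
    rlang::abort(paste0(
      "t_end / division_time = ",
      format(config$t_end / config$division_time),
      " exceeds 20; refusing to grow a population above 2^20 cells."
    ))
  }
  params <- config$params
  t_end <- config$t_end
  Td <- config$division_time
  jit <- config$division_jitter_sd
  if (method == "euler") {
    dt <- dt %||% default_dt(params)
    check_euler_dt(params, dt)
  }

  mats_cache <- new.env(parent = emptyenv())
  get_mats <- function(step) {
    key <- format(step, digits = 15)
    if (is.null(mats_cache[[key]])) {
      mats_cache[[key]] <- exact_update_mats(params, step)
    }
    mats_cache[[key]]
  }

  # Simulate one cell over [t0, t1] from state v0; returns the recorded
  # trajectory (including both endpoints) and the exact final state.
  run_cell <- function(v0, t0, t1, seed) {
    life <- t1 - t0
    if (life <= 1e-12) {
      return(list(
        t = t0, states = matrix(v0, 1L, 3L), final = v0
      ))
    }
    if (method == "exact") {
      n_full <- floor(life / save_dt + 1e-9)
      rem <- life - n_full * save_dt
      steps <- c(rep(save_dt, n_full), if (rem > 1e-9) rem)
      noise <- withr::with_seed(
        seed, matrix(stats::rnorm(length(steps) * 3L), length(steps), 3L)
      )
      out <- matrix(0, length(steps) + 1L, 3L)
      out[1L, ] <- v0
      v <- v0
      for (i in seq_along(steps)) {
        m <- get_mats(steps[i])
        v <- drop(m$A %*% v) + drop(noise[i, , drop = FALSE] %*% m$U)
        out[i + 1L, ] <- v
      }
      list(t = t0 + cumsum(c(0, steps)), states = out, final = v)
    } else {
      n <- max(1L, as.integer(round(life / dt)))
      step <- life / n
      noise <- withr::with_seed(seed, matrix(stats::rnorm(n * 3L), n, 3L))
      path <- euler_path(params, noise, step, v0 = v0)
      save_t <- unique(c(seq(0, life, by = save_dt), life))
      idx <- pmin(n + 1L, round(save_t / step) + 1L)
      list(
        t = t0 + (idx - 1L) * step,
        states = path[idx, , drop = FALSE],
        final = path[n + 1L, ]
      )
    }
  }

  cell_rows <- list()
  traj_rows <- list()
  # breadth-first queue; heap ids (founder 1, daughters 2i and 2i + 1) make
  # per-cell seeds independent of processing order
  queue <- list(list(id = 1L, parent = NA_integer_, gen = 0L,
                     birth = 0, state = c(0, 0, 0)))
  while (length(queue) > 0) {
    cell <- queue[[1]]
    queue <- queue[-1]
    seed_i <- derive_seed(colony_seed, cell$id)
    lifespan <- if (jit > 0) {
      withr::with_seed(derive_seed(seed_i, 0L),
        max(Td + stats::rnorm(1, 0, jit), 0.2 * Td))
    } else {
      Td
    }
    div_t <- cell$birth + lifespan
    divides <- div_t <= t_end + 1e-9
    end_t <- if (divides) min(div_t, t_end) else t_end
    sim <- run_cell(cell$state, cell$birth, end_t, seed_i)
    cell_rows[[length(cell_rows) + 1L]] <- tibble::tibble(
      cell_id = cell$id, parent_id = cell$parent, generation = cell$gen,
      birth_time = cell$birth, end_time = end_t, divided = divides
    )
    traj_rows[[length(traj_rows) + 1L]] <- tibble::tibble(
      cell_id = cell$id, t = sim$t,
      x = sim$states[, 1], y = sim$states[, 2], z = sim$states[, 3]
    )
    if (divides) {
      for (d in 0:1) {
        queue[[length(queue) + 1L]] <- list(
          id = 2L * cell$id + d, parent = cell$id, gen = cell$gen + 1L,
          birth = end_t, state = sim$final
        )
      }
    }
  }
  structure(
    list(
      cells = dplyr::bind_rows(cell_rows),
      trajectories = dplyr::bind_rows(traj_rows),
      config = config, colony_seed = colony_seed
    ),
    class = "lineage_tree"
  )
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf(
    "<lineage_tree> %d cells over [0, %g] min (division time %g min)\n",
    nrow(x$cells), x$config$t_end, x$config$division_time
  ))
  invisible(x)
}

cells_alive_at <- function(tree, t) {
  cells <- tree$cells
  alive <- cells$birth_time <= t + 1e-9 &
    ifelse(cells$divided, t < cells$end_time - 1e-9, t <= cells$end_time + 1e-9)
  cells$cell_id[alive]
}

#' Per-cell snapshot table of one or more microcolonies
#'
#' Emulates the per-frame cell tables produced by cell-tracking software:
#' one record per living cell per observation time, with the colony size
#' (cell count at that time) and the reporter fluorescence of each channel,
#' `channel = mean + gain * latent deviation` (x maps to the CFP-like
#' channel, y to YFP, z to RFP).  Latent values are linearly interpolated
#' between recorded trajectory points when an observation time falls between
#' them; interpolation between correlated points attenuates variance, so for
#' quantitative variance work keep `t_grid` on the recording grid (`save_dt`
#' multiples, as the default is).
#'
#' @param trees A `lineage_tree` or list of them (one per colony).
#' @param t_grid Observation times within `[0, t_end]`; defaults to every
#'   3 minutes.
#' @param reporter_means,reporter_gains Channel calibration; default from
#'   each tree's config.
#' @param latent If `TRUE`, emit the latent deviations `x`, `y`, `z` instead
#'   of fluorescence channels.
#' @return A snapshot tibble with columns `colony_id`, `cell_id`, `t_min`,
#'   `colony_size` and either `ch_cfp`, `ch_yfp`, `ch_rfp` or `x`, `y`, `z`.
#' @export
snapshot <- function(trees, t_grid = NULL, reporter_means = NULL,
                     reporter_gains = NULL, latent = FALSE) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  if (length(trees) == 0) {
    return(empty_snapshot(latent))
  }
  purrr::imap_dfr(trees, function(tree, i) {
    stopifnot(inherits(tree, "lineage_tree"))
    cfg <- tree$config
    tg <- t_grid %||% seq(0, cfg$t_end, by = 3)
    if (any(tg < -1e-9) || any(tg > cfg$t_end + 1e-9)) {
      rlang::abort("`t_grid` must lie within [0, t_end].")
    }
    means <- reporter_means %||% cfg$reporter_means
    gains <- reporter_gains %||% cfg$reporter_gains
    traj_by_cell <- split(tree$trajectories, tree$trajectories$cell_id)
    alive_sets <- lapply(tg, function(t) cells_alive_at(tree, t))
    # times at which each cell is observed
    cell_times <- list()
    for (j in seq_along(tg)) {
      for (id in alive_sets[[j]]) {
        key <- as.character(id)
        cell_times[[key]] <- c(cell_times[[key]], tg[j])
      }
    }
    recs <- purrr::imap_dfr(cell_times, function(times, key) {
      tr <- traj_by_cell[[key]]
      interp <- function(col) {
        if (nrow(tr) == 1L) return(rep(tr[[col]], length(times)))
        stats::approx(tr$t, tr[[col]], xout = times, rule = 2)$y
      }
      tibble::tibble(
        colony_id = i, cell_id = as.integer(key), t_min = times,
        x = interp("x"), y = interp("y"), z = interp("z")
      )
    })
    if (nrow(recs) == 0) return(empty_snapshot(latent))
    recs <- recs |>
      dplyr::add_count(.data$t_min, name = "colony_size") |>
      dplyr::arrange(.data$t_min, .data$cell_id)
    if (latent) {
      dplyr::select(
        recs, "colony_id", "cell_id", "t_min", "colony_size", "x", "y", "z"
      )
    } else {
      recs |>
        dplyr::mutate(
          ch_cfp = means[["cfp"]] + gains[["cfp"]] * .data$x,
          ch_yfp = means[["yfp"]] + gains[["yfp"]] * .data$y,
          ch_rfp = means[["rfp"]] + gains[["rfp"]] * .data$z
        ) |>
        dplyr::select(
          "colony_id", "cell_id", "t_min", "colony_size",
          "ch_cfp", "ch_yfp", "ch_rfp"
        )
    }
  })
}

empty_snapshot <- function(latent = FALSE) {
  if (latent) {
    tibble::tibble(
      colony_id = integer(), cell_id = integer(), t_min = numeric(),
      colony_size = integer(), x = numeric(), y = numeric(), z = numeric()
    )
  } else {
    tibble::tibble(
      colony_id = integer(), cell_id = integer(), t_min = numeric(),
      colony_size = integer(), ch_cfp = numeric(), ch_yfp = numeric(),
      ch_rfp = numeric()
    )
  }
}

#' Simulate replicate microcolonies to a snapshot table
#'
#' Convenience wrapper: grows `config$n_colonies` independent colonies
#' (colony seeds derived from the root `seed`) and returns their combined
#' snapshot table.
#'
#' @inheritParams grow_colony
#' @param seed Root seed; defaults to `config$seed` and is required.
#' @param t_grid Observation times (default every 3 minutes).
#' @param latent Emit latent deviations instead of fluorescence.
#' @return A snapshot tibble (see [snapshot()]).
#' @export
simulate_microcolonies <- function(config, seed = config$seed, t_grid = NULL,
                                   method = c("exact", "euler"),
                                   latent = FALSE) {
  stopifnot(inherits(config, "colony_config"))
  method <- match.arg(method)
  if (is.null(seed)) rlang::abort("A `seed` is required for simulation.")
  trees <- purrr::map(
    seq_len(config$n_colonies),
    function(i) grow_colony(config, derive_seed(seed, i), method = method)
  )
  snapshot(trees, t_grid = t_grid, latent = latent)
}

#' Development of activator diversity in growing microcolonies
#'
#' Simulates `n_colonies` replicate microcolonies and tracks how the
#' variance of the latent activator deviation across the cells of a colony
#' grows with time, averaged over colonies with a standard error.  Division
#' resets nothing (daughters inherit concentrations), but shared ancestry
#' correlates cells, so the within-colony variance stays at or below the
#' no-division single-cell curve `variance_x(t)`, which is returned as the
#' column `var_bound` (the theoretical maximum).
#'
#' Colonies with fewer than two cells at a requested time (all colonies
#' before the first division) contribute no estimate there; the number of
#' excluded (colony, time) observations is reported via a message and the
#' `n_colonies_used` column.
#'
#' @inheritParams simulate_microcolonies
#' @param n_colonies Number of replicate colonies (>= 100 recommended for a
#'   stable standard error; fewer triggers a warning).
#' @param t_grid Times at which to evaluate the variance (default every 3
#'   minutes).
#' @param scope `"colony"` (default): variance within each colony, averaged
#'   across colonies.  `"population"`: a single variance across all cells of
#'   all colonies per time, which remains defined when colonies hold a
#'   single cell (e.g. with division times longer than the experiment).
#' @return A tibble of class `colony_variance_curve` with columns `t`,
#'   `mean_var`, `se`, `n_colonies_used`, `var_bound`.
#' @export
population_variance_curve <- function(config, n_colonies = config$n_colonies,
                                      seed, t_grid = NULL,
                                      scope = c("colony", "population"),
                                      method = c("exact", "euler")) {
  stopifnot(inherits(config, "colony_config"))
  scope <- match.arg(scope)
  method <- match.arg(method)
  if (missing(seed)) rlang::abort("A `seed` is required for simulation.")
  if (scope == "colony" && n_colonies < 100) {
    rlang::warn("Fewer than 100 colonies gives an unstable standard error.")
  }
  tg <- t_grid %||% seq(0, config$t_end, by = 3)
  snaps <- purrr::map_dfr(seq_len(n_colonies), function(i) {
    tree <- grow_colony(config, derive_seed(seed, i), method = method)
    snapshot(tree, t_grid = tg, latent = TRUE) |>
      dplyr::mutate(colony_id = i)
  })
  s <- noise_amplitudes(config$params)
  bound <- variance_x(tg, config$params$tau_x, s[["x"]])

  if (scope == "population") {
    out <- snaps |>
      dplyr::group_by(.data$t_min) |>
      dplyr::summarise(
        mean_var = stats::var(.data$x),
        se = NA_real_,
        n_colonies_used = dplyr::n_distinct(.data$colony_id),
        .groups = "drop"
      ) |>
      dplyr::rename(t = "t_min")
  } else {
    per_colony <- snaps |>
      dplyr::group_by(.data$colony_id, .data$t_min) |>
      dplyr::summarise(
        v = if (dplyr::n() >= 2) stats::var(.data$x) else NA_real_,
        .groups = "drop"
      )
    n_excluded <- sum(is.na(per_colony$v))
    if (n_excluded > 0) {
      rlang::inform(sprintf(
        "%d (colony, time) observations had < 2 cells and were excluded.",
        n_excluded
      ))
    }
    out <- per_colony |>
      dplyr::group_by(.data$t_min) |>
      dplyr::summarise(
        mean_var = mean(.data$v, na.rm = TRUE),
        se = stats::sd(.data$v, na.rm = TRUE) / sqrt(sum(!is.na(.data$v))),
        n_colonies_used = sum(!is.na(.data$v)),
        .groups = "drop"
      ) |>
      dplyr::rename(t = "t_min")
    out$mean_var[out$n_colonies_used == 0] <- NA_real_
    attr(out, "n_excluded") <- n_excluded
  }
  out$var_bound <- bound[match(out$t, tg)]
  class(out) <- c("colony_variance_curve", class(out))
  out
}
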