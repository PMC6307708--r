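#' Coefficient of variation of a fluorescence sample
#'
#' Sample standard deviation (n - 1 denominator) divided by the sample
#' mean.  Fluorescence has a non-zero mean, so the CV is a well-defined,
#' dimensionless measure of variability; dividing by the mean makes it
#' invariant to rescaling all values by a positive constant (e.g. microscope
#' gain).
#'
#' @param values Numeric sample with at least 2 values and positive mean.
#' @return Dimensionless CV.
#' @examples
#' coefficient_of_variation(c(2, 4)) # sqrt(2)/3
#' @export
coefficient_of_variation <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    rlang::abort("Need at least 2 values to compute a CV.")
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    rlang::abort("CV requires a strictly positive sample mean.")
  }
  stats::sd(values) / m
}

#' Kraskov k-nearest-neighbour mutual information estimator
#'
#' Non-parametric MI estimate between two continuous samples
#' (Kraskov-Stoegbauer-Grassberger algorithm 1): for each point, the
#' Chebyshev distance to its k-th nearest neighbour in the joint space sets
#' a scale, the strictly closer neighbours along each marginal are counted,
#' and
#' \deqn{\hat I = \psi(k) + \psi(n) -
#'   \langle \psi(n_u + 1) + \psi(n_v + 1) \rangle}
#' with \eqn{\psi} the digamma function.  Exactly tied coordinates break the
#' neighbour ranking, so duplicates are perturbed by a deterministic seeded
#' jitter of `jitter_scale` times the per-dimension interquartile range.
#'
#' @param u,v Numeric vectors of equal length `n > k + 1`.
#' @param k Neighbour count (default 3).
#' @param jitter_scale Relative amplitude of tie-breaking noise.
#' @param seed Seed for the tie-breaking jitter (deterministic default).
#' @return Mutual information estimate in nats (may be slightly negative
#'   for independent data; the estimator is approximately unbiased at 0).
#' @export
ksg_mi <- function(u, v, k = 3L, jitter_scale = 1e-10, seed = 20181227L) {
  if (!is.numeric(u) || !is.numeric(v) || length(u) != length(v)) {
    rlang::abort("`u` and `v` must be numeric vectors of equal length.")
  }
  n <- length(u)
  if (n <= k + 1) {
    rlang::abort(sprintf("Need n > k + 1 = %d samples; got %d.", k + 1L, n))
  }
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    rlang::abort("`u` and `v` must be finite.")
  }
  scale_u <- stats::IQR(u)
  scale_v <- stats::IQR(v)
  if (scale_u == 0 && stats::sd(u) == 0) {
    rlang::abort("`u` is constant; MI is undefined for degenerate support.")
  }
  if (scale_v == 0 && stats::sd(v) == 0) {
    rlang::abort("`v` is constant; MI is undefined for degenerate support.")
  }
  if (jitter_scale > 0 && (anyDuplicated(u) || anyDuplicated(v))) {
    jit <- withr::with_seed(seed, matrix(stats::rnorm(2L * n), n, 2L))
    u <- u + jitter_scale * max(scale_u, stats::sd(u)) * jit[, 1]
    v <- v + jitter_scale * max(scale_v, stats::sd(v)) * jit[, 2]
  }
  cnt <- ksg_neighbor_counts(u, v, as.integer(k))
  digamma(k) + digamma(n) -
    mean(digamma(cnt$n_u + 1) + digamma(cnt$n_v + 1))
}

#' Bin colony statistics by microcolony size
#'
#' The estimation pipeline applied to per-cell snapshot tables: every
#' (colony, time) observation yields a statistic computed across that
#' colony's cells -- the coefficient of variation of one channel, or the
#' mutual information between two channels -- and is assigned to a
#' colony-size bin (half-open intervals `[lo, hi)` over cell counts).
#' Replicate tables are concatenated before binning.
#'
#' For the CV, each contributing observation gives one value and the bin
#' reports their mean and standard error.  For MI the default (`pooled =
#' TRUE`) pools the cells of all observations in a bin and computes a single
#' Kraskov estimate per bin (standard error `NA`); with `pooled = FALSE` an
#' estimate is computed per observation with at least `k + 2` cells and
#' summarised like the CV.
#'
#' Observations too small for the statistic (fewer than 2 cells for CV,
#' `k + 2` for per-observation MI) are skipped; skipped counts are reported
#' in a message and in the `"skipped"` attribute, since the earliest frames
#' of a microcolony (one cell) are always skipped and a high correlation
#' among very few cells would otherwise be over-valued.
#'
#' @param snapshots A snapshot tibble (see [snapshot()]) or a list of
#'   replicate tibbles.
#' @param statistic `"cv"` or `"mi"`.
#' @param channel Channel for the CV (default `"ch_cfp"`).
#' @param channels Length-2 channel pair for MI (default YFP/RFP, the two
#'   downstream reporters).
#' @param bin_edges Strictly increasing colony-size bin edges; default
#'   powers of two `c(2, 4, 8, ..., 256)`.
#' @param pooled Pool cells across observations within a bin before
#'   estimating MI (default) or estimate per observation.
#' @param k Neighbour count for the MI estimator.
#' @return A tibble of class `binned_stat` with columns `bin_lo`, `bin_hi`,
#'   `bin_label`, `n_contrib`, `value`, `se`.
#' @export
bin_by_colony_size <- function(snapshots,
                               statistic = c("cv", "mi"),
                               channel = "ch_cfp",
                               channels = c("ch_yfp", "ch_rfp"),
                               bin_edges = 2^(1:8),
                               pooled = TRUE,
                               k = 3L) {
  statistic <- match.arg(statistic)
  if (is.data.frame(snapshots)) snapshots <- list(snapshots)
  tab <- dplyr::bind_rows(snapshots, .id = "replicate")
  if (nrow(tab) == 0) rlang::abort("Empty snapshot input.")
  if (is.unsorted(bin_edges, strictly = TRUE) || length(bin_edges) < 2) {
    rlang::abort("`bin_edges` must be strictly increasing with >= 2 edges.")
  }
  needed <- if (statistic == "cv") channel else channels
  missing_cols <- setdiff(
    c("replicate", "colony_id", "cell_id", "t_min", "colony_size", needed),
    names(tab)
  )
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "Snapshot table lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }

  min_cells <- if (statistic == "cv") 2L else as.integer(k) + 2L
  obs_sizes <- tab |>
    dplyr::distinct(
      .data$replicate, .data$colony_id, .data$t_min, .data$colony_size
    )
  # an observation is skipped if too small for the statistic (or, when
  # pooling, if it falls outside the binned size range entirely)
  too_small <- if (statistic == "mi" && pooled) bin_edges[1] else min_cells
  n_skipped <- sum(
    obs_sizes$colony_size < too_small |
      obs_sizes$colony_size >= bin_edges[length(bin_edges)]
  )

  tab <- tab |>
    dplyr::mutate(
      bin_idx = findInterval(.data$colony_size, bin_edges,
        rightmost.closed = FALSE
      )
    ) |>
    dplyr::filter(.data$bin_idx >= 1, .data$bin_idx < length(bin_edges))

  label_of <- function(idx) {
    sprintf("[%g,%g)", bin_edges[idx], bin_edges[idx + 1L])
  }

  if (statistic == "cv") {
    per_obs <- tab |>
      dplyr::group_by(
        .data$replicate, .data$colony_id, .data$t_min, .data$bin_idx
      ) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::summarise(
        value = coefficient_of_variation(.data[[channel]]),
        .groups = "drop"
      )
    out <- per_obs |>
      dplyr::group_by(.data$bin_idx) |>
      dplyr::summarise(
        n_contrib = dplyr::n(),
        se = stats::sd(.data$value) / sqrt(dplyr::n()),
        value = mean(.data$value),
        .groups = "drop"
      )
  } else if (pooled) {
    out <- tab |>
      dplyr::group_by(.data$bin_idx) |>
      dplyr::summarise(
        n_contrib = dplyr::n_distinct(
          paste(.data$replicate, .data$colony_id, .data$t_min)
        ),
        n_cells = dplyr::n(),
        value = if (dplyr::n() > k + 1) {
          ksg_mi(.data[[channels[1]]], .data[[channels[2]]], k = k)
        } else {
          NA_real_
        },
        se = NA_real_,
        .groups = "drop"
      ) |>
      dplyr::filter(!is.na(.data$value)) |>
      dplyr::select(-"n_cells")
  } else {
    per_obs <- tab |>
      dplyr::group_by(
        .data$replicate, .data$colony_id, .data$t_min, .data$bin_idx
      ) |>
      dplyr::filter(dplyr::n() >= min_cells) |>
      dplyr::summarise(
        value = ksg_mi(.data[[channels[1]]], .data[[channels[2]]], k = k),
        .groups = "drop"
      )
    out <- per_obs |>
      dplyr::group_by(.data$bin_idx) |>
      dplyr::summarise(
        n_contrib = dplyr::n(),
        se = stats::sd(.data$value) / sqrt(dplyr::n()),
        value = mean(.data$value),
        .groups = "drop"
      )
  }

  if (n_skipped > 0) {
    rlang::inform(sprintf(
      "%d (colony, time) observations below %d cells were skipped.",
      n_skipped, min_cells
    ))
  }
  out <- out |>
    dplyr::mutate(
      bin_lo = bin_edges[.data$bin_idx],
      bin_hi = bin_edges[.data$bin_idx + 1L],
      bin_label = label_of(.data$bin_idx)
    ) |>
    dplyr::arrange(.data$bin_lo) |>
    dplyr::select(
      "bin_lo", "bin_hi", "bin_label", "n_contrib", "value", "se"
    )
  attr(out, "skipped") <- n_skipped
  attr(out, "statistic") <- statistic
  class(out) <- c("binned_stat", class(out))
  out
}
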