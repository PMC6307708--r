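#' Convert a protein half-life to an Ornstein-Uhlenbeck correlation time
#'
#' A protein removed by first-order degradation/dilution with half-life
#' `half_life` decorrelates on the timescale `tau = half_life / ln(2)`.
#' `tau_to_half_life()` is the inverse.
#'
#' @param half_life Protein half-life in minutes (strictly positive).
#' @param tau Correlation time in minutes (strictly positive).
#' @return Correlation time (or half-life) in minutes, same length as input.
#' @examples
#' half_life_to_tau(30) # ~43.28 min
#' @export
half_life_to_tau <- function(half_life) {
  check_positive(half_life, "half_life")
  half_life / log(2)
}

#' @rdname half_life_to_tau
#' @export
tau_to_half_life <- function(tau) {
  check_positive(tau, "tau")
  tau * log(2)
}

#' Noise amplitude that fixes the stationary activator variance at one
#'
#' Returns `sqrt(2 / tau_x)`, the unique amplitude for which the stationary
#' variance of an Ornstein-Uhlenbeck process with correlation time `tau_x`
#' equals 1 (so `Var{X(t)} = 1 - exp(-2 t / tau_x)` at all times).  This is
#' the variance-constrained noise mode, which isolates the effect of the
#' activator's timescale from the effect of its fluctuation magnitude.
#'
#' @param tau_x Correlation time in minutes (strictly positive).
#' @return Noise amplitude in deviation-units * minutes^(-1/2).
#' @examples
#' constrained_sigma(2) # 1
#' constrained_sigma(8) # 0.5
#' @export
constrained_sigma <- function(tau_x) {
  check_positive(tau_x, "tau_x")
  sqrt(2 / tau_x)
}

#' Parameters of the linear activator cascade
#'
#' Defines the three-species Langevin model in which a stochastic activator
#' X (zero-mean deviations from steady state, correlation time `tau_x`)
#' drives two downstream proteins Y and Z:
#' \deqn{\dot x = -x/\tau_x + \sigma_x \eta_x}
#' \deqn{\dot y = (g_y x - y)/\tau_y + \sigma_y \eta_y}
#' \deqn{\dot z = (g_z x - z)/\tau_z + \sigma_z \eta_z}
#' with independent unit white noises \eqn{\eta}.
#'
#' Two noise modes are supported.  In `"free"` mode a single amplitude
#' `sigma` (default 1) applies to every species and the stationary activator
#' variance grows as `sigma^2 tau_x / 2`.  In `"constrained"` mode each
#' species' amplitude is inversely scaled with its own correlation time,
#' `sigma_i = sqrt(2 / tau_i)`, so the stationary variance contributed by
#' every intrinsic noise source is exactly 1 regardless of half-life; this is
#' the mode in which changing the activator half-life changes the timescale
#' of fluctuations but not their stationary magnitude.  Explicit `sigma_y` /
#' `sigma_z` overrides are accepted in either mode for sensitivity analysis.
#'
#' @param tau_x,tau_y,tau_z Correlation times in minutes (strictly positive).
#'   `tau = half_life / ln 2`; use [half_life_to_tau()] to convert.
#' @param g_y,g_z Dimensionless promoter gains of the two downstream genes.
#' @param sigma Noise amplitude of the activator
#'   (deviation-units * min^(-1/2)).  Defaults to 1 in free mode and to
#'   `constrained_sigma(tau_x)` in constrained mode; supplying any other
#'   value in constrained mode is an error.
#' @param sigma_mode `"free"` or `"constrained"`.
#' @param sigma_y,sigma_z Optional per-species overrides of the downstream
#'   noise amplitudes.
#' @return An object of class `cascade_params`.
#' @seealso [read_cascade_config()] to build parameters from a YAML file.
#' @examples
#' cascade_params(tau_x = half_life_to_tau(30), tau_y = 20, tau_z = 20)
#' cascade_params(tau_x = 5, tau_y = 20, tau_z = 20, sigma_mode = "constrained")
#' @export
cascade_params <- function(tau_x, tau_y = tau_x, tau_z = tau_y,
                           g_y = 1, g_z = 1,
                           sigma = NULL,
                           sigma_mode = c("free", "constrained"),
                           sigma_y = NULL, sigma_z = NULL) {
  sigma_mode <- match.arg(sigma_mode)
  for (nm in c("tau_x", "tau_y", "tau_z")) {
    check_positive_scalar(get(nm), nm)
  }
  for (nm in c("g_y", "g_z")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      rlang::abort(sprintf("`%s` must be a finite numeric scalar.", nm))
    }
  }
  if (sigma_mode == "constrained") {
    target <- sqrt(2 / tau_x)
    if (is.null(sigma)) {
      sigma <- target
    } else if (abs(sigma - target) > 1e-8 * target) {
      rlang::abort(paste0(
        "In constrained mode `sigma` must equal sqrt(2 / tau_x) = ",
        format(target), "; got ", format(sigma), "."
      ))
    }
  } else if (is.null(sigma)) {
    sigma <- 1
  }
  check_positive_scalar(sigma, "sigma")
  if (!is.null(sigma_y)) check_positive_scalar(sigma_y, "sigma_y")
  if (!is.null(sigma_z)) check_positive_scalar(sigma_z, "sigma_z")

  structure(
    list(
      tau_x = tau_x, tau_y = tau_y, tau_z = tau_z,
      g_y = g_y, g_z = g_z,
      sigma = sigma, sigma_mode = sigma_mode,
      sigma_y = sigma_y, sigma_z = sigma_z
    ),
    class = "cascade_params"
  )
}

#' Per-species noise amplitudes implied by a parameter set
#'
#' Resolves the `sigma_mode` and any per-species overrides into the three
#' amplitudes that enter the Langevin equations.
#'
#' @param params A [cascade_params()] object.
#' @return Named numeric vector `c(x = , y = , z = )`.
#' @export
noise_amplitudes <- function(params) {
  stopifnot(inherits(params, "cascade_params"))
  if (params$sigma_mode == "constrained") {
    base <- c(
      x = sqrt(2 / params$tau_x),
      y = sqrt(2 / params$tau_y),
      z = sqrt(2 / params$tau_z)
    )
  } else {
    base <- c(x = params$sigma, y = params$sigma, z = params$sigma)
  }
  if (!is.null(params$sigma_y)) base[["y"]] <- params$sigma_y
  if (!is.null(params$sigma_z)) base[["z"]] <- params$sigma_z
  base
}

#' @export
print.cascade_params <- function(x, ...) {
  s <- noise_amplitudes(x)
  cat("<cascade_params>\n")
  cat(sprintf(
    "  activator:  tau_x = %.4g min (half-life %.4g min), sigma_x = %.4g\n",
    x$tau_x, tau_to_half_life(x$tau_x), s[["x"]]
  ))
  cat(sprintf(
    "  downstream: tau_y = %.4g, tau_z = %.4g min; gains g_y = %.3g, g_z = %.3g\n",
    x$tau_y, x$tau_z, x$g_y, x$g_z
  ))
  cat(sprintf(
    "  noise mode: %s (sigma_y = %.4g, sigma_z = %.4g)\n",
    x$sigma_mode, s[["y"]], s[["z"]]
  ))
  invisible(x)
}

#' Read cascade parameters from a YAML configuration file
#'
#' Recognised keys: `tau_x` (or `half_life_x`), `tau_y` (or `half_life_y`),
#' `tau_z` (or `half_life_z`), `g_y`, `g_z`, `sigma`, `sigma_mode`,
#' `sigma_y`, `sigma_z`.  Exactly one of the `tau_*` / `half_life_*` pair
#' must be given per species; unknown keys are an error so that typos do not
#' silently fall back to defaults.
#'
#' @param path Path to a YAML file, or a named list already parsed.
#' @return A [cascade_params()] object.
#' @export
read_cascade_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) rlang::abort("Config must be a YAML mapping.")
  known <- c(
    "tau_x", "tau_y", "tau_z", "half_life_x", "half_life_y", "half_life_z",
    "g_y", "g_z", "sigma", "sigma_mode", "sigma_y", "sigma_z"
  )
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "Unknown parameter key(s): ", paste(bad, collapse = ", "),
      ". Known keys: ", paste(known, collapse = ", "), "."
    ))
  }
  tau_of <- function(sp, required = TRUE) {
    tk <- paste0("tau_", sp)
    hk <- paste0("half_life_", sp)
    if (!is.null(cfg[[tk]]) && !is.null(cfg[[hk]])) {
      rlang::abort(sprintf("Give `%s` or `%s`, not both.", tk, hk))
    }
    if (!is.null(cfg[[tk]])) return(cfg[[tk]])
    if (!is.null(cfg[[hk]])) return(half_life_to_tau(cfg[[hk]]))
    if (required) rlang::abort(sprintf("Missing `%s` (or `%s`).", tk, hk))
    NULL
  }
  tx <- tau_of("x")
  ty <- tau_of("y", required = FALSE) %||% tx
  tz <- tau_of("z", required = FALSE) %||% ty
  # exact [[ indexing: $ would let `sigma` partially match `sigma_mode`
  cascade_params(
    tau_x = tx, tau_y = ty, tau_z = tz,
    g_y = cfg[["g_y"]] %||% 1, g_z = cfg[["g_z"]] %||% 1,
    sigma = cfg[["sigma"]],
    sigma_mode = cfg[["sigma_mode"]] %||% "free",
    sigma_y = cfg[["sigma_y"]], sigma_z = cfg[["sigma_z"]]
  )
}

# --- internal validation helpers ---------------------------------------------

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    rlang::abort(sprintf("`%s` must be strictly positive and finite.", name))
  }
  invisible(x)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L) {
    rlang::abort(sprintf("`%s` must be a single number.", name))
  }
  check_positive(x, name)
}

check_time_grid <- function(t_grid) {
  if (!is.numeric(t_grid) || length(t_grid) == 0) {
    rlang::abort("`t_grid` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(t_grid)) || any(t_grid < 0)) {
    rlang::abort("`t_grid` must be finite and non-negative.")
  }
  if (is.unsorted(t_grid, strictly = FALSE)) {
    rlang::abort("`t_grid` must be sorted in increasing order.")
  }
  invisible(t_grid)
}
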