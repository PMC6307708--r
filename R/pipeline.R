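#' Run a complete analysis from a configuration file
#'
#' Executes one of the package's module chains from a YAML configuration and
#' writes its outputs, a log and a machine-readable run manifest to
#' `out_dir`.  The `command` key selects the chain:
#'
#' * `simulate` -- ensemble simulation of the cascade
#'   ([simulate_ensemble()]); writes `ensemble.tsv`.
#' * `colony` -- growing microcolonies ([simulate_microcolonies()],
#'   [population_variance_curve()]); writes `snapshots.tsv` and
#'   `variance_curve.tsv`.
#' * `sweep` -- rate-fidelity trade-off ([tradeoff_sweep()]); writes
#'   `tradeoff.tsv`.
#' * `estimate` -- binned CV/MI statistics from snapshot tables
#'   ([bin_by_colony_size()]); writes `binned_<statistic>.tsv`.
#' * `reproduce-figures` -- moment/MI time courses, the trade-off sweep and
#'   the colony variance curve, with plots rendered to PNG.
#'
#' Stochastic commands (`simulate`, `colony`, `reproduce-figures`, and
#' `estimate` when it simulates its own input) require a seed, given either
#' as the `seed` key or the `seed` argument; there is no silent default.
#'
#' @param config Path to a YAML file or an equivalent named list.  Keys:
#'   `command` (required); `params` (cascade parameter block, see
#'   [read_cascade_config()]); command-specific blocks documented in the
#'   vignette.
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed; overrides the config's `seed` key.
#' @param log_level `"info"` or `"quiet"`.
#' @return Invisibly, a list with the computed objects and the manifest.
#' @export
run_pipeline <- function(config, out_dir = ".", seed = NULL,
                         log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) rlang::abort("Config must be a YAML mapping.")
  known_top <- c(
    "command", "params", "seed", "simulate", "colony", "sweep",
    "estimate", "out_dir"
  )
  bad <- setdiff(names(cfg), known_top)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "Unknown config key(s): ", paste(bad, collapse = ", "),
      ". Known keys: ", paste(known_top, collapse = ", "), "."
    ))
  }
  command <- cfg[["command"]]
  commands <- c("simulate", "colony", "sweep", "estimate", "reproduce-figures")
  if (is.null(command) || !command %in% commands) {
    rlang::abort(paste0(
      "Config key `command` must be one of: ", paste(commands, collapse = ", "), "."
    ))
  }
  seed <- seed %||% cfg[["seed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    log_lines <<- c(log_lines, line)
    if (log_level == "info") message(line)
  }
  needs_seed <- command %in% c("simulate", "colony", "reproduce-figures") ||
    (command == "estimate" && is.null(cfg[["estimate"]][["snapshots"]]))
  if (needs_seed && is.null(seed)) {
    rlang::abort(paste0(
      "Command `", command,
      "` is stochastic and requires an explicit seed (key `seed` or argument)."
    ))
  }

  params <- if (!is.null(cfg[["params"]])) read_cascade_config(cfg[["params"]]) else NULL
  say("command: %s", command)
  if (!is.null(seed)) say("seed: %s", format(seed))

  results <- list()
  skipped <- 0L

  if (command == "simulate") {
    sc <- cfg[["simulate"]] %||% list()
    if (is.null(params)) rlang::abort("`simulate` requires a `params` block.")
    ens <- simulate_ensemble(
      params,
      n = sc[["n"]] %||% 1000L, t_end = sc[["t_end"]] %||% (5 * params$tau_x),
      dt = sc[["dt"]], seed = seed, method = sc[["method"]] %||% "euler",
      save_every = sc[["save_every"]] %||% 10L
    )
    readr::write_tsv(ens, file.path(out_dir, "ensemble.tsv"))
    say("wrote ensemble.tsv (%d time points, n = %d)", nrow(ens), ens$n[1])
    results$ensemble <- ens
  }

  if (command %in% c("colony", "reproduce-figures")) {
    cc <- cfg[["colony"]] %||% list()
    if (is.null(params)) rlang::abort("This command requires a `params` block.")
    config_obj <- colony_config(
      params,
      division_time = cc[["division_time"]] %||% 15,
      t_end = cc[["t_end"]] %||% 60,
      n_colonies = cc[["n_colonies"]] %||% 100L,
      division_jitter_sd = cc[["division_jitter_sd"]] %||% 0,
      seed = seed
    )
    snaps <- simulate_microcolonies(config_obj, seed = seed)
    readr::write_tsv(snaps, file.path(out_dir, "snapshots.tsv"))
    say("wrote snapshots.tsv (%d records, %d colonies)",
        nrow(snaps), config_obj$n_colonies)
    curve <- withCallingHandlers(
      population_variance_curve(config_obj, seed = derive_seed(seed, 10007L)),
      message = function(m) {
        say("%s", sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    )
    readr::write_tsv(curve, file.path(out_dir, "variance_curve.tsv"))
    say("wrote variance_curve.tsv")
    results$snapshots <- snaps
    results$variance_curve <- curve
    if (command == "reproduce-figures") {
      p <- plot_variance_curve(curve)
      ggplot2::ggsave(file.path(out_dir, "variance_curve.png"), p,
        width = 6, height = 4, dpi = 150
      )
      say("wrote variance_curve.png")
    }
  }

  if (command %in% c("sweep", "reproduce-figures")) {
    sw <- cfg[["sweep"]] %||% list()
    grid <- 10^seq(
      sw[["log10_tau_min"]] %||% -1, sw[["log10_tau_max"]] %||% 4,
      length.out = sw[["n_points"]] %||% 25L
    )
    base <- params
    sweep_tab <- tradeoff_sweep(
      grid, base_params = base,
      sigma_mode = sw[["sigma_mode"]] %||% "constrained"
    )
    readr::write_tsv(
      dplyr::as_tibble(sweep_tab), file.path(out_dir, "tradeoff.tsv")
    )
    say("wrote tradeoff.tsv (%d points)", nrow(sweep_tab))
    results$tradeoff <- sweep_tab
    if (command == "reproduce-figures") {
      ggplot2::ggsave(
        file.path(out_dir, "tradeoff.png"), ggplot2::autoplot(sweep_tab),
        width = 6, height = 4, dpi = 150
      )
      say("wrote tradeoff.png")
    }
  }

  if (command == "estimate") {
    ec <- cfg[["estimate"]] %||% list()
    if (!is.null(ec[["snapshots"]])) {
      paths <- ec[["snapshots"]]
      snaps <- purrr::map(paths, function(p) {
        readr::read_tsv(p, show_col_types = FALSE)
      })
      say("read %d snapshot table(s)", length(snaps))
    } else {
      if (is.null(params)) {
        rlang::abort("`estimate` without input tables requires a `params` block.")
      }
      cc <- cfg[["colony"]] %||% list()
      config_obj <- colony_config(
        params,
        division_time = cc[["division_time"]] %||% 15,
        t_end = cc[["t_end"]] %||% 60,
        n_colonies = cc[["n_colonies"]] %||% 5L,
        seed = seed
      )
      snaps <- simulate_microcolonies(config_obj, seed = seed)
      say("simulated %d colonies for estimation", config_obj$n_colonies)
    }
    statistic <- ec[["statistic"]] %||% "cv"
    binned <- withCallingHandlers(
      bin_by_colony_size(
        snaps,
        statistic = statistic,
        channel = ec[["channel"]] %||% "ch_cfp",
        channels = unlist(ec[["channels"]] %||% c("ch_yfp", "ch_rfp")),
        bin_edges = unlist(ec[["bin_edges"]] %||% 2^(1:8)),
        pooled = ec[["pooled"]] %||% TRUE,
        k = ec[["k"]] %||% 3L
      ),
      message = function(m) {
        say("%s", sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    )
    skipped <- attr(binned, "skipped") %||% 0L
    readr::write_tsv(
      dplyr::as_tibble(binned),
      file.path(out_dir, paste0("binned_", statistic, ".tsv"))
    )
    say("wrote binned_%s.tsv (%d bins, %d observations skipped)",
        statistic, nrow(binned), skipped)
    results$binned <- binned
  }

  manifest <- list(
    package = "infocascade",
    version = as.character(utils::packageVersion("infocascade")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    command = command,
    seed = seed,
    params = if (!is.null(params)) unclass(params) else NULL,
    config = cfg,
    skipped_observations = skipped,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
  writeLines(log_lines, log_path)
  invisible(c(results, list(manifest = manifest)))
}
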