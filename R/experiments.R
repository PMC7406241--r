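#' Experiment configuration
#'
#' Bundles simulation parameters with experiment-level settings: replicate
#' seeds, sweep grids and an output directory. Configurations round-trip
#' through flat JSON files ([read_golgi_config()], [write_golgi_config()])
#' so every output bundle can be reproduced from its config echo.
#'
#' @param params A [golgi_params()] object.
#' @param seeds Integer vector of distinct replicate seeds (the `seed`
#'   inside `params` is ignored by multi-seed drivers).
#' @param kb_grid,km_grid Sweep grids for [run_sweep()]; default 9
#'   log-spaced points spanning 1e-2 to 1e2 on each axis.
#' @param out_dir Output directory for the drivers (`NULL`: return results
#'   without writing).
#' @return A list of class `"golgi_config"`.
#' @export
golgi_config <- function(params = golgi_params(),
                         seeds = 1:3,
                         kb_grid = 10^seq(-2, 2, length.out = 9),
                         km_grid = 10^seq(-2, 2, length.out = 9),
                         out_dir = NULL) {
  stopifnot(inherits(params, "golgi_params"),
            length(seeds) >= 1, !anyDuplicated(seeds),
            length(kb_grid) >= 1, length(km_grid) >= 1)
  structure(list(params = params, seeds = as.integer(seeds),
                 kb_grid = kb_grid, km_grid = km_grid, out_dir = out_dir),
            class = "golgi_config")
}

#' @rdname golgi_config
#' @param path Path of a JSON config file.
#' @export
read_golgi_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  par_fields <- setdiff(names(formals(golgi_params)), "...")
  pars <- x[intersect(names(x), par_fields)]
  params <- do.call(golgi_params, pars)
  golgi_config(params,
               seeds = x$seeds %||% 1:3,
               kb_grid = x$kb_grid %||% 10^seq(-2, 2, length.out = 9),
               km_grid = x$km_grid %||% 10^seq(-2, 2, length.out = 9),
               out_dir = x$out_dir)
}

#' @rdname golgi_config
#' @param config A `golgi_config` object.
#' @export
write_golgi_config <- function(config, path) {
  flat <- c(unclass(config$params),
            list(seeds = config$seeds, kb_grid = config$kb_grid,
                 km_grid = config$km_grid, out_dir = config$out_dir))
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a tibble (or JSON-able list) atomically: temp file + rename
write_atomic <- function(x, path, json = FALSE) {
  tmp <- paste0(path, ".tmp")
  if (json) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    readr::write_csv(x, tmp)
  }
  file.rename(tmp, path)
  invisible(path)
}

#' Run a single reproducible simulation bundle
#'
#' Runs one simulation with the configured parameters and writes (when
#' `out_dir` is set) the standard artifact bundle: a config echo
#' (`config.json`), the scalar series (`series.csv`), the compartment
#' snapshots (`snapshots.csv`), the transport log (`transport.csv`), the
#' event log (`events.csv`, if recorded) and an observables summary
#' (`summary.json`). Files are written to a temporary name and renamed, so
#' a bundle is never partially overwritten.
#'
#' @param config A [golgi_config()] object (only `params` and `out_dir` are
#'   used).
#' @return The `golgi_sim` object, invisibly when writing to disk.
#' @export
run_single <- function(config) {
  stopifnot(inherits(config, "golgi_config"))
  sim <- golgi_simulate(config$params)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_golgi_config(config, out("config.json"))
    write_atomic(sim$series, out("series.csv"))
    write_atomic(sim$snapshots, out("snapshots.csv"))
    write_atomic(sim$transport, out("transport.csv"))
    if (!is.null(sim$events)) write_atomic(sim$events, out("events.csv"))
    write_atomic(as.list(glance(sim)), out("summary.json"), json = TRUE)
    write_atomic(list(
      schema_version = "1.0",
      series = names(sim$series),
      snapshots = names(sim$snapshots),
      transport = names(sim$transport),
      events = c("time", "kind", "identity", "id1", "id2", "cargo_moved")
    ), out("schema.json"), json = TRUE)
    return(invisible(sim))
  }
  sim
}

#' Phase-diagram sweep over budding and conversion rates
#'
#' Runs the simulator on the full `kb_grid` x `km_grid` grid for every
#' replicate seed, recalibrating the influx per grid point, and aggregates
#' the steady-state observables (typical size, system purity, mean and
#' relative SD of the total size) across seeds. Grid points are independent
#' and computed in a fixed order; a failing point is recorded with `NA`
#' values and does not abort the sweep.
#'
#' @param config A [golgi_config()] object.
#' @param .progress Print one line per grid point.
#' @return A list of class `"golgi_sweep"`: `runs` (one row per grid point
#'   and seed) and `summary` (mean and SD across seeds per grid point).
#'   Written as `sweep_runs.csv` / `sweep_summary.csv` when `out_dir` is
#'   set.
#' @export
run_sweep <- function(config, .progress = FALSE) {
  stopifnot(inherits(config, "golgi_config"))
  grid <- tidyr::expand_grid(kb = config$kb_grid, km = config$km_grid,
                             seed = config$seeds)
  runs <- purrr::pmap_dfr(grid, function(kb, km, seed) {
    base <- config$params
    point <- tryCatch({
      p <- golgi_params(
        kb = kb, km = km, n_target = base$n_target,
        alpha_er = base$alpha_er, alpha_tgn = base$alpha_tgn,
        budding_mode = base$budding_mode, fusion = base$fusion,
        t_max = base$t_max, t_burn = base$t_burn,
        sample_dt = base$sample_dt, snapshot_dt = base$snapshot_dt,
        seed = seed, cargo_mode = base$cargo_mode,
        cargo_time = base$cargo_time, cargo_n = base$cargo_n,
        cargo_frac = base$cargo_frac)
      glance(golgi_simulate(p))
    }, error = function(e) {
      warning(sprintf("sweep point kb=%g km=%g seed=%d failed: %s",
                      kb, km, seed, conditionMessage(e)), call. = FALSE)
      tibble(kb = kb, km = km, seed = seed)
    })
    if (.progress) message(sprintf("kb=%.3g km=%.3g seed=%d done", kb, km, seed))
    point
  })
  summary <- runs |>
    dplyr::group_by(.data$kb, .data$km) |>
    dplyr::summarise(
      dplyr::across(c("mean_size", "rel_sd_size", "typical_size",
                      "system_purity"),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~stats::sd(.x, na.rm = TRUE))),
      n_seeds = dplyr::n(), .groups = "drop")
  out <- structure(list(runs = runs, summary = summary, config = config),
                   class = "golgi_sweep")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_golgi_config(config, file.path(config$out_dir, "config.json"))
    write_atomic(runs, file.path(config$out_dir, "sweep_runs.csv"))
    write_atomic(summary, file.path(config$out_dir, "sweep_summary.csv"))
  }
  out
}

#' @export
print.golgi_sweep <- function(x, ...) {
  cat("<golgi_sweep>\n")
  cat(sprintf("  %d grid points x %d seeds\n", nrow(x$summary),
              length(x$config$seeds)))
  print(x$summary, n = 10)
  invisible(x)
}

#' Phase-diagram heat map
#'
#' @param sweep A `golgi_sweep` object.
#' @param metric Column of the sweep summary to display (default
#'   `"system_purity_mean"`; `"typical_size_mean"` gives the size diagram).
#' @return A ggplot heat map over (kb, km) on log axes.
#' @export
plot_phase_diagram <- function(sweep, metric = "system_purity_mean") {
  ggplot2::ggplot(sweep$summary,
                  ggplot2::aes(.data$kb, .data$km, fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "budding rate kb", y = "conversion rate km")
}

#' Pulse-chase experiment with replicate ensemble
#'
#' Injects a pulse of passive cargo at steady state (`cargo_time`, after
#' burn-in) in each of the replicate runs, follows the remaining-cargo
#' count, fits the ensemble-averaged decay with [exit_kinetics()], and
#' pools the transport logs for enrichment analysis.
#'
#' @param config A [golgi_config()] object; its seeds define the ensemble.
#' @param pulse_size Number of cargo in the pulse (default 50).
#' @return A list of class `"golgi_pulse"`: `decay` (ensemble-mean
#'   remaining fraction vs time), `fit` (decay rate and R^2), `enrichment`,
#'   `direction`, `transport` (pooled log), `per_seed` (injected/exited
#'   counts). CSV/JSON artifacts are written when `out_dir` is set.
#' @export
run_pulse_chase <- function(config, pulse_size = 50) {
  stopifnot(inherits(config, "golgi_config"))
  base <- config$params
  if (base$cargo_time < base$t_burn) {
    stop("Pulse before burn-in: set `cargo_time >= t_burn`.", call. = FALSE)
  }
  sims <- purrr::map(config$seeds, function(s) {
    p <- base
    p$seed <- as.integer(s)
    p$cargo_mode <- "pulse"
    p$cargo_n <- as.integer(pulse_size)
    golgi_simulate(p)
  })
  per_seed <- purrr::map2_dfr(sims, config$seeds, function(sim, s) {
    tibble(seed = s,
           cargo_injected = unname(sim$counters[["cargo_injected"]]),
           cargo_exited = unname(sim$counters[["cargo_exited_er"]] +
                                   sim$counters[["cargo_exited_tgn"]]))
  })
  decay <- purrr::map_dfr(sims, ~pulse_decay(.x)) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(remaining = mean(.data$remaining), .groups = "drop")
  # drop the loading front: fit from the ensemble peak onward
  peak <- which.max(decay$remaining)
  fit_data <- decay[peak:nrow(decay), ]
  fit_data$time <- fit_data$time - fit_data$time[1]
  fit <- exit_kinetics(fit_data)
  transport <- dplyr::bind_rows(
    purrr::map2(sims, config$seeds,
                ~dplyr::mutate(.x$transport, seed = .y)))
  enr <- tryCatch(enrichment_vector(transport), error = function(e) NULL)
  out <- structure(list(
    decay = decay, fit = fit, enrichment = enr,
    direction = if (!is.null(enr)) directionality(enr) else NA_character_,
    transport = transport, per_seed = per_seed, config = config
  ), class = "golgi_pulse")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_golgi_config(config, file.path(config$out_dir, "config.json"))
    write_atomic(decay, file.path(config$out_dir, "pulse_decay.csv"))
    write_atomic(transport, file.path(config$out_dir, "pulse_transport.csv"))
    write_atomic(c(as.list(fit),
                   if (!is.null(enr)) as.list(enr),
                   list(direction = out$direction)),
                 file.path(config$out_dir, "pulse_summary.json"), json = TRUE)
  }
  out
}

#' @export
print.golgi_pulse <- function(x, ...) {
  cat("<golgi_pulse>\n")
  cat(sprintf("  ensemble of %d runs, exit rate %.3g (R^2 = %.3f)\n",
              length(x$config$seeds), x$fit$rate, x$fit$r_squared))
  if (!is.null(x$enrichment)) {
    cat(sprintf("  enrichment E = (%.2f, %.2f, %.2f) -> %s\n",
                x$enrichment$e_cis, x$enrichment$e_medial,
                x$enrichment$e_trans, x$direction))
  }
  invisible(x)
}
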