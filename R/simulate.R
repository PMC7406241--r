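#' Run the exact stochastic simulator
#'
#' Simulates the full self-organisation model with the compiled Gillespie
#' engine: starting (by default) from an empty system, pure cis vesicles are
#' injected at rate `j`, compartments fuse homotypically with one another
#' and with the ER/TGN boundaries, shed pure vesicles by budding, and their
#' patches mature irreversibly cis to medial to trans. Waiting times are
#' exponential at the total propensity and one event fires at a time, so the
#' trajectory samples the exact law of the jump process. Identical `seed`
#' and parameters give a bitwise-identical trajectory.
#'
#' @param params A [golgi_params()] object.
#' @param init Optional compartment table to start from (default: empty
#'   system).
#' @return An object of class `"golgi_sim"`: a list with
#' \describe{
#'   \item{series}{tibble sampled every `sample_dt`: `time`,
#'     `n_compartments`, `n_total`, `n_cis`, `n_medial`, `n_trans`,
#'     `cargo_in_system`, `cargo_exited`.}
#'   \item{snapshots}{tibble of full compartment tables sampled every
#'     `snapshot_dt`.}
#'   \item{transport}{tibble of cargo-carrying vesicle transport episodes:
#'     donor composition at budding, acceptor composition at fusion, vesicle
#'     identity at fusion, cargo carried, back-fusion and boundary flags.}
#'   \item{events}{full event log (only when `record_events = TRUE`).}
#'   \item{final_state}{compartment table at `t_max`.}
#'   \item{counters}{named numeric: injected/exited patches and cargo,
#'     event counts.}
#'   \item{events_by_kind}{named numeric event tallies.}
#'   \item{params}{the parameter object.}
#' }
#' @examples
#' sim <- golgi_simulate(golgi_params(kb = 1, km = 1, n_target = 60,
#'                                    t_max = 5, t_burn = 1, seed = 42))
#' sim
#' @export
golgi_simulate <- function(params, init = NULL) {
  stopifnot(inherits(params, "golgi_params"))
  if (is.null(init)) {
    init <- data.frame(n_cis = integer(), n_medial = integer(),
                       n_trans = integer(), cargo = integer())
  }
  raw <- cpp_run(params_for_engine(params), as.data.frame(init))
  out <- list(
    series = as_tibble(raw$series),
    snapshots = as_tibble(raw$snapshots),
    transport = as_tibble(raw$transport),
    events = if (params$record_events) as_tibble(raw$events) else NULL,
    final_state = as_tibble(raw$final_state),
    counters = raw$counters,
    events_by_kind = raw$events_by_kind,
    params = params
  )
  class(out) <- "golgi_sim"
  out
}

#' @export
print.golgi_sim <- function(x, ...) {
  p <- x$params
  cat("<golgi_sim>\n")
  cat(sprintf("  kb = %g, km = %g, j = %g, t_max = %g, seed = %d\n",
              p$kb, p$km, p$j, p$t_max, p$seed))
  cat(sprintf("  events: %s\n",
              format(x$counters[["n_events"]], big.mark = ",")))
  fin <- x$final_state
  cat(sprintf("  final state: %d compartments, %d patches, %d cargo\n",
              nrow(fin), sum(fin$n_cis + fin$n_medial + fin$n_trans),
              sum(fin$cargo)))
  s <- steady_state_stats(x$series, p$t_burn)
  cat(sprintf("  steady-state size: %.1f +/- %.1f (rel SD %.1f%%) over t > %g\n",
              s$mean, s$sd, 100 * s$rel_sd, p$t_burn))
  invisible(x)
}

#' Tidy a simulation into its scalar time series
#'
#' @param x A `golgi_sim` object.
#' @param ... Unused.
#' @return The `series` tibble in long form: `time`, `quantity`, `value`.
#' @export
tidy.golgi_sim <- function(x, ...) {
  tidyr::pivot_longer(x$series, -"time", names_to = "quantity",
                      values_to = "value")
}

#' One-row summary of a simulation
#'
#' @param x A `golgi_sim` object.
#' @param ... Unused.
#' @return A one-row tibble: steady-state mean and relative SD of the total
#'   size, typical compartment size, mean system purity, event count.
#' @export
glance.golgi_sim <- function(x, ...) {
  p <- x$params
  s <- steady_state_stats(x$series, p$t_burn)
  ts <- tryCatch(typical_size(x$snapshots, p$t_burn), error = function(e) NA_real_)
  pur <- mean_system_purity(x$snapshots, p$t_burn)
  tibble(
    kb = p$kb, km = p$km, j = p$j, seed = p$seed,
    mean_size = s$mean, rel_sd_size = s$rel_sd,
    typical_size = ts, system_purity = pur,
    n_events = unname(x$counters[["n_events"]])
  )
}

#' Plot the species totals of a simulation
#'
#' @param object A `golgi_sim` object.
#' @param ... Unused.
#' @return A ggplot: total patches of each identity versus time.
#' @export
autoplot.golgi_sim <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$series[, c("time", "n_cis", "n_medial", "n_trans", "n_total")],
    -"time", names_to = "species", values_to = "patches")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$patches,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(
      n_cis = "#3B75AF", n_medial = "#EF8636", n_trans = "#519E3E",
      n_total = "grey30")) +
    ggplot2::labs(x = "time (1/Kf)", y = "patches", colour = NULL)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
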