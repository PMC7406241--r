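#' Simulation parameters
#'
#' Builds and validates the parameter set of the self-organisation model.
#' Time is measured in units of the inverse homotypic fusion rate (1/Kf), so
#' after normalisation the model has three kinetic parameters: the injection
#' rate `j`, the budding rate `kb` and the biochemical conversion rate `km`,
#' all dimensionless ratios to the fusion rate.
#'
#' When `j` is `NULL` it is calibrated from the target mean system size
#' `n_target` with [calibrate_influx()], the well-sorted mean-field inversion,
#' so that the steady-state total patch number fluctuates around `n_target`.
#'
#' @param kb Budding-to-fusion rate ratio (dimensionless, >= 0).
#' @param km Conversion-to-fusion rate ratio (dimensionless, >= 0). The same
#'   per-patch rate applies to both reactions (cis to medial, medial to trans).
#' @param n_target Target mean total system size, in membrane patches. Used to
#'   calibrate `j` when `j` is `NULL`.
#' @param j Injection-to-fusion rate ratio: rate at which new pure cis
#'   vesicles enter from the ER. `NULL` (default) derives it from `n_target`.
#' @param alpha_er,alpha_tgn Fraction of cis (resp. trans) identity patches in
#'   the ER (resp. TGN) boundary, in `[0, 1]`. They scale homotypic fusion
#'   with the boundaries, i.e. exit from the system.
#' @param budding_mode `"saturated"` (budding flux of every identity present
#'   equals `kb * n`, the saturated Michaelis-Menten regime) or `"linear"`
#'   (flux `kb * n_i` per identity).
#' @param fusion Logical; if `FALSE`, fusion between two compartments that
#'   are both larger than a vesicle is prohibited. Fusions involving a
#'   size-1 vesicle, and all boundary fusions, are kept, so vesicular
#'   exchange still operates.
#' @param t_max Simulation horizon, in units of 1/Kf.
#' @param t_burn Burn-in time discarded by steady-state observables; must be
#'   smaller than `t_max`.
#' @param sample_dt Sampling interval of the scalar time series.
#' @param snapshot_dt Sampling interval of full compartment snapshots.
#' @param seed Integer seed of the simulator's random stream.
#' @param cargo_mode `"none"`, `"pulse"` (tag the next `cargo_n` injected
#'   vesicles after `cargo_time` with one cargo each) or `"continuous"` (tag
#'   each injected vesicle after `cargo_time` with probability `cargo_frac`).
#'   Cargo molecules are passive labels: they never alter any propensity.
#' @param cargo_time Time at which cargo injection starts (defaults to
#'   `t_burn` so transport statistics sample the steady state).
#' @param cargo_n Pulse size (number of cargo) for `cargo_mode = "pulse"`.
#' @param cargo_frac Tagging probability for `cargo_mode = "continuous"`.
#' @param record_events Logical; keep the full event log (one row per
#'   elementary event). Off by default: logs can reach millions of rows.
#' @param check Logical; re-derive patch and cargo conservation from scratch
#'   after every event and stop on any violation. Used by the validation
#'   suite; costs O(compartments) per event.
#'
#' @return A list of class `"golgi_params"`.
#' @examples
#' p <- golgi_params(kb = 1, km = 1, n_target = 300, seed = 1)
#' p$j  # calibrated influx: 200
#' @export
golgi_params <- function(kb = 1, km = 1, n_target = 300, j = NULL,
                         alpha_er = 1, alpha_tgn = 1,
                         budding_mode = c("saturated", "linear"),
                         fusion = TRUE,
                         t_max = 100, t_burn = 20,
                         sample_dt = 0.1, snapshot_dt = 1,
                         seed = 1L,
                         cargo_mode = c("none", "pulse", "continuous"),
                         cargo_time = NULL, cargo_n = 0L, cargo_frac = 0,
                         record_events = FALSE, check = FALSE) {
  budding_mode <- match.arg(budding_mode)
  cargo_mode <- match.arg(cargo_mode)
  stopifnot(
    is.numeric(kb), length(kb) == 1, kb >= 0,
    is.numeric(km), length(km) == 1, km >= 0,
    is.numeric(alpha_er), alpha_er >= 0, alpha_er <= 1,
    is.numeric(alpha_tgn), alpha_tgn >= 0, alpha_tgn <= 1,
    is.numeric(t_max), t_max > 0,
    is.numeric(t_burn), t_burn >= 0,
    is.numeric(sample_dt), sample_dt > 0,
    is.numeric(snapshot_dt), snapshot_dt > 0,
    is.logical(fusion), is.logical(record_events), is.logical(check),
    cargo_n >= 0, cargo_frac >= 0, cargo_frac <= 1
  )
  if (t_burn >= t_max) {
    stop("`t_burn` must be smaller than `t_max`.", call. = FALSE)
  }
  if (is.null(j)) {
    stopifnot(is.numeric(n_target), n_target > 0)
    j <- calibrate_influx(n_target, km, alpha_er, alpha_tgn)
  } else {
    stopifnot(is.numeric(j), j >= 0)
  }
  if (is.null(cargo_time)) cargo_time <- t_burn
  structure(
    list(
      kb = as.numeric(kb), km = as.numeric(km), j = as.numeric(j),
      n_target = as.numeric(n_target),
      alpha_er = as.numeric(alpha_er), alpha_tgn = as.numeric(alpha_tgn),
      budding_mode = budding_mode, fusion = isTRUE(fusion),
      t_max = as.numeric(t_max), t_burn = as.numeric(t_burn),
      sample_dt = as.numeric(sample_dt), snapshot_dt = as.numeric(snapshot_dt),
      seed = as.integer(seed),
      cargo_mode = cargo_mode, cargo_time = as.numeric(cargo_time),
      cargo_n = as.integer(cargo_n), cargo_frac = as.numeric(cargo_frac),
      record_events = isTRUE(record_events), check = isTRUE(check)
    ),
    class = "golgi_params"
  )
}

#' @export
print.golgi_params <- function(x, ...) {
  cat("<golgi_params>\n")
  cat(sprintf("  kinetics : kb = %g, km = %g, j = %g (N target = %g)\n",
              x$kb, x$km, x$j, x$n_target))
  cat(sprintf("  exits    : alpha_ER = %g, alpha_TGN = %g\n",
              x$alpha_er, x$alpha_tgn))
  cat(sprintf("  modes    : budding %s, inter-compartment fusion %s\n",
              x$budding_mode, if (x$fusion) "on" else "off"))
  cat(sprintf("  horizon  : t_max = %g, burn-in = %g (units 1/Kf), seed = %d\n",
              x$t_max, x$t_burn, x$seed))
  if (x$cargo_mode != "none") {
    cat(sprintf("  cargo    : %s from t = %g", x$cargo_mode, x$cargo_time))
    if (x$cargo_mode == "pulse") cat(sprintf(" (pulse of %d)", x$cargo_n))
    if (x$cargo_mode == "continuous") cat(sprintf(" (fraction %g)", x$cargo_frac))
    cat("\n")
  }
  invisible(x)
}

# internal: params as the flat named list the C++ engine expects
params_for_engine <- function(params, seed = NULL) {
  stopifnot(inherits(params, "golgi_params"))
  p <- unclass(params)
  p$fusion_on <- as.integer(p$fusion)
  p$budding_linear <- as.integer(p$budding_mode == "linear")
  p$cargo_mode_code <- match(p$cargo_mode, c("none", "pulse", "continuous")) - 1L
  p$record_events <- as.integer(p$record_events)
  p$check <- as.integer(p$check)
  if (!is.null(seed)) p$seed <- as.integer(seed)
  p
}
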