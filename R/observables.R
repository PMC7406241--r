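#' Compartment size distribution and typical size
#'
#' Pools all compartments (vesicles included) from the post-burn-in
#' snapshots into a size histogram. The typical compartment size is the
#' ratio of the second over the first moment of the size distribution,
#' `<n^2>/<n>`; for the geometric-like distributions produced by the model
#' it sits close to half the exponential cut-off size.
#'
#' @param snapshots A snapshot tibble (`time`, `id`, `n_cis`, `n_medial`,
#'   `n_trans`, ...), e.g. `sim$snapshots`.
#' @param t_burn Snapshots at `time <= t_burn` are discarded.
#' @return A tibble with columns `n` (size), `count` and `freq`, and
#'   attribute `"typical_size"`; see also [typical_size()].
#' @export
size_distribution <- function(snapshots, t_burn = 0) {
  snaps <- dplyr::filter(as_tibble(snapshots), .data$time > t_burn)
  if (nrow(snaps) == 0) stop("No compartments after burn-in.", call. = FALSE)
  sizes <- snaps$n_cis + snaps$n_medial + snaps$n_trans
  hist <- dplyr::count(tibble(n = sizes), .data$n, name = "count")
  hist$freq <- hist$count / sum(hist$count)
  attr(hist, "typical_size") <- mean(sizes^2) / mean(sizes)
  hist
}

#' @rdname size_distribution
#' @return `typical_size()` returns the scalar `<n^2>/<n>`.
#' @examples
#' snaps <- tibble::tibble(time = 1, id = 1:5,
#'                         n_cis = c(1, 1, 1, 1, 4),
#'                         n_medial = 0L, n_trans = 0L)
#' typical_size(snaps)  # 2.5
#' @export
typical_size <- function(snapshots, t_burn = 0) {
  attr(size_distribution(snapshots, t_burn), "typical_size")
}

#' Size-weighted system purity
#'
#' The purity of the system is the purity of each compartment (distance of
#' its composition from perfectly mixed, see [purity()]) averaged over
#' compartments weighted by their size, ignoring vesicles (size-1
#' compartments, which are pure by construction and would otherwise swamp
#' the average).
#'
#' @param snapshots A snapshot tibble; purity is computed per snapshot time.
#' @param t_burn Snapshots at `time <= t_burn` are discarded.
#' @return A tibble with one row per snapshot time: `time`, `purity`,
#'   `n_weight` (total size of the non-vesicle compartments). Snapshot
#'   times with only vesicles get `NA` purity, with a warning.
#' @examples
#' snaps <- tibble::tibble(time = 1, id = 1:2, n_cis = c(2L, 3L),
#'                         n_medial = c(0L, 3L), n_trans = c(0L, 0L))
#' system_purity(snaps)  # (2*1 + 6*0.5) / 8 = 0.625
#' @export
system_purity <- function(snapshots, t_burn = 0) {
  snaps <- dplyr::filter(as_tibble(snapshots), .data$time > t_burn)
  if (nrow(snaps) == 0) stop("No snapshots after burn-in.", call. = FALSE)
  snaps$n <- snaps$n_cis + snaps$n_medial + snaps$n_trans
  snaps$p <- purity(snaps[, c("n_cis", "n_medial", "n_trans")])
  out <- snaps |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(purity = sum(.data$n * .data$p) / sum(.data$n),
                     n_weight = sum(.data$n), .groups = "drop")
  all_times <- dplyr::distinct(snaps, .data$time)
  out <- dplyr::left_join(all_times, out, by = "time")
  if (anyNA(out$purity)) {
    warning("Some snapshots contain only vesicles; system purity is ",
            "undefined there (NA).", call. = FALSE)
    out$n_weight[is.na(out$n_weight)] <- 0
  }
  out
}

#' @rdname system_purity
#' @return `mean_system_purity()` returns the time-average of the
#'   per-snapshot purity (snapshots with only vesicles dropped).
#' @export
mean_system_purity <- function(snapshots, t_burn = 0) {
  mean(system_purity(snapshots, t_burn)$purity, na.rm = TRUE)
}

#' Steady-state mean and fluctuations of a scalar series
#'
#' Time-average and relative standard deviation of the total system size
#' (or any sampled scalar) after burn-in. The model's size fluctuations
#' grow as budding slows: large, transient compartments exit in single
#' events, producing relative fluctuations of order 30% at `kb ~ 0.01`.
#'
#' @param series A series tibble with a `time` column, e.g. `sim$series`.
#' @param t_burn Samples at `time <= t_burn` are discarded.
#' @param var Name of the column to summarise (default `"n_total"`).
#' @param min_samples Minimum number of post-burn-in samples required.
#' @return A one-row tibble: `mean`, `sd`, `rel_sd`, `n_samples`.
#' @export
steady_state_stats <- function(series, t_burn = 0, var = "n_total",
                               min_samples = 10) {
  x <- dplyr::filter(as_tibble(series), .data$time > t_burn)[[var]]
  if (length(x) < min_samples) {
    stop("Fewer than ", min_samples, " samples after burn-in.", call. = FALSE)
  }
  m <- mean(x)
  s <- stats::sd(x)
  tibble(mean = m, sd = s, rel_sd = if (m > 0) s / m else NA_real_,
         n_samples = length(x))
}

#' Cargo enrichment vector of vesicular transport
#'
#' For every recorded transport episode (a cargo-carrying vesicle budding
#' from a donor and fusing with an acceptor) the composition difference
#' `dphi_i = phi_i(acceptor) - phi_i(donor)` is a number in `[-1, 1]` per
#' identity. Averaged over episodes — weighted by the cargo each vesicle
#' carries, or unweighted — this gives the enrichment vector `E`, whose
#' components are normalised for readability so that `sum_i |E_i| = 1`.
#' `E_cis < 0` with `E_trans > 0` signals anterograde transport, the
#' reverse retrograde; see [directionality()].
#'
#' @param transport A transport tibble (`sim$transport`).
#' @param weight `"cargo"` (default: an episode carrying c cargo counts c
#'   times) or `"event"` (each cargo-carrying episode counts once).
#' @param normalize Normalise so absolute components sum to 1 (default).
#' @param include_back_fusion Keep episodes whose acceptor is the original
#'   donor (default `TRUE`; they are genuine budding/fusion events, with
#'   near-zero composition difference).
#' @param include_boundary Keep episodes that end on the ER/TGN boundary
#'   (default `FALSE`: enrichment quantifies inter-compartment exchange).
#' @return A one-row tibble of class `"golgi_enrichment"`: `e_cis`,
#'   `e_medial`, `e_trans`, their raw (unnormalised) versions, `n_events`
#'   and `total_cargo`.
#' @export
enrichment_vector <- function(transport, weight = c("cargo", "event"),
                              normalize = TRUE, include_back_fusion = TRUE,
                              include_boundary = FALSE) {
  weight <- match.arg(weight)
  tr <- as_tibble(transport)
  if (!include_back_fusion) tr <- dplyr::filter(tr, !.data$back_fusion)
  if (!include_boundary) tr <- dplyr::filter(tr, .data$to_boundary == 0)
  tr <- dplyr::filter(tr, .data$cargo >= 1)
  if (nrow(tr) == 0) stop("No cargo-carrying transport events.", call. = FALSE)
  w <- if (weight == "cargo") tr$cargo else rep(1, nrow(tr))
  raw <- c(
    cis = stats::weighted.mean(tr$acceptor_phi_cis - tr$donor_phi_cis, w),
    medial = stats::weighted.mean(tr$acceptor_phi_medial - tr$donor_phi_medial, w),
    trans = stats::weighted.mean(tr$acceptor_phi_trans - tr$donor_phi_trans, w)
  )
  e <- raw
  if (normalize) {
    s <- sum(abs(raw))
    if (s == 0) {
      warning("Mean enrichment is the zero vector; normalisation undefined, ",
              "returning zeros.", call. = FALSE)
    } else {
      e <- raw / s
    }
  }
  out <- tibble(
    e_cis = e[["cis"]], e_medial = e[["medial"]], e_trans = e[["trans"]],
    raw_cis = raw[["cis"]], raw_medial = raw[["medial"]],
    raw_trans = raw[["trans"]],
    n_events = nrow(tr), total_cargo = sum(tr$cargo)
  )
  class(out) <- c("golgi_enrichment", class(out))
  out
}

#' Classify the directionality of vesicular transport
#'
#' Applies the sign rules to an enrichment vector: transport is
#' *anterograde* if `E_cis < 0` and `E_trans > 0`, *retrograde* if
#' `E_cis > 0` and `E_trans < 0`, *centripetal* (toward mixed/medial
#' compartments) if `E_medial` is the unique positive maximal component
#' while `E_cis <= 0` and `E_trans <= 0`, and *mixed* otherwise.
#'
#' @param e An enrichment vector: the tibble from [enrichment_vector()] or
#'   a numeric vector `c(e_cis, e_medial, e_trans)`.
#' @return A single string: `"anterograde"`, `"retrograde"`,
#'   `"centripetal"` or `"mixed"`.
#' @examples
#' directionality(c(-0.5, 0, 0.5))   # anterograde
#' directionality(c(-0.2, 0.6, -0.2)) # centripetal
#' @export
directionality <- function(e) {
  if (is.data.frame(e)) e <- c(e$e_cis, e$e_medial, e$e_trans)
  stopifnot(is.numeric(e), length(e) == 3)
  ec <- e[1]; em <- e[2]; et <- e[3]
  if (ec < 0 && et > 0) return("anterograde")
  if (ec > 0 && et < 0) return("retrograde")
  if (em > 0 && ec <= 0 && et <= 0 && em > ec && em > et) return("centripetal")
  "mixed"
}

#' Exponential exit kinetics of a cargo pulse
#'
#' Fits the decay of the remaining-cargo fraction after a pulse: a
#' least-squares fit of `log(fraction remaining)` against time since the
#' pulse. An exponential exit — as seen in FRAP and pulse-chase
#' experiments — gives a straight line; the fit returns the decay rate and
#' the coefficient of determination of the log-linear fit.
#'
#' @param decay A tibble with columns `time` and `remaining` (cargo counts
#'   or fractions; an ensemble mean works best). Points with
#'   `remaining <= 0` are dropped (log undefined).
#' @param min_points Minimum number of usable decay points (default 5).
#' @return A one-row tibble: `rate`, `r_squared`, `n_points`.
#' @examples
#' d <- tibble::tibble(time = 0:10, remaining = 50 * exp(-0.3 * (0:10)))
#' exit_kinetics(d)$rate  # 0.3
#' @export
exit_kinetics <- function(decay, min_points = 5) {
  d <- dplyr::filter(as_tibble(decay), .data$remaining > 0)
  if (nrow(d) < min_points) {
    stop("Need at least ", min_points, " positive decay points.", call. = FALSE)
  }
  fit <- stats::lm(log(remaining) ~ time, data = d)
  tibble(
    rate = -unname(stats::coef(fit)[["time"]]),
    r_squared = summary(fit)$r.squared,
    n_points = nrow(d)
  )
}

#' Remaining-cargo curve of a pulse run
#'
#' Extracts the remaining-in-system cargo count versus time since the pulse
#' from a simulation run with `cargo_mode = "pulse"`.
#'
#' @param sim A `golgi_sim` run with a cargo pulse.
#' @return A tibble with `time` (since the pulse start) and `remaining`.
#' @export
pulse_decay <- function(sim) {
  p <- sim$params
  if (p$cargo_mode != "pulse") stop("Not a pulse-chase run.", call. = FALSE)
  s <- dplyr::filter(sim$series, .data$time >= p$cargo_time)
  tibble(time = s$time - p$cargo_time, remaining = s$cargo_in_system)
}
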