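#' Regular barycentric bin grid on the composition simplex
#'
#' Compartment compositions live on the 2-simplex spanned by the pure cis,
#' medial and trans compositions. The grid places bin centers at all
#' lattice points `(i, j, k)/resolution` with `i + j + k = resolution`.
#'
#' @param resolution Number of bins per triangle edge (default 20).
#' @return A tibble with columns `bin`, `phi_cis`, `phi_medial`,
#'   `phi_trans` (the bin centers) and the cartesian plotting coordinates
#'   `x`, `y` (cis vertex at the origin, trans at (1, 0), medial at the
#'   apex).
#' @export
simplex_grid <- function(resolution = 20) {
  stopifnot(resolution >= 1)
  idx <- expand.grid(i = 0:resolution, j = 0:resolution)
  idx <- idx[idx$i + idx$j <= resolution, ]
  grid <- tibble(
    phi_cis = idx$i / resolution,
    phi_medial = idx$j / resolution,
    phi_trans = (resolution - idx$i - idx$j) / resolution
  )
  grid <- grid[order(-grid$phi_cis, -grid$phi_medial), ]
  grid$bin <- seq_len(nrow(grid))
  cart <- bary_to_cart(grid[, c("phi_cis", "phi_medial", "phi_trans")])
  dplyr::bind_cols(grid[, c("bin", "phi_cis", "phi_medial", "phi_trans")], cart)
}

#' @rdname simplex_grid
#' @param phi A data frame or matrix of compositions (columns cis, medial,
#'   trans).
#' @return `bary_to_cart()` returns a tibble with `x`, `y`.
#' @export
bary_to_cart <- function(phi) {
  phi <- as.matrix(phi)
  tibble(x = phi[, 3] + 0.5 * phi[, 2], y = sqrt(3) / 2 * phi[, 2])
}

# nearest-bin-center assignment; ties broken toward the lower bin index
assign_bins <- function(phi, grid) {
  phi <- as.matrix(phi)
  centers <- as.matrix(grid[, c("phi_cis", "phi_medial", "phi_trans")])
  # squared distance matrix (points x centers), small enough to be dense
  d2 <- outer(rowSums(phi^2), rep(1, nrow(centers))) -
    2 * phi %*% t(centers) +
    outer(rep(1, nrow(phi)), rowSums(centers^2))
  grid$bin[apply(d2, 1, which.min)]
}

#' Composition-simplex occupancy and cargo flux maps
#'
#' Bins the steady-state structure and the vesicular cargo fluxes in
#' barycentric composition space. Occupancy (per bin): the time-averaged
#' total patch content and compartment count of compartments whose
#' composition falls in the bin. Flux arrows (per donor bin): the base is
#' the bin center, the tip the cargo-weighted mean acceptor composition of
#' transport episodes leaving that bin; the weight is the cargo flux along
#' the path per unit time, normalised by the mean number of cargo in the
#' system. Back-fusion episodes and boundary exits are excluded from the
#' arrows.
#'
#' @param snapshots Snapshot tibble (`sim$snapshots`).
#' @param transport Transport tibble (`sim$transport`); may be `NULL` or
#'   empty, giving an empty arrow set.
#' @param t_burn Burn-in time; earlier snapshots/episodes are discarded.
#' @param resolution Bins per simplex edge (default 20).
#' @param series Optional series tibble used to normalise arrow weights by
#'   the time-averaged cargo content; without it, weights are normalised by
#'   the total cargo transported.
#' @return A list of class `"golgi_simplex"`: `occupancy` (bin table with
#'   `size_content` and `count`), `arrows` (donor bin, tip composition,
#'   `weight`, `cargo`, `n_events`), `grid`, `resolution`.
#' @export
simplex_maps <- function(snapshots, transport = NULL, t_burn = 0,
                         resolution = 20, series = NULL) {
  grid <- simplex_grid(resolution)
  snaps <- dplyr::filter(as_tibble(snapshots), .data$time > t_burn)
  if (nrow(snaps) == 0) stop("No snapshots after burn-in.", call. = FALSE)
  n_times <- dplyr::n_distinct(snaps$time)
  f <- comp_fractions(snaps)
  f$bin <- assign_bins(f[, c("phi_cis", "phi_medial", "phi_trans")], grid)
  occ <- f |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(size_content = sum(.data$n) / n_times,
                     count = dplyr::n() / n_times, .groups = "drop")
  occupancy <- dplyr::left_join(grid, occ, by = "bin")
  occupancy$size_content[is.na(occupancy$size_content)] <- 0
  occupancy$count[is.na(occupancy$count)] <- 0

  arrows <- tibble(bin = integer(), x = numeric(), y = numeric(),
                   tip_phi_cis = numeric(), tip_phi_medial = numeric(),
                   tip_phi_trans = numeric(), xend = numeric(),
                   yend = numeric(), weight = numeric(), cargo = numeric(),
                   n_events = integer())
  if (!is.null(transport) && nrow(transport) > 0) {
    tr <- as_tibble(transport) |>
      dplyr::filter(.data$time > t_burn, .data$cargo >= 1,
                    !.data$back_fusion, .data$to_boundary == 0)
    if (nrow(tr) > 0) {
      tr$bin <- assign_bins(
        tr[, c("donor_phi_cis", "donor_phi_medial", "donor_phi_trans")], grid)
      duration <- max(snaps$time) - t_burn
      norm <- if (!is.null(series)) {
        mean(dplyr::filter(as_tibble(series), .data$time > t_burn)$cargo_in_system)
      } else {
        sum(tr$cargo)
      }
      arrows <- tr |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(
          tip_phi_cis = stats::weighted.mean(.data$acceptor_phi_cis, .data$cargo),
          tip_phi_medial = stats::weighted.mean(.data$acceptor_phi_medial, .data$cargo),
          tip_phi_trans = stats::weighted.mean(.data$acceptor_phi_trans, .data$cargo),
          cargo = sum(.data$cargo), n_events = dplyr::n(), .groups = "drop") |>
        dplyr::mutate(weight = .data$cargo / duration / norm)
      base <- grid[match(arrows$bin, grid$bin), ]
      tip <- bary_to_cart(arrows[, c("tip_phi_cis", "tip_phi_medial",
                                     "tip_phi_trans")])
      arrows$x <- base$x
      arrows$y <- base$y
      arrows$xend <- tip$x
      arrows$yend <- tip$y
      arrows <- arrows[, c("bin", "x", "y", "tip_phi_cis", "tip_phi_medial",
                           "tip_phi_trans", "xend", "yend", "weight",
                           "cargo", "n_events")]
    }
  }
  structure(list(occupancy = occupancy, arrows = arrows, grid = grid,
                 resolution = resolution),
            class = "golgi_simplex")
}

#' @export
print.golgi_simplex <- function(x, ...) {
  cat("<golgi_simplex>\n")
  cat(sprintf("  resolution %d (%d bins), %d occupied, %d flux arrows\n",
              x$resolution, nrow(x$grid), sum(x$occupancy$count > 0),
              nrow(x$arrows)))
  invisible(x)
}

#' Plot a composition-simplex map
#'
#' @param object A `golgi_simplex` object from [simplex_maps()].
#' @param fill `"size_content"` or `"count"`: the occupancy measure shown.
#' @param ... Unused.
#' @return A ggplot: occupancy as coloured points on the triangle, flux
#'   arrows overlaid with opacity proportional to their cargo weight.
#' @export
autoplot.golgi_simplex <- function(object, fill = c("size_content", "count"),
                                   ...) {
  fill <- match.arg(fill)
  occ <- dplyr::filter(object$occupancy, .data[[fill]] > 0)
  corners <- tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = corners, ggplot2::aes(.data$x, .data$y),
                       colour = "grey60") +
    ggplot2::geom_point(data = occ,
                        ggplot2::aes(.data$x, .data$y, colour = .data[[fill]]),
                        size = 2) +
    ggplot2::scale_colour_viridis_c(trans = "sqrt") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::annotate("text", x = c(-0.03, 1.03, 0.5), y = c(-0.03, -0.03, 0.93),
                      label = c("cis", "trans", "medial"), size = 3.5)
  if (nrow(object$arrows) > 0) {
    arr <- object$arrows
    arr$alpha <- arr$weight / max(arr$weight)
    p <- p + ggplot2::geom_segment(
      data = arr,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$alpha),
      arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt")),
      colour = "black", show.legend = FALSE)
  }
  p
}
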