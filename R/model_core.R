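#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

# The three membrane identities, in strict maturation order. Conversion is
# irreversible (cis -> medial -> trans); trans has no successor.
GOLGI_IDENTITIES <- c("cis", "medial", "trans")

#' Identity labels and maturation order
#'
#' The model's three membrane identities in their strict, immutable
#' maturation order: cis, medial, trans. Biochemical conversion only ever
#' maps an identity to its successor; trans is terminal.
#'
#' @return Character vector `c("cis", "medial", "trans")`.
#' @export
golgi_identities <- function() GOLGI_IDENTITIES

#' Build a table of compartments
#'
#' A compartment is a membrane body made of integer numbers of cis, medial
#' and trans patches (total size `n >= 1`) plus a count of passive cargo.
#' Compartment tables are ordinary tibbles with one row per compartment;
#' all rate-law functions operate on them row-wise.
#'
#' @param n_cis,n_medial,n_trans Non-negative integer patch counts, recycled
#'   to a common length. Each row must total at least one patch.
#' @param cargo Non-negative cargo counts (default 0).
#' @param id Optional unique compartment identifiers (default sequential).
#' @return A tibble with columns `id`, `n_cis`, `n_medial`, `n_trans`,
#'   `cargo`.
#' @examples
#' compartment(n_cis = c(3, 0), n_medial = c(2, 0), n_trans = c(5, 1))
#' @export
compartment <- function(n_cis = 0, n_medial = 0, n_trans = 0, cargo = 0,
                        id = NULL) {
  out <- tibble(n_cis = as.integer(n_cis), n_medial = as.integer(n_medial),
                n_trans = as.integer(n_trans), cargo = as.integer(cargo))
  if (any(out$n_cis < 0 | out$n_medial < 0 | out$n_trans < 0 | out$cargo < 0)) {
    stop("Patch and cargo counts must be non-negative.", call. = FALSE)
  }
  if (any(out$n_cis + out$n_medial + out$n_trans < 1)) {
    stop("Every compartment must contain at least one patch.", call. = FALSE)
  }
  out$id <- if (is.null(id)) seq_len(nrow(out)) else id
  if (anyDuplicated(out$id)) stop("Compartment ids must be unique.", call. = FALSE)
  out[, c("id", "n_cis", "n_medial", "n_trans", "cargo")]
}

#' Compartment sizes and composition fractions
#'
#' Appends the total size `n` and the identity fractions
#' `phi_i = n_i / n` to a compartment table. The fractions lie on the
#' composition simplex: each is in `[0, 1]` and they sum to one.
#'
#' @param comps A compartment table (see [compartment()]).
#' @return The input tibble with extra columns `n`, `phi_cis`, `phi_medial`,
#'   `phi_trans`.
#' @export
comp_fractions <- function(comps) {
  comps <- as_tibble(comps)
  n <- comps$n_cis + comps$n_medial + comps$n_trans
  if (any(n < 1)) stop("Every compartment must contain at least one patch.", call. = FALSE)
  comps$n <- n
  comps$phi_cis <- comps$n_cis / n
  comps$phi_medial <- comps$n_medial / n
  comps$phi_trans <- comps$n_trans / n
  comps
}

phi_matrix <- function(comps) {
  f <- comp_fractions(comps)
  cbind(cis = f$phi_cis, medial = f$phi_medial, trans = f$phi_trans)
}

#' Homotypic fusion rate between two compartments
#'
#' Fusion is homotypic: its rate is proportional to the probability that the
#' two partners present the same identity at the contact site,
#' \deqn{K_f \sum_i \phi_i(a)\,\phi_i(b),}
#' with the fusion rate between identical compartments `Kf = 1` in
#' normalised units. Two pure compartments of the same identity fuse at rate
#' 1; orthogonal compositions never fuse. When inter-compartment fusion is
#' switched off in `params`, fusion between two compartments that are both
#' larger than a vesicle is prohibited (rate 0); fusions involving at least
#' one size-1 vesicle keep the homotypic law, so vesicular exchange — the
#' only remaining aggregation route — still operates.
#'
#' @param a,b Compartment tables of equal length (rates are computed
#'   row-wise). The same compartment may not appear on both sides of a row:
#'   self-fusion is undefined.
#' @param params A [golgi_params()] object (only the `fusion` toggle is
#'   used); `NULL` means fusion on.
#' @return Numeric vector of rates in `[0, 1]`, per unit time 1/Kf.
#' @examples
#' a <- compartment(n_cis = 2)
#' b <- compartment(n_cis = 5, id = 2)
#' fusion_rate(a, b)  # identical pure compositions: 1
#' @export
fusion_rate <- function(a, b, params = NULL) {
  a <- as_tibble(a); b <- as_tibble(b)
  if (nrow(a) != nrow(b)) stop("`a` and `b` must have the same number of rows.", call. = FALSE)
  if (!is.null(a$id) && !is.null(b$id) && any(a$id == b$id)) {
    stop("Self-fusion is undefined: the same compartment appears on both sides.",
         call. = FALSE)
  }
  r <- rowSums(phi_matrix(a) * phi_matrix(b))
  if (!is.null(params) && !params$fusion) {
    na <- a$n_cis + a$n_medial + a$n_trans
    nb <- b$n_cis + b$n_medial + b$n_trans
    r[na >= 2 & nb >= 2] <- 0
  }
  r
}

#' Fusion rate of a compartment with a boundary
#'
#' The ER and TGN boundaries follow the same homotypic rule as compartments:
#' the ER presents a fraction `alpha_er` of cis patches and the TGN a
#' fraction `alpha_tgn` of trans patches, so a compartment fuses with the ER
#' at rate `alpha_er * phi_cis` and with the TGN at rate
#' `alpha_tgn * phi_trans`. Boundary fusion removes the compartment from the
#' system: it is the only exit route.
#'
#' @param a A compartment table.
#' @param boundary `"er"` or `"tgn"`.
#' @param params A [golgi_params()] object supplying `alpha_er`/`alpha_tgn`,
#'   or a single numeric `alpha` via the `alpha` argument.
#' @param alpha Optional explicit homotypic fraction, overriding `params`.
#' @return Numeric vector of exit rates, per unit time 1/Kf.
#' @export
boundary_fusion_rate <- function(a, boundary = c("er", "tgn"), params = NULL,
                                 alpha = NULL) {
  boundary <- match.arg(boundary)
  if (is.null(alpha)) {
    if (is.null(params)) stop("Supply `params` or `alpha`.", call. = FALSE)
    alpha <- if (boundary == "er") params$alpha_er else params$alpha_tgn
  }
  stopifnot(alpha >= 0, alpha <= 1)
  phi <- phi_matrix(a)
  unname(alpha * phi[, if (boundary == "er") "cis" else "trans"])
}

#' Vesicle budding rates per identity
#'
#' Budding emits a pure, size-1 vesicle of one identity from any compartment
#' larger than a vesicle. In the default `"saturated"` mode the budding flux
#' of every identity *present* in the compartment equals `kb * n` regardless
#' of its abundance (the saturated regime of Michaelis-Menten kinetics, with
#' budding machinery finding any target patch by diffusion). In `"linear"`
#' mode the flux is proportional to abundance, `kb * n_i`. Size-1
#' compartments never bud in either mode.
#'
#' @param a A compartment table.
#' @param params A [golgi_params()] object (`kb`, `budding_mode`).
#' @return A tibble with one row per compartment and columns `cis`,
#'   `medial`, `trans` holding the per-identity budding rates.
#' @examples
#' p <- golgi_params(kb = 1)
#' budding_rates(compartment(3, 2, 5), p)  # saturated: 10 for each identity
#' @export
budding_rates <- function(a, params) {
  f <- comp_fractions(a)
  counts <- cbind(f$n_cis, f$n_medial, f$n_trans)
  eligible <- f$n >= 2
  r <- switch(params$budding_mode,
    saturated = (counts >= 1) * f$n * params$kb,
    linear = counts * params$kb,
    stop("Unknown budding mode.", call. = FALSE)
  )
  r <- r * eligible
  tibble(cis = r[, 1], medial = r[, 2], trans = r[, 3])
}

#' Biochemical conversion rates
#'
#' Each membrane patch independently undergoes irreversible conversion
#' cis -> medial -> trans at per-patch rate `km` (the same for both
#' reactions). For a compartment the two reaction propensities are therefore
#' `km * n_cis` (cis to medial) and `km * n_medial` (medial to trans); trans
#' is terminal. Free vesicles convert like any other compartment, so a cis
#' vesicle can mature before it fuses.
#'
#' @param a A compartment table.
#' @param params A [golgi_params()] object (`km`).
#' @return A tibble with columns `cis_to_medial`, `medial_to_trans` and
#'   `total`.
#' @export
conversion_rates <- function(a, params) {
  a <- as_tibble(a)
  tibble(
    cis_to_medial = params$km * a$n_cis,
    medial_to_trans = params$km * a$n_medial,
    total = params$km * (a$n_cis + a$n_medial)
  )
}

#' Compartment purity
#'
#' Purity measures how far a compartment's composition is from the perfectly
#' mixed point `(1/3, 1/3, 1/3)`, as a normalised Euclidean distance on the
#' composition simplex:
#' \deqn{P = \sqrt{\tfrac{3}{2} \sum_i (\phi_i - \tfrac13)^2}.}
#' The scaling is fixed by the three anchor compositions: `P = 0` for equal
#' amounts of the three identities, `P = 1/2` for equal amounts of exactly
#' two identities, and `P = 1` for a single identity. Purity is invariant
#' under permutation of the identities.
#'
#' @param a A compartment table, or a numeric matrix/vector of composition
#'   fractions (rows summing to 1).
#' @return Numeric vector of purities in `[0, 1]`.
#' @examples
#' purity(compartment(1, 1, 1))  # 0
#' purity(compartment(1, 1, 0))  # 0.5
#' purity(compartment(5, 0, 0))  # 1
#' @export
purity <- function(a) {
  if (is.numeric(a)) {
    phi <- if (is.matrix(a)) a else matrix(a, nrow = 1)
    if (ncol(phi) != 3) stop("Composition must have three components.", call. = FALSE)
    if (any(abs(rowSums(phi) - 1) > 1e-8)) {
      stop("Composition fractions must sum to 1.", call. = FALSE)
    }
  } else {
    phi <- phi_matrix(a)
  }
  pmin(1, sqrt(1.5 * rowSums((phi - 1 / 3)^2)))
}
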