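#' Enumerate all addressable events and their propensities
#'
#' Reference (interpreted, O(M^2)) enumeration of every elementary event
#' available to a system state, with its propensity: injection of a new cis
#' vesicle (rate `j`), homotypic fusion of every unordered compartment pair,
#' fusion of every compartment with each boundary, vesicle budding per
#' compartment and identity, and biochemical conversion per compartment and
#' reaction. The compiled simulator must sample events with probabilities
#' proportional to exactly these rates; the test-suite holds it to this
#' enumeration.
#'
#' @param comps A compartment table (may have zero rows: an empty system,
#'   where only injection can fire).
#' @param params A [golgi_params()] object.
#' @return A list with `total` (the summed propensity) and `events`, a
#'   tibble with columns `kind` (`injection`, `fusion`, `boundary_fusion`,
#'   `budding`, `conversion`), `a`, `b` (row indices into `comps`, `NA`
#'   where not applicable), `identity` (identity or boundary involved) and
#'   `rate`.
#' @examples
#' p <- golgi_params(j = 2, kb = 1, km = 1)
#' total_propensity(compartment(1, 0, 0), p)$total  # j + ER exit + conversion
#' @export
total_propensity <- function(comps, params) {
  events <- list(tibble(kind = "injection", a = NA_integer_, b = NA_integer_,
                        identity = NA_character_, rate = params$j))
  m <- if (is.null(comps)) 0L else nrow(comps)
  if (m > 0) {
    comps <- as_tibble(comps)
    if (m >= 2) {
      pairs <- utils::combn(m, 2)
      events <- c(events, list(tibble(
        kind = "fusion", a = pairs[1, ], b = pairs[2, ],
        identity = NA_character_,
        rate = fusion_rate(comps[pairs[1, ], ], comps[pairs[2, ], ], params)
      )))
    }
    events <- c(events, list(
      tibble(kind = "boundary_fusion", a = seq_len(m), b = NA_integer_,
             identity = "er",
             rate = boundary_fusion_rate(comps, "er", params)),
      tibble(kind = "boundary_fusion", a = seq_len(m), b = NA_integer_,
             identity = "tgn",
             rate = boundary_fusion_rate(comps, "tgn", params))
    ))
    bud <- budding_rates(comps, params)
    events <- c(events, purrr::map(GOLGI_IDENTITIES, function(i) {
      tibble(kind = "budding", a = seq_len(m), b = NA_integer_, identity = i,
             rate = bud[[i]])
    }))
    conv <- conversion_rates(comps, params)
    events <- c(events, list(
      tibble(kind = "conversion", a = seq_len(m), b = NA_integer_,
             identity = "cis", rate = conv$cis_to_medial),
      tibble(kind = "conversion", a = seq_len(m), b = NA_integer_,
             identity = "medial", rate = conv$medial_to_trans)
    ))
  }
  events <- dplyr::filter(dplyr::bind_rows(events), .data$rate > 0 |
                            .data$kind == "injection")
  list(total = sum(events$rate), events = events)
}

#' Execute one Gillespie step of the reference stepper
#'
#' Draws an exponential waiting time at the total propensity, selects one
#' event with probability proportional to its rate, and executes it on the
#' compartment table: injection appends a pure cis vesicle; fusion merges
#' the two partners' patches and cargo; boundary fusion removes the
#' compartment; budding moves one patch of the chosen identity onto a new
#' pure vesicle (each cargo following independently with probability `1/n`);
#' conversion matures one patch into its successor identity.
#'
#' This interpreted stepper uses R's global RNG and is intended for small
#' systems (validation, worked examples); production runs use
#' [golgi_simulate()].
#'
#' @param comps A compartment table.
#' @param params A [golgi_params()] object.
#' @return A list with `comps` (the new state), `event` (a one-row tibble:
#'   `dt`, `kind`, `identity`, ids involved) and `exited` (patch counts
#'   leaving through a boundary this step, if any).
#' @export
golgi_step <- function(comps, params) {
  prop <- total_propensity(comps, params)
  if (prop$total <= 0) stop("Total propensity is zero: no event can fire.", call. = FALSE)
  dt <- stats::rexp(1, rate = prop$total)
  pick <- sample.int(nrow(prop$events), 1, prob = prop$events$rate)
  ev <- prop$events[pick, ]
  exited <- c(cis = 0L, medial = 0L, trans = 0L)
  next_id <- if (is.null(comps) || nrow(comps) == 0) 1L else max(comps$id) + 1L

  if (ev$kind == "injection") {
    comps <- dplyr::bind_rows(comps, compartment(1, 0, 0, id = next_id))
  } else if (ev$kind == "fusion") {
    a <- ev$a; b <- ev$b
    comps$n_cis[a] <- comps$n_cis[a] + comps$n_cis[b]
    comps$n_medial[a] <- comps$n_medial[a] + comps$n_medial[b]
    comps$n_trans[a] <- comps$n_trans[a] + comps$n_trans[b]
    comps$cargo[a] <- comps$cargo[a] + comps$cargo[b]
    comps <- comps[-b, ]
  } else if (ev$kind == "boundary_fusion") {
    a <- ev$a
    exited <- c(cis = comps$n_cis[a], medial = comps$n_medial[a],
                trans = comps$n_trans[a])
    comps <- comps[-a, ]
  } else if (ev$kind == "budding") {
    a <- ev$a
    col <- paste0("n_", ev$identity)
    n <- comps$n_cis[a] + comps$n_medial[a] + comps$n_trans[a]
    moved <- stats::rbinom(1, comps$cargo[a], 1 / n)
    comps[[col]][a] <- comps[[col]][a] - 1L
    comps$cargo[a] <- comps$cargo[a] - moved
    vesicle <- compartment(
      n_cis = as.integer(ev$identity == "cis"),
      n_medial = as.integer(ev$identity == "medial"),
      n_trans = as.integer(ev$identity == "trans"),
      cargo = moved, id = next_id
    )
    comps <- dplyr::bind_rows(comps, vesicle)
  } else if (ev$kind == "conversion") {
    a <- ev$a
    if (ev$identity == "cis") {
      comps$n_cis[a] <- comps$n_cis[a] - 1L
      comps$n_medial[a] <- comps$n_medial[a] + 1L
    } else {
      comps$n_medial[a] <- comps$n_medial[a] - 1L
      comps$n_trans[a] <- comps$n_trans[a] + 1L
    }
  }
  list(
    comps = comps,
    event = dplyr::bind_cols(tibble(dt = dt), ev["kind"], ev["identity"]),
    exited = exited
  )
}
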