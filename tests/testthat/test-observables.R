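snap1 <- function(n_cis, n_medial = 0L, n_trans = 0L, time = 1) {
  tibble::tibble(time = time, id = seq_along(n_cis),
                 n_cis = as.integer(n_cis), n_medial = as.integer(n_medial),
                 n_trans = as.integer(n_trans))
}

test_that("typical size is the moment ratio of the pooled distribution", {
  # degenerate distribution
  expect_equal(typical_size(snap1(rep(7, 5))), 7)
  # sizes {1,1,1,1,4}: <n^2>/<n> = 4 / (8/5)
  expect_equal(typical_size(snap1(c(1, 1, 1, 1, 4))), 2.5)
  # power-law-with-cutoff distribution p(n) ~ n^(-3/2) exp(-n/n0), the
  # aggregation-fragmentation steady-state shape: <n^2>/<n> -> n0/2
  n0 <- 400
  sizes <- 1:6000
  freq <- exp(-sizes / n0) / sizes^1.5
  set.seed(77)
  snaps <- snap1(sample(sizes, 3e5, replace = TRUE, prob = freq))
  snaps$id <- seq_len(nrow(snaps))
  # exact oracle: moment ratio of the sampling distribution itself
  expect_equal(typical_size(snaps), sum(sizes^2 * freq) / sum(sizes * freq),
               tolerance = 0.02)
  # asymptotic anchor (discreteness correction is O(n0^-1/2))
  expect_equal(typical_size(snaps), n0 / 2, tolerance = 0.1)
  # histogram frequencies sum to one
  h <- size_distribution(snap1(c(1, 1, 2, 5)))
  expect_equal(sum(h$freq), 1)
  expect_error(size_distribution(snap1(1), t_burn = 5), "burn-in")
})

test_that("system purity is size-weighted and ignores vesicles", {
  # all non-vesicles pure
  expect_equal(system_purity(snap1(c(4, 1), n_trans = c(0, 0)))$purity, 1)
  # sizes (2, 6) with purities (1, 0.5) -> 0.625
  s <- snap1(n_cis = c(2, 3), n_medial = c(0, 3))
  expect_equal(system_purity(s)$purity, 0.625)
  # adding vesicles of any identity leaves it unchanged
  s2 <- dplyr::bind_rows(s, snap1(c(1, 0, 0))[1, ],
                         snap1(0, 0, 1) |> dplyr::mutate(id = 99L))
  expect_equal(system_purity(s2)$purity, 0.625)
  # only vesicles: undefined, NA with a warning
  expect_warning(out <- system_purity(snap1(c(1, 1))), "vesicles")
  expect_true(is.na(out$purity))
})

test_that("steady-state stats summarise the post-burn-in series", {
  ser <- tibble::tibble(time = seq(0, 10, 0.1), n_total = 42)
  st <- steady_state_stats(ser, t_burn = 2)
  expect_equal(st$mean, 42)
  expect_equal(st$sd, 0)
  expect_error(steady_state_stats(ser, t_burn = 9.9), "samples")
})

test_that("enrichment vector averages composition differences over cargo", {
  tr1 <- tibble::tibble(
    time = 1, identity = "cis", donor_id = 1, acceptor_id = 2,
    donor_phi_cis = 1, donor_phi_medial = 0, donor_phi_trans = 0,
    acceptor_phi_cis = 0, acceptor_phi_medial = 0, acceptor_phi_trans = 1,
    cargo = 1L, back_fusion = FALSE, to_boundary = 0L)
  e1 <- enrichment_vector(tr1)
  expect_equal(c(e1$raw_cis, e1$raw_medial, e1$raw_trans), c(-1, 0, 1))
  expect_equal(c(e1$e_cis, e1$e_medial, e1$e_trans), c(-0.5, 0, 0.5))
  # two equal-weight events with dphi (+1,-1,0) and (+1,0,-1)
  tr2 <- tibble::tibble(
    time = c(1, 2), identity = "cis", donor_id = 1, acceptor_id = 2,
    donor_phi_cis = 0, donor_phi_medial = c(1, 0), donor_phi_trans = c(0, 1),
    acceptor_phi_cis = 1, acceptor_phi_medial = 0, acceptor_phi_trans = 0,
    cargo = 1L, back_fusion = FALSE, to_boundary = 0L)
  e2 <- enrichment_vector(tr2)
  expect_equal(c(e2$e_cis, e2$e_medial, e2$e_trans), c(0.5, -0.25, -0.25))
  # normalisation: absolute components sum to one whenever nonzero
  expect_equal(abs(e1$e_cis) + abs(e1$e_medial) + abs(e1$e_trans), 1)
  # cargo weighting: an episode with 3 cargo counts three times
  tr3 <- dplyr::mutate(tr2, cargo = c(3L, 1L))
  e3 <- enrichment_vector(tr3, weight = "cargo")
  raw <- (3 * c(1, -1, 0) + 1 * c(1, 0, -1)) / 4
  expect_equal(c(e3$raw_cis, e3$raw_medial, e3$raw_trans), raw)
  e3e <- enrichment_vector(tr3, weight = "event")
  expect_equal(c(e3e$e_cis, e3e$e_medial, e3e$e_trans),
               c(e2$e_cis, e2$e_medial, e2$e_trans))
  # boundary exits are excluded by default, switchable
  tr4 <- dplyr::mutate(tr1, to_boundary = 2L)
  expect_error(enrichment_vector(tr4), "No cargo-carrying")
  expect_equal(enrichment_vector(tr4, include_boundary = TRUE)$e_trans, 0.5)
})

test_that("directionality classification follows the sign rules", {
  expect_equal(directionality(c(-0.5, 0, 0.5)), "anterograde")
  expect_equal(directionality(c(0.5, 0, -0.5)), "retrograde")
  expect_equal(directionality(c(-0.2, 0.6, -0.2)), "centripetal")
  expect_equal(directionality(c(0.2, 0.6, 0.2)), "mixed")
  expect_equal(directionality(c(0, 0, 0)), "mixed")
})

test_that("exit kinetics recovers an exact exponential decay", {
  set.seed(9)
  d <- tibble::tibble(time = seq(0, 20, 0.5),
                      remaining = 80 * exp(-0.37 * time + rnorm(41, 0, 1e-5)))
  fit <- exit_kinetics(d)
  expect_equal(fit$rate, 0.37, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_error(exit_kinetics(d[1:3, ]), "at least")
})

test_that("medial enrichment at intermediate budding needs inter-compartment fusion", {
  # in the crossover regime vesicles converge on medial-rich compartments
  # only because mixed compartments keep merging; with inter-compartment
  # fusion prohibited the medial gain collapses
  ens <- function(fus) {
    base <- golgi_params(kb = 0.2, km = 1, n_target = 300, t_max = 80,
                         t_burn = 30, fusion = fus, cargo_mode = "pulse",
                         cargo_time = 30)
    run_pulse_chase(golgi_config(base, seeds = 1:20), 50)$enrichment$e_medial
  }
  expect_gt(ens(TRUE), ens(FALSE) + 0.2)
})

test_that("memoryless single-compartment exit recovers its analytic rate", {
  # one aggregate, no budding/conversion/injection: cargo leaves exactly when
  # the compartment exits, at rate alpha_er * phi_cis = rho
  rho <- 0.5
  set.seed(21)
  exit_times <- replicate(400, {
    p <- golgi_params(j = 0, kb = 0, km = 0, alpha_er = rho, alpha_tgn = 0,
                      t_max = 60, t_burn = 1, n_target = 10,
                      seed = sample.int(1e6, 1))
    sim <- golgi_simulate(p, init = compartment(n_cis = 4, cargo = 1))
    s <- sim$series
    if (max(s$cargo_exited) < 1) NA else min(s$time[s$cargo_exited >= 1])
  })
  expect_lt(mean(is.na(exit_times)), 0.01)
  expect_equal(mean(exit_times, na.rm = TRUE), 1 / rho, tolerance = 0.15)
})
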