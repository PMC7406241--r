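test_that("propensity enumeration covers exactly the addressable events", {
  p <- params_unit(j = 3, kb = 1, km = 1)
  # empty system: injection only
  empty <- compartment(1)[0, ]
  expect_equal(total_propensity(empty, p)$total, 3)
  # one pure cis vesicle with alpha_ER = 1, km = 1: injection + ER exit +
  # conversion, no budding
  one <- compartment(n_cis = 1)
  prop <- total_propensity(one, p)
  expect_equal(prop$total, 3 + 1 + 1)
  expect_setequal(unique(prop$events$kind),
                  c("injection", "boundary_fusion", "conversion"))
  # two identical pure compartments with fusion off: no pair term
  two <- compartment(n_cis = c(3, 4))
  p_off <- params_unit(j = 3, kb = 1, km = 1, fusion = FALSE)
  expect_false("fusion" %in% total_propensity(two, p_off)$events$kind)
  expect_equal(total_propensity(two, p_off)$total,
               total_propensity(two, p)$total - 1)
})

test_that("engine class propensities agree with the interpreted enumeration", {
  p <- golgi_params(j = 2, kb = 0.5, km = 1.5, alpha_er = 0.8, alpha_tgn = 0.6,
                    t_max = 10, t_burn = 1)
  for (state in frozen_states()) {
    eng <- golgisim:::cpp_class_propensities(engine_params(p),
                                             as.data.frame(state))
    or <- total_propensity(state, p)
    expect_equal(unname(eng[["total"]]), or$total, tolerance = 1e-12)
    by_kind <- function(k) sum(or$events$rate[or$events$kind == k])
    expect_equal(unname(eng[["fusion"]]), by_kind("fusion"))
    expect_equal(unname(eng[["boundary_fusion_er"]] + eng[["boundary_fusion_tgn"]]),
                 by_kind("boundary_fusion"))
    expect_equal(unname(eng[["budding"]]), by_kind("budding"))
    expect_equal(unname(eng[["conversion_cis_medial"]] +
                          eng[["conversion_medial_trans"]]),
                 by_kind("conversion"))
  }
  # with inter-compartment fusion off, both routes agree on the reduced
  # (vesicle-only) fusion propensity
  p_off <- golgi_params(j = 2, kb = 0.5, km = 1.5, alpha_er = 0.8,
                        alpha_tgn = 0.6, fusion = FALSE, t_max = 10,
                        t_burn = 1)
  for (state in frozen_states()) {
    eng <- golgisim:::cpp_class_propensities(engine_params(p_off),
                                             as.data.frame(state))
    or <- total_propensity(state, p_off)
    expect_equal(unname(eng[["total"]]), or$total, tolerance = 1e-12)
    expect_equal(unname(eng[["fusion"]]),
                 sum(or$events$rate[or$events$kind == "fusion"]))
  }
})

test_that("reference stepper executes events per the transition rules", {
  set.seed(11)
  p <- params_unit(j = 0.1, kb = 1, km = 1)
  # forced fusion: merged counts and cargo
  comps <- compartment(n_cis = c(3, 0), n_medial = c(0, 2), cargo = c(1, 2))
  p_fuse <- params_unit(j = 0, kb = 0, km = 0)
  # only fusion has positive rate here (mixed overlap is zero for these two,
  # so use overlapping compositions)
  comps <- compartment(n_cis = c(3, 2), n_medial = c(0, 2))
  repeat {
    st <- golgi_step(comps, p_fuse)
    if (st$event$kind == "fusion") break
  }
  expect_equal(nrow(st$comps), 1)
  expect_equal(st$comps$n_cis, 5)
  expect_equal(st$comps$n_medial, 2)
  # forced budding from (3,2,0): donor loses one patch, vesicle is pure
  p_bud <- golgi_params(j = 0, kb = 1, km = 0, alpha_er = 0, alpha_tgn = 0,
                        fusion = FALSE, t_max = 10, t_burn = 1, n_target = 10)
  st <- golgi_step(compartment(3, 2, 0), p_bud)
  expect_equal(st$event$kind, "budding")
  expect_equal(nrow(st$comps), 2)
  sizes <- st$comps$n_cis + st$comps$n_medial + st$comps$n_trans
  expect_setequal(sizes, c(4, 1))
  ves <- st$comps[sizes == 1, ]
  expect_equal(sum(unlist(ves[, c("n_cis", "n_medial", "n_trans")]) > 0), 1)
  # conversion on a cis vesicle yields a pure medial vesicle
  p_conv <- golgi_params(j = 0, kb = 0, km = 2, alpha_er = 0, alpha_tgn = 0,
                         t_max = 10, t_burn = 1, n_target = 10)
  st <- golgi_step(compartment(n_cis = 1), p_conv)
  expect_equal(st$event$kind, "conversion")
  expect_equal(unlist(st$comps[, c("n_cis", "n_medial", "n_trans")]),
               c(n_cis = 0, n_medial = 1, n_trans = 0))
  # zero-propensity state errors
  expect_error(golgi_step(compartment(n_trans = 1), p_conv), "zero")
})

test_that("identical seed and parameters give identical trajectories", {
  p <- golgi_params(kb = 2, km = 1, n_target = 80, t_max = 10, t_burn = 2,
                    seed = 99, record_events = TRUE,
                    cargo_mode = "continuous", cargo_frac = 0.2, cargo_time = 2)
  s1 <- golgi_simulate(p)
  s2 <- golgi_simulate(p)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$series, s2$series)
  expect_identical(s1$transport, s2$transport)
  # a different seed gives a different event log
  p2 <- p; p2$seed <- 100L
  expect_false(identical(golgi_simulate(p2)$events$time, s1$events$time))
})

test_that("conservation holds after every event and vesicles bud pure", {
  # the engine re-derives patch/cargo conservation from scratch per event
  p <- golgi_params(kb = 2, km = 1, n_target = 100, t_max = 15, t_burn = 2,
                    seed = 5, check = TRUE, record_events = TRUE,
                    cargo_mode = "continuous", cargo_frac = 0.3, cargo_time = 0)
  sim <- golgi_simulate(p)
  cnt <- sim$counters
  fin <- sim$final_state
  expect_equal(sum(fin$n_cis + fin$n_medial + fin$n_trans),
               unname(cnt[["injected_patches"]] - cnt[["exited_er"]] -
                        cnt[["exited_tgn"]]))
  expect_equal(sum(fin$cargo),
               unname(cnt[["cargo_injected"]] - cnt[["cargo_exited_er"]] -
                        cnt[["cargo_exited_tgn"]]))
  # series bookkeeping is consistent at every sample
  expect_equal(sim$series$n_total,
               sim$series$n_cis + sim$series$n_medial + sim$series$n_trans)
  # only forward conversions exist in the event log
  kinds <- unique(sim$events$kind)
  expect_true(all(kinds %in% c("injection", "fusion", "boundary_fusion_er",
                               "boundary_fusion_tgn", "budding",
                               "conversion_cis_medial",
                               "conversion_medial_trans")))
  # every injection and budding creates a pure size-1 vesicle by construction;
  # check via snapshots: no compartment of size zero is ever recorded
  expect_true(all(sim$snapshots$n_cis + sim$snapshots$n_medial +
                    sim$snapshots$n_trans >= 1))
})

test_that("fusion toggle spares vesicle exchange but bars compartment mergers", {
  # rate law: both partners >= 2 patches -> 0; vesicle pairs keep the law
  p_off <- params_unit(fusion = FALSE)
  big_a <- compartment(n_cis = 3)
  big_b <- compartment(n_cis = 4, id = 2)
  ves <- compartment(n_cis = 1, id = 3)
  expect_equal(fusion_rate(big_a, big_b, p_off), 0)
  expect_equal(fusion_rate(big_a, ves, p_off), 1)
  expect_equal(fusion_rate(ves, compartment(n_cis = 1, id = 4), p_off), 1)
  # in a full run, every fusion event involves at least one vesicle, and
  # multi-patch compartments still form (by vesicle accretion) and bud
  p <- golgi_params(kb = 1, km = 1, n_target = 80, t_max = 15, t_burn = 2,
                    seed = 17, fusion = FALSE, record_events = TRUE,
                    snapshot_dt = 0.5)
  sim <- golgi_simulate(p)
  expect_gt(unname(sim$events_by_kind[["fusion"]]), 0)
  expect_gt(unname(sim$events_by_kind[["budding"]]), 0)
  # reconstruct sizes at each fusion from the event log: replaying is
  # heavyweight, so check via snapshots that large compartments coexist with
  # the vesicle pool (they can only have grown one vesicle at a time)
  sizes <- sim$snapshots$n_cis + sim$snapshots$n_medial + sim$snapshots$n_trans
  expect_gt(max(sizes), 2)
})

test_that("single-species limit reaches the mean-field size balance", {
  # kb = 0, km = 0, alpha_ER = 1: injection at rate j balanced by unit-rate
  # homotypic ER exit gives a mean total size close to j
  p <- golgi_params(kb = 0, km = 0, j = 50, n_target = 100, t_max = 300,
                    t_burn = 50, seed = 8)
  m <- steady_state_stats(golgi_simulate(p)$series, 50)$mean
  expect_equal(m, 50, tolerance = 0.15)
})

test_that("cargo pulses are conserved and exit exactly once", {
  p <- golgi_params(kb = 1, km = 1, n_target = 100, t_max = 50, t_burn = 10,
                    seed = 3, cargo_mode = "pulse", cargo_time = 10,
                    cargo_n = 50)
  sim <- golgi_simulate(p)
  cnt <- sim$counters
  expect_equal(unname(cnt[["cargo_injected"]]), 50)
  expect_equal(unname(cnt[["cargo_injected"]]),
               unname(cnt[["cargo_exited_er"]] + cnt[["cargo_exited_tgn"]]) +
                 sum(sim$final_state$cargo))
  # conservation along the whole series
  s <- sim$series
  expect_true(all(s$cargo_in_system + s$cargo_exited <= 50))
})
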