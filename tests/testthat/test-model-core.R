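test_that("fusion rate follows the composition-overlap law", {
  p <- params_unit()
  # identical pure compartments fuse at the reference rate 1
  expect_equal(fusion_rate(compartment(2), compartment(5, id = 2)), 1)
  # orthogonal compositions never fuse
  expect_equal(fusion_rate(compartment(n_cis = 3),
                           compartment(n_trans = 4, id = 2)), 0)
  # (1/2, 1/2, 0) vs (0, 1/2, 1/2): only the medial channel overlaps
  a <- compartment(n_cis = 2, n_medial = 2)
  b <- compartment(n_medial = 3, n_trans = 3, id = 2)
  expect_equal(fusion_rate(a, b), 0.25)
  # symmetric in its arguments, bounded by [0, 1]
  phi <- random_compositions(50)
  counts <- round(phi * 60) + 1L
  ca <- compartment(counts[1:25, 1], counts[1:25, 2], counts[1:25, 3])
  cb <- compartment(counts[26:50, 1], counts[26:50, 2], counts[26:50, 3],
                    id = 26:50)
  expect_equal(fusion_rate(ca, cb), fusion_rate(cb, ca))
  expect_true(all(fusion_rate(ca, cb) >= 0 & fusion_rate(ca, cb) <= 1))
  # toggle: rates vanish when inter-compartment fusion is off
  p_off <- params_unit(fusion = FALSE)
  expect_equal(fusion_rate(a, b, p_off), 0)
  # self-fusion is undefined
  expect_error(fusion_rate(a, a), "Self-fusion")
})

test_that("boundary fusion is homotypic with the boundary composition", {
  expect_equal(boundary_fusion_rate(compartment(n_cis = 1), "er", alpha = 1), 1)
  expect_equal(boundary_fusion_rate(compartment(n_trans = 1), "er", alpha = 1), 0)
  # phi_trans = 0.5 against a TGN with alpha = 0.8
  expect_equal(
    boundary_fusion_rate(compartment(n_cis = 2, n_trans = 2), "tgn",
                         alpha = 0.8), 0.4)
  p <- params_unit(alpha_er = 0.6, alpha_tgn = 0.3)
  expect_equal(boundary_fusion_rate(compartment(1, 1, 2), "er", p), 0.6 * 0.25)
  expect_equal(boundary_fusion_rate(compartment(1, 1, 2), "tgn", p), 0.3 * 0.5)
})

test_that("budding rates: saturated and linear modes, vesicles never bud", {
  p <- params_unit(kb = 1)
  # vesicles (size 1) give all-zero rates in both modes
  for (mode in c("saturated", "linear")) {
    pm <- params_unit(kb = 1, budding_mode = mode)
    v <- dplyr::bind_rows(lapply(golgi_identities(), function(i) {
      budding_rates(compartment(n_cis = as.integer(i == "cis"),
                                n_medial = as.integer(i == "medial"),
                                n_trans = as.integer(i == "trans")), pm)
    }))
    expect_true(all(v == 0))
  }
  # saturated: every identity present buds at kb * n
  r <- budding_rates(compartment(3, 2, 5), p)
  expect_equal(unlist(r), c(cis = 10, medial = 10, trans = 10))
  expect_equal(sum(unlist(r)), 30)
  # absent identities get zero
  r2 <- budding_rates(compartment(n_cis = 4, n_trans = 6), params_unit(kb = 2))
  expect_equal(unlist(r2), c(cis = 20, medial = 0, trans = 20))
  # linear: proportional to per-identity counts
  rl <- budding_rates(compartment(3, 2, 5),
                      params_unit(kb = 1, budding_mode = "linear"))
  expect_equal(unlist(rl), c(cis = 3, medial = 2, trans = 5))
})

test_that("conversion is irreversible, per patch, and additive over fusion", {
  p <- params_unit(km = 1)
  # trans is terminal
  expect_equal(conversion_rates(compartment(n_trans = 9), p)$total, 0)
  r <- conversion_rates(compartment(3, 2, 5), p)
  expect_equal(r$cis_to_medial, 3)
  expect_equal(r$medial_to_trans, 2)
  # a vesicle converts too
  expect_equal(conversion_rates(compartment(n_cis = 1), params_unit(km = 2))$total, 2)
  # conversion propensity of a fused compartment = sum of the parts
  a <- compartment(4, 1, 2)
  b <- compartment(0, 3, 3)
  ab <- compartment(4, 4, 5)
  expect_equal(conversion_rates(ab, p)$total,
               conversion_rates(a, p)$total + conversion_rates(b, p)$total)
})

test_that("purity matches its anchors and the brute-force distance", {
  # printed anchors: perfectly mixed, two identities, single identity
  expect_equal(purity(compartment(1, 1, 1)), 0)
  expect_equal(purity(compartment(1, 1, 0)), 0.5)
  expect_equal(purity(compartment(5, 0, 0)), 1)
  # invariant under permutation of identities
  expect_equal(purity(compartment(n_medial = 1, n_trans = 1)), 0.5)
  expect_equal(purity(compartment(n_cis = 2, n_trans = 2)), 0.5)
  # closed form equals the Euclidean distance from (1/3,1/3,1/3) normalised
  # by its value at a pure composition, for 1000 random compositions
  phi <- random_compositions(1000, seed = 42)
  brute <- apply(phi, 1, function(r) {
    sqrt(sum((r - 1 / 3)^2)) / sqrt(sum((c(1, 0, 0) - 1 / 3)^2))
  })
  expect_equal(purity(phi), brute, tolerance = 1e-12)
  # maximal exactly on pure compartments
  expect_true(all(purity(phi[rowSums(phi == 0) < 2, ]) < 1))
})

test_that("compartment constructor enforces its invariants", {
  expect_error(compartment(0, 0, 0), "at least one patch")
  expect_error(compartment(-1, 2, 0), "non-negative")
  expect_error(compartment(c(1, 1), id = c(7, 7)), "unique")
  f <- comp_fractions(compartment(3, 2, 5))
  expect_equal(f$n, 10)
  expect_equal(f$phi_cis + f$phi_medial + f$phi_trans, 1)
})
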