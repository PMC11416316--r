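test_that("preset geometry is recovered from the generated truth", {
  y <- make_ground_truth(basket_preset("yeast", seed = 5))
  gy <- measure_geometry(y)
  expect_lt(abs(gy$strut_tilt - 30), 0.5)
  expect_lt(abs(gy$distal_offset - 540), 5)
  expect_lt(abs(gy$distal_ring_diameter - 760), 5)
  m <- make_ground_truth(basket_preset("mouse", seed = 5))
  gm <- measure_geometry(m)
  expect_lt(abs(gm$strut_tilt - 6), 0.5)
  expect_lt(abs(gm$distal_offset - 630), 5)
  expect_lt(abs(gm$distal_ring_diameter - 1000), 5)
})

test_that("zero tilt puts all strut beads at one radial distance", {
  p <- small_params()
  p$strut_tilt <- 0
  st <- make_ground_truth(p)
  sel <- which(st$bead$subunit == "Mlp1s")
  sel <- sel[seq_len(length(sel) - 3L)]   # strut beads, not the blob
  rad <- sqrt(rowSums(st$coords[sel, 1:2]^2))
  expect_lt(diff(range(rad)), 1e-9)
})

test_that("parameter validation rejects invalid geometry", {
  expect_error(ground_truth_params(strut_tilt = 95), "90")
  expect_error(ground_truth_params(distal_offset = -1), "positive")
  expect_error(ground_truth_params(n_symmetry = 0), "n_symmetry")
})

test_that("simulated crosslinks respect cutoff, false-positive count and
          seed determinism", {
  truth <- make_ground_truth(small_params())
  xl0 <- simulate_crosslinks(truth, cutoff = 35, n_true = 40, fp_rate = 0,
                             seed = 7)
  d0 <- score_crosslinks(truth, xl0, cutoff = 35)$distances
  expect_true(all(d0 <= 35))
  # n_true = 90, fp_rate = 0.1 -> floor(90 * 0.1 / 0.9) = 10 violators
  xl1 <- simulate_crosslinks(truth, cutoff = 35, n_true = 90,
                             fp_rate = 0.1, seed = 7)
  expect_equal(nrow(xl1), 100L)
  d1 <- score_crosslinks(truth, xl1, cutoff = 35)$distances
  expect_equal(sum(d1 > 35), 10L)
  expect_equal(sum(attr(xl1, "truth_violates")), 10L)
  # determinism
  xl2 <- simulate_crosslinks(truth, cutoff = 35, n_true = 90,
                             fp_rate = 0.1, seed = 7)
  expect_identical(xl1, xl2)
  # impossible cutoff reported with its value
  expect_error(simulate_crosslinks(truth, cutoff = 0.01, n_true = 5),
               "0.01")
})

test_that("simulated density matches the truth model at zero jitter and
          degrades with noise", {
  truth <- make_ground_truth(small_params())
  g0 <- simulate_density(truth, sigma_scale = 1, jitter = 0)
  expect_equal(gmm_cc(model_to_gmm(truth, 1), g0), 1, tolerance = 1e-9)
  g5 <- simulate_density(truth, sigma_scale = 2, jitter = 5, seed = 3)
  cc5 <- gmm_cc(model_to_gmm(truth, 2), g5)
  expect_lt(cc5, 1)
  rnd <- randomize_initial(truth, seed = 3)
  cc_rand <- gmm_cc(model_to_gmm(rnd, 2), g5)
  expect_gt(cc5, cc_rand)
  # weight renormalization leaves CC unchanged
  g5b <- g5; g5b$weight <- g5$weight / sum(g5$weight)
  expect_equal(gmm_cc(model_to_gmm(truth, 2), g5b), cc5,
               tolerance = 1e-12)
})

test_that("terminal localizations pin strut termini", {
  truth <- make_ground_truth(small_params())
  specs <- simulate_terminal_localizations(truth, sigma = 10)
  # two strut chains -> N and C each -> 4 specs
  expect_length(specs, 4L)
  expect_equal(score_positional(truth, specs)$score, 0)
  # displacing the truth by 3 sigma makes the restraint positive
  moved <- truth
  moved$coords <- truth$coords + 30
  expect_gt(score_positional(moved, specs)$score, 0)
  expect_error(simulate_terminal_localizations(truth, sigma = 10,
                                               subunits = "nope"),
               "strut")
})

test_that("bundle regeneration is bit-identical under a fixed seed", {
  b1 <- small_bundle(seed = 9, fp_rate = 0.05, jitter = 2)
  b2 <- small_bundle(seed = 9, fp_rate = 0.05, jitter = 2)
  expect_identical(b1$truth_state$coords, b2$truth_state$coords)
  expect_identical(b1$crosslinks, b2$crosslinks)
  expect_identical(b1$density, b2$density)
  expect_identical(b1$terminal_localizations, b2$terminal_localizations)
})
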