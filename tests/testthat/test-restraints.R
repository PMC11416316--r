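test_that("crosslink penalties follow the one-sided harmonic with the
          minimum-distance copy assignment", {
  # two beads 45 A apart, cutoff 35, k = 1 -> 0.5 * 10^2 = 50
  st <- toy_state(c(0, 0, 0), c(45, 0, 0))
  xl <- data.frame(protein1 = "A", residue1 = 5L, protein2 = "B",
                   residue2 = 5L, linker = "DSS", multiplicity = 1L)
  class(xl) <- c("crosslink_records", "data.frame")
  r <- score_crosslinks(st, xl, cutoff = 35, k = 1)
  expect_equal(r$score, 50)
  expect_equal(r$distances, 45)
  # within the bound -> 0
  st2 <- toy_state(c(0, 0, 0), c(10, 0, 0))
  expect_equal(score_crosslinks(st2, xl, cutoff = 35)$score, 0)
  # two copies at 50 and 20 A: the minimum rule gives 0
  st3 <- toy_state(c(0, 0, 0), c(50, 0, 0, 20, 0, 0), copies_b = 2L)
  expect_equal(score_crosslinks(st3, xl, cutoff = 35)$score, 0)
  # adding a copy can never increase the penalty (min is monotone)
  st4 <- toy_state(c(0, 0, 0), c(50, 0, 0))
  expect_gte(score_crosslinks(st4, xl, cutoff = 35)$score,
             score_crosslinks(st3, xl, cutoff = 35)$score)
  # unmappable record names itself
  bad <- xl; bad$protein2 <- "Z"
  expect_error(score_crosslinks(st, bad), "does not map")
})

test_that("GMM cross-correlation matches the analytic overlap and a
          numeric integration oracle", {
  g1 <- gaussian_mixture(1, matrix(c(0, 0, 0), 1), 10)
  g2 <- gaussian_mixture(1, matrix(c(20, 0, 0), 1), 10)
  # closed form: exp(-d^2 / (4 sigma^2)) = exp(-1)
  expect_equal(gmm_cc(g1, g2), exp(-1), tolerance = 1e-12)
  # numeric 3D integration oracle on a grid
  ax <- seq(-60, 80, by = 2)
  dens <- function(mu) {
    gx <- exp(-(ax - mu)^2 / 200); gy <- exp(-ax^2 / 200)
    outer(outer(gx, gy), gy)
  }
  f <- dens(0); g <- dens(20)
  cc_num <- sum(f * g) / sqrt(sum(f * f) * sum(g * g))
  expect_equal(gmm_cc(g1, g2), cc_num, tolerance = 1e-6)
  # self-correlation, symmetry, scale invariance, range
  expect_equal(gmm_cc(g1, g1), 1, tolerance = 1e-9)
  set.seed(1)
  ga <- gaussian_mixture(runif(5), matrix(rnorm(15, sd = 30), 5),
                         runif(5, 5, 15))
  gb <- gaussian_mixture(runif(4), matrix(rnorm(12, sd = 30), 4),
                         runif(4, 5, 15))
  expect_equal(gmm_cc(ga, gb), gmm_cc(gb, ga), tolerance = 1e-12)
  gc_ <- gb; gc_$weight <- gb$weight * 7
  expect_equal(gmm_cc(ga, gc_), gmm_cc(ga, gb), tolerance = 1e-12)
  expect_gte(gmm_cc(ga, gb), 0)
  expect_lte(gmm_cc(ga, gb), 1 + 1e-12)
  expect_error(gaussian_mixture(1, matrix(0, 1, 3), 0), "sigma")
})

test_that("model_to_gmm mirrors the coarse beads and sharpness matters", {
  truth <- make_ground_truth(small_params())
  g <- model_to_gmm(truth, sigma_scale = 1)
  expect_length(g$weight, length(coarse_beads(truth)))
  sharp <- simulate_density(truth, sigma_scale = 1, jitter = 0)
  cc1 <- gmm_cc(model_to_gmm(truth, 1), sharp)
  cc2 <- gmm_cc(model_to_gmm(truth, 2), sharp)
  expect_equal(cc1, 1, tolerance = 1e-9)
  expect_lt(cc2, cc1)
})

test_that("positional restraints implement flat-bottom point and slab
          forms", {
  st <- toy_state(c(0, 0, 0))
  at <- positional_spec(target = c(0, 0, 0), subunit = "A", res_first = 1,
                        res_last = 10, tolerance = 10)
  expect_equal(score_positional(st, at)$score, 0)
  # 12 A away with tolerance 10, k = 1 -> 0.5 * 2^2 = 2
  far <- positional_spec(target = c(12, 0, 0), subunit = "A",
                         res_first = 1, res_last = 10, tolerance = 10)
  expect_equal(score_positional(st, far)$score, 2)
  sl_in <- positional_spec(slab = c(-5, 5), subunit = "A", res_first = 1,
                           res_last = 10)
  expect_equal(score_positional(st, sl_in)$score, 0)
  st_out <- toy_state(c(0, 0, 8))
  expect_equal(score_positional(st_out, sl_in)$score, 0.5 * 9)
  expect_error(score_positional(st, positional_spec(
    target = c(0, 0, 0), subunit = "Q", res_first = 1, res_last = 10)),
    "maps to no beads")
})

test_that("proximity restraints bound the minimum inter-domain distance
          symmetrically", {
  st <- toy_state(c(0, 0, 0), c(14, 0, 0))
  pr <- data.frame(subunit1 = "A", first1 = 1, last1 = 10,
                   subunit2 = "B", first2 = 1, last2 = 10,
                   max_distance = 10)
  # min distance = bound + 4 -> 0.5 * 16 = 8
  expect_equal(score_proximity(st, pr)$score, 8)
  prs <- pr[, c(4:6, 1:3, 7)]
  names(prs) <- names(pr)
  expect_equal(score_proximity(st, prs)$score, 8)
  touching <- toy_state(c(0, 0, 0), c(5, 0, 0))
  expect_equal(score_proximity(touching, pr)$score, 0)
  expect_error(score_proximity(st, transform(pr, subunit2 = "Z")),
               "empty domain")
})

test_that("connectivity restrains consecutive beads of one chain only", {
  # threshold 1.2 * (5 + 5) = 12; contact chain at 10 A spacing -> 0
  chain <- toy_state(c(0, 0, 0, 10, 0, 0, 20, 0, 0))
  expect_equal(score_connectivity(chain)$score, 0)
  # one gap of threshold + 3 -> 0.5 * 9 = 4.5
  gap <- toy_state(c(0, 0, 0, 15, 0, 0))
  expect_equal(score_connectivity(gap)$score, 4.5)
  # far-apart chains contribute nothing
  two <- toy_state(c(0, 0, 0, 10, 0, 0), c(500, 0, 0, 510, 0, 0))
  expect_equal(score_connectivity(two)$score, 0)
})

test_that("excluded volume penalizes only non-bonded inter-body overlaps", {
  apart <- toy_state(c(0, 0, 0), c(100, 0, 0))
  expect_equal(score_excluded_volume(apart)$score, 0)
  # radii 10 + 10 at 15 A -> 0.5 * 25 = 12.5 (non-consecutive beads)
  st <- toy_state(c(0, 0, 0), c(15, 0, 0), r = 10)
  expect_equal(score_excluded_volume(st)$score, 12.5)
  # consecutive beads of one chain are exempt
  cons <- toy_state(c(0, 0, 0, 15, 0, 0), r = 10)
  expect_equal(score_excluded_volume(cons)$score, 0)
  # same rigid body is exempt
  st2 <- st
  st2 <- npcbasket:::new_assembly_state(st$coords, st$radius, st$bead,
                                        bodies = list(1:2),
                                        body_fixed = FALSE)
  expect_equal(score_excluded_volume(st2)$score, 0)
})

test_that("equivalence restraints match intra-model distances frame-free", {
  a <- toy_state(c(0, 0, 0, 10, 0, 0, 0, 10, 0))
  al <- data.frame(subunit = "A", residue = c(5L, 15L, 25L),
                   ref_subunit = "A", ref_residue = c(5L, 15L, 25L))
  expect_equal(score_equivalence(a, a, al)$score, 0)
  # one pair differing by 3 A -> 0.5 * 9 = 4.5
  b2 <- toy_state(c(0, 0, 0, 13, 0, 0))
  a2 <- toy_state(c(0, 0, 0, 10, 0, 0))
  al2 <- data.frame(subunit = "A", residue = c(5L, 15L),
                    ref_subunit = "A", ref_residue = c(5L, 15L))
  expect_equal(score_equivalence(a2, b2, al2)$score, 4.5)
  # rigid rotation of the whole state leaves the score unchanged
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rot <- a; rot$coords <- a$coords %*% t(Rm)
  expect_equal(score_equivalence(rot, a, al)$score,
               score_equivalence(a, a, al)$score, tolerance = 1e-9)
  expect_warning(s0 <- score_equivalence(a, a, al[0, ]), "empty")
  expect_equal(s0$score, 0)
})

test_that("total score decomposes exactly and zero weights remove terms", {
  b <- small_bundle(seed = 4)
  sc <- total_score(b$truth_state, b)
  expect_equal(sum(sc$terms), sc$total, tolerance = 1e-9)
  # noiseless bundle: every data term is 0 at the truth and CC = 1
  expect_equal(unname(sc$terms[c("crosslink", "em", "positional",
                                 "proximity")]), rep(0, 4))
  expect_equal(sc$details$em$cc, 1, tolerance = 1e-9)
  # switching a weight off removes its term
  rnd <- randomize_initial(b$truth_state, seed = 1)
  w0 <- restraint_weights(crosslink = 0)
  sc_rnd <- total_score(rnd, b)
  sc_w0 <- total_score(rnd, b, weights = w0)
  expect_gt(sc_rnd$terms[["crosslink"]], 0)
  expect_equal(sc_w0$terms[["crosslink"]], 0)
  expect_equal(sc_w0$total, sc_rnd$total - sc_rnd$terms[["crosslink"]],
               tolerance = 1e-9)
  # all penalties are nonnegative
  expect_true(all(sc_rnd$terms >= 0))
})

test_that("hand-built toy total equals the sum of hand-computed terms", {
  # 3 beads: chain A (2 beads) + chain B (1 bead), radius 5
  st <- toy_state(c(0, 0, 0, 16, 0, 0), c(6, 0, 0))
  xl <- data.frame(protein1 = "A", residue1 = 15L, protein2 = "B",
                   residue2 = 5L, linker = "DSS", multiplicity = 1L)
  bundle <- list(crosslinks = xl, xl_cutoff = 5)
  w <- restraint_weights(em = 1)
  sc <- total_score(st, bundle, weights = w)
  # crosslink: d = 10, cutoff 5 -> 12.5; connectivity: gap 16 vs 12 -> 8;
  # excluded volume: A1-B 6 vs 10 -> 8, A2-B 10 vs 10 -> 0
  expect_equal(unname(sc$terms[["crosslink"]]), 12.5)
  expect_equal(unname(sc$terms[["connectivity"]]), 8)
  expect_equal(unname(sc$terms[["excluded_volume"]]), 8)
  expect_equal(sc$total, 28.5)
})

test_that("compiled plan scoring agrees with the reference scorers", {
  b <- small_bundle(seed = 6, fp_rate = 0.1, jitter = 1)
  plan <- compile_plan(b$truth_state, b)
  for (s in 1:3) {
    st <- randomize_initial(b$truth_state, seed = s)
    ref <- total_score(st, b)
    got <- plan_score(plan, st$coords)
    expect_equal(got$total, ref$total, tolerance = 1e-8)
    expect_equal(got$terms, ref$terms, tolerance = 1e-8)
  }
  # symmetry-image excluded volume agrees too
  plan_s <- compile_plan(b$truth_state, b, include_symmetry_images = TRUE)
  st <- randomize_initial(b$truth_state, seed = 9)
  expect_equal(plan_score(plan_s, st$coords)$terms[["excluded_volume"]],
               total_score(st, b,
                           include_symmetry_images = TRUE)$terms[[
                             "excluded_volume"]],
               tolerance = 1e-8)
})
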