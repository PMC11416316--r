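test_that("randomization respects the fixed scaffold and the seed", {
  truth <- make_ground_truth(small_params())
  fx <- fixed_beads(truth)
  r1 <- randomize_initial(truth, seed = 1)
  r2 <- randomize_initial(truth, seed = 1)
  r3 <- randomize_initial(truth, seed = 2)
  expect_identical(r1$coords[fx, ], truth$coords[fx, ])
  expect_identical(r1$coords, r2$coords)
  expect_false(identical(r1$coords, r3$coords))
  # movable beads land inside the region
  reg <- bounding_region(c(-100, 900), c(-400, 400), c(-900, 200))
  r4 <- randomize_initial(truth, reg, seed = 5)
  mv <- setdiff(movable_beads(truth), unlist(truth$bodies))
  expect_true(all(r4$coords[mv, 1] >= -100 & r4$coords[mv, 1] <= 900))
})

test_that("Metropolis acceptance matches the closed form", {
  set.seed(123)
  acc <- metropolis_accept(rep(1, 1e5), temperature = 1)
  expect_lt(abs(mean(acc) - exp(-1)), 0.01)
  expect_true(all(metropolis_accept(c(-5, -0.001, 0), 1)))
})

test_that("a Gibbs step with zero move magnitudes accepts everything and
          changes nothing", {
  truth <- make_ground_truth(small_params())
  b <- small_bundle()
  efun <- function(s) total_score(s, b)$total
  set.seed(1)
  out <- mc_step(truth, efun, move_set(0, 0, 0, 0), temperature = 1)
  expect_identical(out$state$coords, truth$coords)
  expect_true(all(out$accepted))
})

test_that("replica exchange follows the exchange probability and
          preserves configurations", {
  # beta = (1, 0.5), E = (10, 2): exponent +4, capped at 1
  expect_equal(swap_probability(1, 2, 10, 2), 1)
  # reversed energies: exp(-4)
  expect_equal(swap_probability(1, 2, 2, 10), exp(-4), tolerance = 1e-12)
  # equal temperatures always swap
  expect_equal(swap_probability(1.3, 1.3, 5, -2), 1)
  reps <- lapply(1:4, function(i)
    list(state = matrix(i, 2, 3), temperature = i, energy = i * 2))
  set.seed(2)
  out <- replica_exchange(reps)
  expect_equal(out$attempted, 2L)
  pre <- sort(vapply(reps, function(r) r$state[1, 1], numeric(1)))
  post <- sort(vapply(out$replicas, function(r) r$state[1, 1], numeric(1)))
  expect_equal(pre, post)   # multiset of configurations preserved
  expect_error(replica_exchange(reps[1]), ">= 2")
})

test_that("sampling a single bead in a harmonic well reproduces the
          stationary variance", {
  # E = 0.5 * d^2 (point positional, tolerance 0), T = 1 => var(x) = 1
  st <- toy_state(c(0.5, 0, 0))
  bundle <- list(terminal_localizations = list(positional_spec(
    target = c(0, 0, 0), subunit = "A", res_first = 1, res_last = 10,
    tolerance = 0)))
  cfg <- replica_config(n_replicas = 1L, temperature_ladder = 1,
                        n_steps = 1e5L, n_independent_runs = 1L,
                        seed = 31L, frame_interval = 2L)
  ens <- run_sampling(st, bundle, cfg, move_set(0, 0, 2),
                      region = bounding_region(c(-2, 2), c(-2, 2),
                                               c(-2, 2)))
  xs <- vapply(ens$frames, function(f) f[1, ], numeric(3))
  xs <- xs[, -(1:5000)]   # burn-in
  v <- mean(apply(xs, 1, var))
  expect_lt(abs(v - 1), 0.05)
})

test_that("run_sampling is deterministic, improves on random starts, and
          never moves the scaffold", {
  b <- small_bundle(seed = 12)
  truth <- b$truth_state
  cfg <- replica_config(n_replicas = 3L,
                        temperature_ladder = c(1, 1.6, 2.5),
                        n_steps = 400L, n_independent_runs = 2L,
                        seed = 7L, frame_interval = 40L)
  e1 <- run_sampling(truth, b, cfg)
  e2 <- run_sampling(truth, b, cfg)
  expect_identical(e1$frames, e2$frames)
  expect_identical(e1$scores, e2$scores)
  # best kept score beats a random configuration
  rnd <- randomize_initial(truth, seed = 7)
  expect_lt(min(e1$scores), total_score(rnd, b)$total)
  # per-frame breakdown sums to the recorded score
  expect_lt(max(abs(rowSums(e1$terms) - e1$scores)), 1e-6)
  # fixed scaffold is bit-identical in every recorded frame
  fx <- fixed_beads(truth)
  for (f in e1$frames) expect_identical(f[fx, ], truth$coords[fx, ])
  # provenance covers both runs
  expect_setequal(unique(e1$provenance$run), 1:2)
})

test_that("with only connectivity and excluded volume active, sampled
          chains end up connected", {
  truth <- make_ground_truth(small_params())
  bundle <- list()   # no data terms; priors only
  cfg <- replica_config(n_replicas = 2L, temperature_ladder = c(1, 2),
                        n_steps = 2000L, n_independent_runs = 1L,
                        seed = 3L, frame_interval = 100L)
  ens <- run_sampling(truth, bundle, cfg, k = 10,
                      region = default_region(truth, pad = 30))
  late <- ens$frames[(length(ens$frames) - 4L):length(ens$frames)]
  # a bond is connected if it sits within the restraint threshold plus
  # the thermal fluctuation allowance at kT = 1
  sat <- vapply(late, function(f) {
    s <- truth; s$coords <- f
    cp <- npcbasket:::connectivity_pairs(s, 1.2)
    d <- sqrt(rowSums((f[cp[, 1], , drop = FALSE] -
                         f[cp[, 2], , drop = FALSE])^2))
    mean(d <= cp[, 3] + 1)
  }, numeric(1))
  expect_gt(mean(sat), 0.99)
})
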