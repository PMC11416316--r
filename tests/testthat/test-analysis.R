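fake_ensemble <- function(frames, scores = NULL, runs = NULL) {
  n <- length(frames)
  if (is.null(scores)) scores <- rep(0, n)
  if (is.null(runs)) runs <- rep(1L, n)
  tm <- matrix(0, n, 7,
               dimnames = list(NULL, c("crosslink", "em", "positional",
                                       "proximity", "connectivity",
                                       "excluded_volume", "equivalence")))
  structure(list(state = NULL, frames = frames, scores = scores,
                 terms = tm,
                 provenance = data.frame(run = runs, replica = 1L,
                                         step = seq_len(n))),
            class = "model_ensemble")
}

test_that("good-scoring selection filters by percentile and per-term
          thresholds", {
  base <- matrix(0, 4, 3)
  ens <- fake_ensemble(shifted_frames(base, 1:5),
                       scores = c(5, 1, 3, 2, 4))
  expect_length(select_good_scoring(ens, percentile = 100)$frames, 5L)
  # hand-enumerated: scores <= 3 keeps 3 of 5
  sel <- select_good_scoring(ens, term_max = c(crosslink = Inf),
                             percentile = 60)
  expect_length(sel$frames, 3L)
  expect_true(all(sel$scores <= 3))
  # an unsatisfiable threshold yields an explicit empty outcome
  expect_warning(empty <- select_good_scoring(ens,
                                              term_max = c(crosslink = -1)),
                 "no good-scoring")
  expect_true(isTRUE(attr(empty, "no_good_scoring")))
  expect_length(empty$frames, 0L)
})

test_that("rmsd is exact for uniform shifts and permutation-aware for
          equivalent copies", {
  st <- toy_state(c(0, 0, 0, 10, 0, 0))
  expect_equal(rmsd(st, st), 0)
  sh <- st; sh$coords <- st$coords + matrix(c(2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(rmsd(st, sh), 2)
  # two equivalent copies swapped in space -> 0 when permutation allowed
  a <- toy_state(c(0, 0, 0), c(100, 0, 0, 200, 0, 0), copies_b = 2L)
  b <- a
  b$coords <- a$coords[c(1, 3, 2), ]
  expect_gt(rmsd(a, b), 0)
  expect_equal(rmsd(a, b, copy_permutation = TRUE), 0)
  expect_error(rmsd(st, toy_state(c(0, 0, 0))), "topolog")
})

test_that("greedy threshold clustering partitions frames as constructed", {
  base <- matrix(0, 5, 3)
  same <- cluster_models(shifted_frames(base, rep(0, 6)), threshold = 1)
  expect_length(same$clusters, 1L)
  # two tight blobs 100 A apart at threshold 10 -> 2 clusters
  two <- cluster_models(shifted_frames(base, c(0, 1, 2, 100, 101, 102)),
                        threshold = 10)
  expect_length(two$clusters, 2L)
  expect_setequal(lengths(two$clusters), c(3L, 3L))
  # infinite threshold -> a single cluster
  one <- cluster_models(shifted_frames(base, c(0, 50, 400)),
                        threshold = Inf)
  expect_length(one$clusters, 1L)
  # clusters partition the input
  expect_setequal(unlist(two$clusters), 1:6)
})

test_that("model precision averages pairwise RMSDs", {
  base <- matrix(0, 4, 3)
  expect_equal(model_precision(shifted_frames(base, c(0, 4)))$pairwise, 4)
  # 3 members with hand-set pairwise RMSDs 3, 6, 9 along one axis
  mp <- model_precision(shifted_frames(base, c(0, 3, 9)))
  expect_equal(mp$pairwise, mean(c(3, 9, 6)))
  expect_message(mp1 <- model_precision(shifted_frames(base, 0)),
                 "singleton")
  expect_equal(mp1$pairwise, 0)
})

test_that("the two-half exhaustiveness protocol passes identical halves
          and rejects disjoint ones", {
  base <- matrix(0, 4, 3)
  # identical halves: duplicated frames in both halves
  sh <- rep(c(0, 5, 10, 60, 65, 70), 10)
  ens <- fake_ensemble(shifted_frames(base, c(sh, sh)),
                       scores = rep(stats::rnorm(60, 100, 1), 2),
                       runs = rep(1:2, each = 60))
  grid <- c(2, 5, 10, 20, 40, 80)
  sp <- sampling_precision(ens, thresholds = grid)
  expect_equal(sp$precision, 2)
  expect_true(all(sp$tests$pass))
  # 90/10 vs 10/90 bimodal fixture fails at small thresholds
  h1 <- c(rep(0, 45), rep(300, 5))
  h2 <- c(rep(0, 5), rep(300, 45))
  ens2 <- fake_ensemble(shifted_frames(base, c(h1, h2)),
                        runs = rep(1:2, each = 50))
  sp2 <- sampling_precision(ens2, thresholds = c(5, 20, 100, 400))
  expect_false(any(sp2$tests$pass[sp2$tests$threshold <= 100]))
  # single run refuses to split
  ens3 <- fake_ensemble(shifted_frames(base, 1:6))
  expect_error(sampling_precision(ens3), "independent runs")
})

test_that("sampling precision is bounded for a seeded Gaussian cloud and
          by the merged-cluster model precision", {
  set.seed(8)
  base <- matrix(0, 6, 3)
  # isotropic per-bead jitter, sd 5 A -> typical pairwise RMSD ~ sigma*sqrt(2)
  frames <- lapply(1:80, function(i)
    base + matrix(rnorm(18, 0, 5), 6, 3))
  ens <- fake_ensemble(frames, scores = rnorm(80),
                       runs = rep(1:2, each = 40))
  sp <- sampling_precision(ens, thresholds = seq(2, 30, by = 2))
  expect_lte(sp$precision, 15)   # within ~3 sigma of the generator
  mp <- model_precision(frames)
  expect_lte(sp$precision, mp$pairwise + 2)  # grid-resolution slack
})

test_that("localization densities are member fractions on a voxel grid", {
  st <- toy_state(c(0, 0, 0))
  one <- localization_density(list(st$coords), st, subunits = "A",
                              voxel = 2)
  expect_equal(max(one$data), 1)
  # support equals the smoothed envelope of the single model
  expect_true(all(one$data %in% c(0, 1)))
  # two members in disjoint regions peak at 0.5 each
  two <- localization_density(list(st$coords, st$coords + 60), st,
                              subunits = "A", voxel = 2)
  expect_equal(max(two$data), 0.5)
  # identical members give a binary map with max 1
  same <- localization_density(list(st$coords, st$coords, st$coords), st,
                               subunits = "A", voxel = 2)
  expect_equal(max(same$data), 1)
  expect_true(all(same$data %in% c(0, 1)))
  # normalization: integral = mean member envelope volume
  vol1 <- sum(one$data > 0) * one$voxel^3
  vol2 <- sum(two$data) * two$voxel^3
  expect_equal(vol2, vol1, tolerance = 0.05)
  expect_error(localization_density(list(st$coords), st, subunits = "Q"),
               "selector")
})

test_that("satisfaction reports count links and compare ensemble to
          per-model rates", {
  b <- small_bundle(seed = 2)
  truth <- b$truth_state
  rep1 <- satisfaction_report(list(truth$coords), truth, b, cutoff = 35)
  expect_equal(rep1$pct_satisfied_ensemble, 100)
  expect_equal(rep1$centroid_cc, 1, tolerance = 1e-9)
  # hand-built: 4 links, one pushed beyond the cutoff in every member
  st <- toy_state(c(0, 0, 0, 12, 0, 0, 24, 0, 0, 300, 0, 0))
  xl <- data.frame(protein1 = "A", residue1 = c(5L, 5L, 15L, 5L),
                   protein2 = "A", residue2 = c(15L, 25L, 25L, 35L),
                   linker = "DSS", multiplicity = 1L)
  rep2 <- satisfaction_report(list(st$coords), st,
                              list(crosslinks = xl), cutoff = 35)
  expect_equal(rep2$pct_satisfied_ensemble, 75)
  # ensemble-level rate is never below the per-model mean
  mixed <- satisfaction_report(list(st$coords, st$coords * 1.5), st,
                               list(crosslinks = xl), cutoff = 35)
  expect_gte(mixed$pct_satisfied_ensemble,
             mean(mixed$pct_satisfied_per_model))
})
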