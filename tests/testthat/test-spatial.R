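test_that("pairwise distances stay within tomograms", {
  d <- data.frame(tomogram = c("t1", "t1", "t2", "t2", "t2"),
                  x = c(0, 50, 0, 3, 7), y = 0, z = 0)
  pt <- particle_table(d, units = "nm")
  pd <- pairwise_distances(pt)
  expect_equal(pd$t1, 50)
  expect_equal(sort(pd$t2), c(3, 4, 7))
  # 2 + 3 points -> 1 + 3 pairs, never the 6 cross-tomogram ones
  expect_equal(sum(lengths(pd)), 4L)
  expect_error(particle_table(d), "units")
  # coordinates outside a declared box are rejected
  box <- list(t1 = rbind(c(0, 10), c(0, 10), c(0, 10)),
              t2 = rbind(c(0, 10), c(0, 10), c(0, 10)))
  expect_error(particle_table(d, units = "nm", boxes = box), "outside")
})

test_that("a single pair lands only in its distance bin", {
  d <- data.frame(tomogram = "t1", x = c(100, 205), y = 100, z = 100)
  box <- list(t1 = rbind(c(0, 400), c(0, 400), c(0, 400)))
  pt <- particle_table(d, units = "nm", boxes = box)
  gr <- radial_distribution(pt, bin_width = 25, r_max = 200)
  hit <- which(gr$g > 0)
  expect_length(hit, 1L)
  expect_true(gr$r[hit] > 100 & gr$r[hit] < 125)
})

test_that("CSR input gives g(r) ~ 1 within the analytic envelope", {
  pt <- simulate_csr_table(n_tomograms = 12, n_per_tomogram = 120,
                           box_edge = 1000, seed = 5)
  gr <- radial_distribution(pt, bin_width = 25)
  bins <- seq(3, length(gr$r))
  env <- gr_csr_envelope(gr, level = 0.95, bins = bins)
  inside <- gr$g >= env$lo & gr$g <= env$hi
  # beyond the first two bins the whole curve stays inside the 95%
  # (curve-wise) envelope
  expect_true(all(inside[bins]))
  expect_true(all(gr$g >= 0))
  # doubling the intensity leaves the CSR expectation at 1
  pt2 <- simulate_csr_table(n_tomograms = 12, n_per_tomogram = 240,
                            box_edge = 1000, seed = 6)
  gr2 <- radial_distribution(pt2, bin_width = 25)
  expect_lt(abs(mean(gr2$g[-(1:2)]) - 1), 0.05)
})

test_that("averaging is per tomogram, not pooled pairs", {
  # tomogram A has many points, B has few: the mean curve weights both
  # tomograms equally
  set.seed(3)
  mk <- function(tm, n) data.frame(tomogram = tm,
                                   x = runif(n, 0, 500),
                                   y = runif(n, 0, 500),
                                   z = runif(n, 0, 500))
  d <- rbind(mk("a", 150), mk("b", 10))
  box <- rbind(c(0, 500), c(0, 500), c(0, 500))
  pt <- particle_table(d, units = "nm", boxes = list(a = box, b = box))
  gr <- radial_distribution(pt, bin_width = 50)
  expect_equal(gr$g, colMeans(gr$per_tomogram))
  expect_equal(nrow(gr$per_tomogram), 2L)
})

test_that("class filters select particle subsets", {
  d <- data.frame(tomogram = "t1", x = c(0, 50, 200), y = 0, z = 0,
                  class = c("single", "double", "double"))
  box <- list(t1 = rbind(c(0, 400), c(-200, 200), c(-200, 200)))
  pt <- particle_table(d, units = "nm", boxes = box)
  expect_equal(pairwise_distances(pt, classes = "double")$t1, 150)
  expect_error(radial_distribution(pt, classes = "nope"), "no particles")
})
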