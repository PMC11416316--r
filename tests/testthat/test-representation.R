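test_that("subunit specs validate segment tiling and copies", {
  expect_s3_class(subunit_spec("X", 100), "subunit_spec")
  expect_error(subunit_spec("X", 100, copies = 0), "copies")
  expect_error(subunit_spec("X", 100, segments = data.frame(
    first = c(1L, 40L), last = c(50L, 100L), kind = "disordered")),
    "gaps/overlap")
  expect_error(subunit_spec("X", 100, segments = data.frame(
    first = 1L, last = 90L, kind = "disordered")), "cover")
  sp <- subunit_spec("X", sequence = strrep("A", 37))
  expect_equal(sp$length, 37L)
})

test_that("coarse-graining centers windows and sizes radii", {
  # 10 collinear residues at 1 A spacing -> one bead at the midpoint
  line <- cbind(0:9, 0, 0)
  cg <- coarse_grain(line, 10)
  expect_equal(unname(cg$coords[1, ]), c(4.5, 0, 0))
  expect_equal(cg$radius, bead_radius(10))
  # residues_per_bead = 1 reproduces the input positions
  cg1 <- coarse_grain(line, 1)
  expect_equal(unname(cg1$coords), unname(line))
  # 20 residues at 10 per bead -> 2 beads with equal radii
  cg2 <- coarse_grain(cbind(0:19, 0, 0), 10)
  expect_equal(nrow(cg2$coords), 2L)
  expect_equal(cg2$radius[1], cg2$radius[2])
  expect_equal(cg2$res_first, c(1L, 11L))
  expect_error(coarse_grain(matrix(0, 0, 3), 10), "empty")
})

test_that("stated stoichiometries give 21/12 (yeast) and 24/12 (mouse)", {
  y <- count_stoichiometry(yeast_basket_specs())
  expect_identical(y$n_subunits, 21L)
  expect_identical(y$n_types, 12L)
  m <- count_stoichiometry(mouse_basket_specs())
  expect_identical(m$n_subunits, 24L)
  expect_identical(m$n_types, 12L)
})

test_that("build_representation instantiates copies, drops excluded
          segments, and is deterministic", {
  s1 <- build_representation(yeast_basket_specs())
  s2 <- build_representation(yeast_basket_specs())
  expect_identical(s1$coords, s2$coords)
  # total represented residues = sum((length - excluded) * copies)
  expected <- sum(vapply(yeast_basket_specs(), function(sp) {
    exc <- sp$segments$kind == "excluded"
    (sp$length - sum(sp$segments$last[exc] - sp$segments$first[exc] + 1L)) *
      sp$copies
  }, numeric(1)))
  expect_equal(n_represented_residues(s1), expected)
  # degenerate one-bead chain
  one <- build_representation(subunit_spec("T", 10))
  expect_equal(n_beads(one), 1L)
  expect_equal(one$bead$res_last, 10L)
  # excluded-only middle segment shortens the chain
  sp <- subunit_spec("E", 30, segments = data.frame(
    first = c(1L, 11L, 21L), last = c(10L, 20L, 30L),
    kind = c("disordered", "excluded", "disordered")))
  st <- build_representation(sp)
  expect_equal(n_beads(st), 2L)
  expect_equal(n_represented_residues(st), 20)
})

test_that("rigid segments with source coordinates become dual-resolution
          rigid bodies", {
  src <- cbind(seq(0, 19), 0, 0)
  sp <- subunit_spec("R", 20, segments = data.frame(
    first = 1L, last = 20L, kind = "rigid"), source_model = src)
  st <- build_representation(sp)
  expect_length(st$bodies, 1L)
  expect_setequal(unique(st$bead$resolution), c(1L, 10L))
  # fine level = 20 beads, coarse = 2 beads, all in the body
  expect_equal(n_beads(st), 22L)
  expect_length(st$bodies[[1]], 22L)
})

test_that("symmetry images are exact rotations that preserve counts", {
  st <- build_representation(subunit_spec("T", 40))
  expect_equal(apply_symmetry(st, 1)[[1]]$coords, st$coords)
  imgs <- apply_symmetry(st, 8)
  th <- 2 * pi * 3 / 8
  Rm <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_lt(max(abs(imgs[[4]]$coords - st$coords %*% t(Rm))), 1e-9)
  full <- do.call(rbind, lapply(imgs, `[[`, "coords"))
  expect_equal(nrow(full), 8L * n_beads(st))
})
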