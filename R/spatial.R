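## Pairwise distances and the radial distribution function g(r) of
## particle coordinates per tomogram, averaged over tomograms. Particles
## are treated as a 3D point pattern inside each tomogram's box;
## normalization uses the box's isotropised set covariance (translational
## edge correction), evaluated by spherical quadrature.

#' Particle table: per-tomogram point coordinates
#'
#' @param data Data frame with columns `tomogram`, `x`, `y`, `z` and
#'   optionally `class`.
#' @param units Declared length unit, `"nm"` or `"A"` (required).
#' @param boxes Optional named list of 3x2 matrices (rows x/y/z, columns
#'   min/max) per tomogram; defaults to each tomogram's coordinate range.
#' @return Object of class `particle_table`.
#' @export
particle_table <- function(data, units, boxes = NULL) {
  if (missing(units) || !units %in% c("nm", "A"))
    stop("particle_table: units must be declared as \"nm\" or \"A\"")
  need <- c("tomogram", "x", "y", "z")
  if (!all(need %in% names(data)))
    stop("particle_table: need columns tomogram, x, y, z")
  if (is.null(data$class)) data$class <- "all"
  toms <- unique(data$tomogram)
  if (is.null(boxes)) {
    boxes <- lapply(toms, function(tm) {
      d <- data[data$tomogram == tm, ]
      rbind(range(d$x), range(d$y), range(d$z))
    })
    names(boxes) <- toms
  }
  for (tm in toms) {
    d <- data[data$tomogram == tm, ]
    b <- boxes[[as.character(tm)]]
    if (is.null(b)) stop("particle_table: no box for tomogram ", tm)
    inside <- d$x >= b[1, 1] & d$x <= b[1, 2] & d$y >= b[2, 1] &
      d$y <= b[2, 2] & d$z >= b[3, 1] & d$z <= b[3, 2]
    if (!all(inside))
      stop("particle_table: coordinates outside the box in tomogram ", tm)
  }
  structure(list(data = data, units = units, boxes = boxes),
            class = "particle_table")
}

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf("<particle_table> %d particles in %d tomogram(s) [%s]\n",
              nrow(x$data), length(x$boxes), x$units))
  invisible(x)
}

#' Within-tomogram pairwise distances
#'
#' All unordered pair distances for the filtered class(es), grouped per
#' tomogram; pairs never cross tomograms.
#'
#' @param table A [particle_table()].
#' @param classes Optional class filter.
#' @return Named list of numeric distance vectors, one per tomogram.
#' @export
pairwise_distances <- function(table, classes = NULL) {
  stopifnot(inherits(table, "particle_table"))
  d <- table$data
  if (!is.null(classes)) d <- d[d$class %in% classes, ]
  out <- lapply(split(d, d$tomogram), function(g)
    if (nrow(g) < 2L) numeric(0) else
      as.numeric(dist(as.matrix(g[, c("x", "y", "z")]))))
  out[order(names(out))]
}

## isotropised set covariance of a box with edges L at radius r, by
## quadrature over a Fibonacci sphere: mean over directions u of
## prod_i max(L_i - r |u_i|, 0)
box_set_covariance <- function(r, L, n_dirs = 300L) {
  i <- seq_len(n_dirs) - 0.5
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  cz <- 1 - 2 * i / n_dirs
  sz <- sqrt(pmax(0, 1 - cz^2))
  U <- abs(cbind(sz * cos(phi), sz * sin(phi), cz))
  vapply(r, function(ri) {
    v <- pmax(L[1] - ri * U[, 1], 0) * pmax(L[2] - ri * U[, 2], 0) *
      pmax(L[3] - ri * U[, 3], 0)
    mean(v)
  }, numeric(1))
}

## expected pair counts per bin for n CSR points in a box with edges L:
## n(n-1)/2 * integral over bin of 4 pi r^2 cbar(r) dr / V^2
expected_pairs <- function(breaks, n, L) {
  V <- prod(L)
  vapply(seq_len(length(breaks) - 1L), function(b) {
    rr <- seq(breaks[b], breaks[b + 1], length.out = 5L)
    f <- 4 * pi * rr^2 * box_set_covariance(rr, L) / V^2
    h <- diff(rr[1:2])
    int <- h * (f[1] / 2 + f[2] + f[3] + f[4] + f[5] / 2)
    n * (n - 1) / 2 * int
  }, numeric(1))
}

#' Radial distribution function per tomogram, averaged over tomograms
#'
#' For each tomogram, `g(r)` in each distance bin is the observed pair
#' count divided by the count expected for a homogeneous (CSR) process of
#' the same intensity in the same box, with translational edge
#' correction. The final curve is the unweighted mean of the per-tomogram
#' curves (not pooled pairs). Tomograms with fewer than two filtered
#' particles are skipped.
#'
#' @param table A [particle_table()].
#' @param bin_width Bin width in the table's units (default 25).
#' @param r_max Maximum distance; default half the shortest box edge.
#' @param classes Optional class filter.
#' @return List of class `gr_result`: `r` (bin midpoints), `g` (mean
#'   curve), `per_tomogram` and `expected` matrices, `counts`,
#'   `bin_width`, `units`.
#' @export
radial_distribution <- function(table, bin_width = 25, r_max = NULL,
                                classes = NULL) {
  stopifnot(inherits(table, "particle_table"))
  d <- table$data
  if (!is.null(classes)) d <- d[d$class %in% classes, ]
  if (!nrow(d)) stop("radial_distribution: no particles after filtering")
  edges <- vapply(table$boxes, function(b) b[, 2] - b[, 1], numeric(3))
  if (is.null(r_max)) r_max <- min(edges) / 2
  breaks <- seq(0, r_max, by = bin_width)
  if (length(breaks) < 2L)
    stop("radial_distribution: r_max smaller than one bin")
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  per <- list(); expd <- list(); cnts <- list()
  for (tm in names(table$boxes)) {
    g <- d[d$tomogram == tm, ]
    if (nrow(g) < 2L) next
    L <- table$boxes[[tm]][, 2] - table$boxes[[tm]][, 1]
    dd <- as.numeric(dist(as.matrix(g[, c("x", "y", "z")])))
    obs <- graphics::hist(dd[dd < max(breaks)], breaks = breaks,
                          plot = FALSE)$counts
    ex <- expected_pairs(breaks, nrow(g), L)
    per[[tm]] <- obs / ex
    expd[[tm]] <- ex
    cnts[[tm]] <- obs
  }
  if (!length(per))
    stop("radial_distribution: need >= 2 particles in >= 1 tomogram")
  P <- do.call(rbind, per)
  used <- rownames(P)
  n_used <- vapply(used, function(tm) sum(d$tomogram == tm), integer(1))
  structure(list(r = mids, g = colMeans(P), per_tomogram = P,
                 expected = do.call(rbind, expd),
                 counts = do.call(rbind, cnts),
                 bin_width = bin_width, units = table$units,
                 breaks = breaks, boxes = table$boxes[used],
                 n_particles = n_used),
            class = "gr_result")
}

#' @export
print.gr_result <- function(x, ...) {
  cat(sprintf("<gr_result> %d bins of %.0f %s over %d tomogram(s)\n",
              length(x$r), x$bin_width, x$units, nrow(x$per_tomogram)))
  invisible(x)
}

#' Monte-Carlo CSR envelope for an averaged g(r) curve
#'
#' Global (curve-wise) null envelope of the tomogram-averaged g(r) under
#' complete spatial randomness, by simulation: CSR replicates with the
#' observed tomogram boxes and particle counts are generated, each
#' replicate's mean curve is reduced to its maximum studentized
#' deviation from 1 over the tested bins, and the envelope half-width is
#' that statistic's `level` quantile times the per-bin replicate spread.
#' The whole tested curve stays inside the envelope with probability
#' `level` under CSR. Deterministic in `seed`.
#'
#' @param gr A `gr_result`.
#' @param level Coverage level (default 0.95).
#' @param n_sim Number of CSR replicates (default 99).
#' @param bins Bin indices the envelope must cover jointly (default all).
#' @param seed Seed for the replicate stream.
#' @return Data frame with `r`, `lo`, `hi` (non-tested bins get the
#'   pointwise band).
#' @export
gr_csr_envelope <- function(gr, level = 0.95, n_sim = 99L,
                            bins = seq_along(gr$r), seed = 1L) {
  M <- nrow(gr$per_tomogram)
  nb <- length(gr$r)
  G <- with_seed(seed, {
    t(vapply(seq_len(n_sim), function(b) {
      acc <- matrix(0, M, nb)
      for (t in seq_len(M)) {
        bx <- gr$boxes[[t]]
        n <- gr$n_particles[t]
        pts <- cbind(runif(n, bx[1, 1], bx[1, 2]),
                     runif(n, bx[2, 1], bx[2, 2]),
                     runif(n, bx[3, 1], bx[3, 2]))
        dd <- as.numeric(dist(pts))
        obs <- graphics::hist(dd[dd < max(gr$breaks)],
                              breaks = gr$breaks, plot = FALSE)$counts
        acc[t, ] <- obs / gr$expected[t, ]
      }
      colMeans(acc)
    }, numeric(nb)))
  })
  s <- pmax(apply(G, 2, stats::sd), 1e-12)
  tmax <- apply(abs(G[, bins, drop = FALSE] - 1) /
                  rep(s[bins], each = n_sim), 1, max)
  # exact rank-based critical value: the m-th largest replicate statistic
  # gives an envelope the observed curve escapes with probability
  # (1 - level) under CSR
  m <- max(1L, floor((1 - level) * (n_sim + 1L)))
  crit <- sort(tmax, decreasing = TRUE)[m]
  data.frame(r = gr$r, lo = 1 - crit * s, hi = 1 + crit * s)
}

#' Simulate a CSR particle table
#'
#' Homogeneous Poisson-like pattern: `n_per_tomogram` uniform points per
#' tomogram box. Used for null calibration of [radial_distribution()].
#'
#' @param n_tomograms,n_per_tomogram Table dimensions.
#' @param box_edge Cubic box edge length.
#' @param units Length unit label.
#' @param seed Integer seed.
#' @export
simulate_csr_table <- function(n_tomograms = 10L, n_per_tomogram = 100L,
                               box_edge = 1000, units = "nm", seed = 1L) {
  with_seed(seed, {
    d <- do.call(rbind, lapply(seq_len(n_tomograms), function(tm)
      data.frame(tomogram = sprintf("t%02d", tm),
                 x = runif(n_per_tomogram, 0, box_edge),
                 y = runif(n_per_tomogram, 0, box_edge),
                 z = runif(n_per_tomogram, 0, box_edge))))
    boxes <- lapply(unique(d$tomogram), function(tm)
      rbind(c(0, box_edge), c(0, box_edge), c(0, box_edge)))
    names(boxes) <- unique(d$tomogram)
    particle_table(d, units = units, boxes = boxes)
  })
}
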