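#' @useDynLib npcbasket, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rnorm setNames ks.test chisq.test qnorm var dist
#' @importFrom utils read.csv write.csv head
NULL

SEGMENT_KINDS <- c("rigid", "coiled-coil", "disordered", "excluded")

#' Declare one subunit of the assembly
#'
#' A subunit specification carries the protein name, its length in
#' residues (or a sequence, from which the length is taken), the number of
#' copies per symmetry unit, and a segment annotation that tiles the
#' sequence into rigid, coiled-coil, disordered and excluded stretches.
#' Excluded segments (typically FG-repeat regions) produce no beads.
#'
#' @param name Subunit identifier, e.g. `"Mlp1"`.
#' @param length Length in residues. Ignored when `sequence` is given.
#' @param sequence Optional amino-acid sequence string.
#' @param copies Copies per symmetry unit (>= 1).
#' @param segments Data frame with columns `first`, `last`, `kind`
#'   (one of `"rigid"`, `"coiled-coil"`, `"disordered"`, `"excluded"`).
#'   Segments must tile `1..length` without gaps or overlap. Default:
#'   one disordered segment covering the whole chain.
#' @param source_model Optional matrix of per-residue coordinates (rows =
#'   residues of the rigid segments, in residue order) used to build rigid
#'   bodies for `"rigid"` segments.
#' @return An object of class `subunit_spec`.
#' @export
subunit_spec <- function(name, length = NULL, sequence = NULL, copies = 1L,
                         segments = NULL, source_model = NULL) {
  if (!is.null(sequence)) length <- nchar(sequence)
  if (is.null(length) || length < 1L)
    stop("subunit_spec: '", name, "' needs a positive length or a sequence")
  copies <- as.integer(copies)
  if (copies < 1L) stop("subunit_spec: '", name, "' needs copies >= 1")
  if (is.null(segments))
    segments <- data.frame(first = 1L, last = as.integer(length),
                           kind = "disordered")
  segments <- segments[order(segments$first), , drop = FALSE]
  if (!all(segments$kind %in% SEGMENT_KINDS))
    stop("subunit_spec: unknown segment kind in '", name, "'")
  expect <- 1L
  for (i in seq_len(nrow(segments))) {
    if (segments$first[i] != expect)
      stop("subunit_spec: segments of '", name,
           "' must tile 1..length without gaps/overlap (at residue ",
           segments$first[i], ", expected ", expect, ")")
    expect <- segments$last[i] + 1L
  }
  if (expect != length + 1L)
    stop("subunit_spec: segments of '", name, "' do not cover 1..", length)
  structure(list(name = name, length = as.integer(length), copies = copies,
                 segments = segments, source_model = source_model),
            class = "subunit_spec")
}

#' @export
print.subunit_spec <- function(x, ...) {
  cat(sprintf("<subunit_spec> %s: %d aa x %d copies, %d segment(s)\n",
              x$name, x$length, x$copies, nrow(x$segments)))
  invisible(x)
}

#' Coarse-graining policy
#'
#' Multiscale schedule mapping residues to beads. Rigid segments backed by
#' a source model are represented at both a fine and a coarse level
#' (crosslinks are scored at the finer level, excluded volume at the
#' coarser one); flexible segments are represented at the coarse level
#' only. Bead radius is volume-proportional:
#' `r = r0 * n_residues^(1/3)`.
#'
#' @param flexible_res_per_bead Residues per bead for flexible strings.
#' @param rigid_fine,rigid_coarse Residues per bead for the two levels of
#'   rigid segments with coordinates.
#' @param r0 Radius scale in Angstrom for a one-residue bead.
#' @return A list of class `cg_policy`.
#' @export
cg_policy <- function(flexible_res_per_bead = 10L, rigid_fine = 1L,
                      rigid_coarse = 10L, r0 = 3.0) {
  stopifnot(flexible_res_per_bead >= 1L, rigid_fine >= 1L, rigid_coarse >= 1L,
            r0 > 0)
  structure(list(flexible_res_per_bead = as.integer(flexible_res_per_bead),
                 rigid_fine = as.integer(rigid_fine),
                 rigid_coarse = as.integer(rigid_coarse), r0 = r0),
            class = "cg_policy")
}

#' Radius of a coarse-grained bead
#'
#' Volume-equivalent sphere for `nres` residues: `r0 * nres^(1/3)`.
#'
#' @param nres Residue count per bead.
#' @param r0 One-residue radius in Angstrom.
#' @export
bead_radius <- function(nres, r0 = 3.0) r0 * nres^(1 / 3)

#' Coarse-grain per-residue coordinates into a bead chain
#'
#' Consecutive windows of `residues_per_bead` residues collapse into one
#' bead whose center is the window centroid and whose radius is the
#' volume-equivalent sphere for the window's residue count.
#'
#' @param coords Numeric matrix (n_residues x 3) ordered by residue index.
#' @param residues_per_bead Window size.
#' @param r0 Radius scale (Angstrom).
#' @param res_start Residue index of the first row (1-based).
#' @return List with `coords` (beads x 3), `radius`, `res_first`,
#'   `res_last`, `nres`.
#' @export
coarse_grain <- function(coords, residues_per_bead, r0 = 3.0, res_start = 1L) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("coarse_grain: empty input coordinates")
  if (ncol(coords) != 3L) stop("coarse_grain: coords must be n x 3")
  n <- nrow(coords)
  k <- as.integer(residues_per_bead)
  stopifnot(k >= 1L)
  starts <- seq.int(1L, n, by = k)
  ends <- pmin(starts + k - 1L, n)
  centers <- t(vapply(seq_along(starts), function(i)
    colMeans(coords[starts[i]:ends[i], , drop = FALSE]), numeric(3)))
  nres <- ends - starts + 1L
  list(coords = centers, radius = bead_radius(nres, r0),
       res_first = as.integer(res_start + starts - 1L),
       res_last = as.integer(res_start + ends - 1L), nres = nres)
}

## ---- assembly state ------------------------------------------------------

new_assembly_state <- function(coords, radius, bead, bodies = list(),
                               body_fixed = logical(0), n_symmetry = 8L) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  stopifnot(ncol(coords) == 3L, nrow(coords) == length(radius),
            nrow(bead) == nrow(coords), all(radius > 0),
            length(bodies) == length(body_fixed))
  bead_body <- rep(NA_integer_, nrow(coords))
  for (b in seq_along(bodies)) {
    idx <- bodies[[b]]
    if (any(!is.na(bead_body[idx])))
      stop("assembly_state: a bead may belong to at most one rigid body")
    bead_body[idx] <- b
  }
  chain_key <- paste(bead$subunit, bead$copy, bead$resolution, sep = "\r")
  chain <- match(chain_key, unique(chain_key))
  bead$chain <- chain
  structure(list(coords = coords, radius = as.numeric(radius), bead = bead,
                 bodies = bodies, body_fixed = body_fixed,
                 bead_body = bead_body, n_symmetry = as.integer(n_symmetry)),
            class = "assembly_state")
}

#' @export
print.assembly_state <- function(x, ...) {
  nfix <- if (length(x$bodies)) sum(lengths(x$bodies)[x$body_fixed]) else 0L
  cat(sprintf(paste0("<assembly_state> %d beads, %d chains, %d rigid bodies",
                     " (%d beads fixed), C%d symmetry\n"),
              nrow(x$coords), max(x$bead$chain), length(x$bodies), nfix,
              x$n_symmetry))
  invisible(x)
}

#' Number of beads in a state
#' @param state An `assembly_state`.
#' @export
n_beads <- function(state) nrow(state$coords)

#' Indices of movable beads
#'
#' Beads outside any rigid body, or inside a non-fixed body.
#' @param state An `assembly_state`.
#' @export
movable_beads <- function(state) {
  fixed <- !is.na(state$bead_body) & state$body_fixed[state$bead_body]
  which(!fixed)
}

#' Indices of fixed (scaffold) beads
#' @param state An `assembly_state`.
#' @export
fixed_beads <- function(state) {
  if (!length(state$bodies)) return(integer(0))
  which(!is.na(state$bead_body) & state$body_fixed[state$bead_body])
}

#' Total residues represented in a state
#'
#' Sums the residue counts of coarse-level beads (the finer rigid level
#' duplicates residues already counted at the coarse level).
#' @param state An `assembly_state`.
#' @export
n_represented_residues <- function(state) {
  coarse <- state$bead$resolution == max(state$bead$resolution) |
    !duplicated(paste(state$bead$subunit, state$bead$copy))
  b <- state$bead
  per_chain <- tapply(seq_len(nrow(b)), b$chain, function(ix) {
    sum(b$res_last[ix] - b$res_first[ix] + 1L)
  })
  # count each (subunit, copy) once, at its coarsest resolution level
  info <- unique(b[, c("chain", "subunit", "copy", "resolution")])
  keep <- unlist(lapply(split(info, paste(info$subunit, info$copy)),
                        function(d) d$chain[which.max(d$resolution)]))
  sum(per_chain[as.character(keep)])
}

## ---- build ---------------------------------------------------------------

#' Build the multiscale bead representation of one symmetry unit
#'
#' Instantiates every copy of every subunit. Excluded segments produce no
#' beads. Rigid segments with a `source_model` become rigid bodies carried
#' at two resolutions (fine and coarse, moving together); all other
#' segments become flexible strings of coarse beads. Chains without source
#' coordinates are laid out as straight rods (arbitrary placement; sampling
#' randomizes movable parts anyway).
#'
#' @param specs List of [subunit_spec()] objects.
#' @param policy A [cg_policy()].
#' @param n_symmetry Rotational symmetry order of the full assembly.
#' @return An `assembly_state` for one symmetry unit.
#' @export
build_representation <- function(specs, policy = cg_policy(),
                                 n_symmetry = 8L) {
  if (inherits(specs, "subunit_spec")) specs <- list(specs)
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("build_representation: duplicate subunit names")
  coords <- list(); radius <- list(); bead <- list()
  bodies <- list(); body_fixed <- logical(0)
  lane <- 0L
  for (sp in specs) {
    for (cp in seq_len(sp$copies)) {
      lane <- lane + 1L
      body_beads <- integer(0)
      for (si in seq_len(nrow(sp$segments))) {
        seg <- sp$segments[si, ]
        if (seg$kind == "excluded") next
        seg_len <- seg$last - seg$first + 1L
        rigid <- seg$kind == "rigid" && !is.null(sp$source_model)
        if (rigid) {
          src <- as.matrix(sp$source_model)
          rows <- seg$first:seg$last
          if (max(rows) > nrow(src))
            stop("build_representation: source_model of '", sp$name,
                 "' shorter than rigid segment")
          src <- src[rows, , drop = FALSE]
          levels <- unique(c(policy$rigid_fine, policy$rigid_coarse))
          for (rpb in levels) {
            cg <- coarse_grain(src, rpb, policy$r0, res_start = seg$first)
            nb <- nrow(cg$coords)
            at <- sum(vapply(coords, nrow, 1L))
            coords[[length(coords) + 1L]] <- cg$coords
            radius[[length(radius) + 1L]] <- cg$radius
            bead[[length(bead) + 1L]] <- data.frame(
              subunit = sp$name, copy = cp, resolution = rpb,
              res_first = cg$res_first, res_last = cg$res_last,
              nres = cg$nres)
            body_beads <- c(body_beads, at + seq_len(nb))
          }
        } else {
          rpb <- policy$flexible_res_per_bead
          starts <- seq.int(seg$first, seg$last, by = rpb)
          ends <- pmin(starts + rpb - 1L, seg$last)
          nres <- ends - starts + 1L
          rad <- bead_radius(nres, policy$r0)
          # straight rod along +x, one lane per chain along y
          x0 <- cumsum(2 * rad) - rad
          pos <- cbind(x0 + 2 * seg$first, 25 * lane, 0)
          coords[[length(coords) + 1L]] <- pos
          radius[[length(radius) + 1L]] <- rad
          bead[[length(bead) + 1L]] <- data.frame(
            subunit = sp$name, copy = cp, resolution = rpb,
            res_first = as.integer(starts), res_last = as.integer(ends),
            nres = nres)
        }
      }
      if (length(body_beads)) {
        bodies[[length(bodies) + 1L]] <- body_beads
        body_fixed <- c(body_fixed, FALSE)
      }
    }
  }
  if (!length(coords)) stop("build_representation: no beads produced")
  new_assembly_state(do.call(rbind, coords), unlist(radius),
                     do.call(rbind, bead), bodies, body_fixed, n_symmetry)
}

## ---- symmetry ------------------------------------------------------------

rot_z <- function(theta) {
  c_ <- cos(theta); s <- sin(theta)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

#' Rotational symmetry images of a symmetry unit
#'
#' Returns the `n` images of the state rotated about the central (z) axis
#' by multiples of `2*pi/n`, for clash checks and full-assembly export.
#' The input state is image 1 (identity) and is not modified.
#'
#' @param state An `assembly_state`.
#' @param n Symmetry order (>= 1). Defaults to the state's symmetry.
#' @return List of `n` assembly states.
#' @export
apply_symmetry <- function(state, n = state$n_symmetry) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  lapply(seq_len(n) - 1L, function(k) {
    out <- state
    out$coords <- state$coords %*% t(rot_z(2 * pi * k / n))
    out
  })
}

#' Count subunit instances and distinct types
#'
#' @param specs List of [subunit_spec()] objects.
#' @return List with `n_subunits` (sum of copies) and `n_types`
#'   (distinct subunit names).
#' @export
count_stoichiometry <- function(specs) {
  if (inherits(specs, "subunit_spec")) specs <- list(specs)
  list(n_subunits = sum(vapply(specs, `[[`, integer(1), "copies")),
       n_types = length(unique(vapply(specs, `[[`, character(1), "name"))))
}
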