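## Synthetic basket generator: a ground-truth assembly with known geometry
## plus simulated versions of every input the pipeline consumes.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters of the synthetic ground-truth basket
#'
#' Geometry of an idealized eight-fold-symmetric basket: a fixed two-tier
#' scaffold ring (the double nuclear ring), strut chains tilted from the
#' central axis that converge on a distal ring, and short flexible anchor
#' chains near the scaffold. The yeast preset uses a 30 degree strut tilt,
#' a 540 Angstrom axial distal offset and a 760 Angstrom distal ring
#' diameter; the mouse preset uses 6 degrees, 630 Angstrom and a 1000
#' Angstrom distal diameter. Struts are ~100 Angstrom thick. The strut
#' attachment radius (`scaffold_ring_radius`) is derived from tilt, offset
#' and distal diameter so the three are geometrically consistent:
#' `R = D/2 + offset * tan(tilt)`.
#'
#' @param n_symmetry Rotational symmetry order (default 8).
#' @param strut_tilt Strut angle from the central axis, degrees in [0, 90).
#' @param distal_offset Axial distance from the scaffold plane to the
#'   distal ring, Angstrom.
#' @param distal_ring_diameter Diameter of the distal ring, Angstrom.
#' @param strut_thickness Lateral separation scale of the two strut
#'   chains, Angstrom.
#' @param scaffold_ring_radius Strut attachment radius, Angstrom; derived
#'   from the other parameters when `NULL`.
#' @param beads_per_strut Coarse beads along each strut chain.
#' @param anchor_chain_lengths Named integer vector of residue counts for
#'   the flexible anchor chains (names become subunit names; a name may
#'   repeat via `copies` encoded as duplicated names).
#' @param seed Integer seed controlling the stochastic parts (anchor-chain
#'   conformations).
#' @return An object of class `ground_truth_params`.
#' @export
ground_truth_params <- function(n_symmetry = 8L, strut_tilt = 30,
                                distal_offset = 540,
                                distal_ring_diameter = 760,
                                strut_thickness = 100,
                                scaffold_ring_radius = NULL,
                                beads_per_strut = 45L,
                                anchor_chain_lengths = c(Nup1s = 60, Nup60s = 50,
                                                         Nup2s = 40),
                                seed = 1L) {
  if (n_symmetry < 1L) stop("ground_truth_params: n_symmetry must be >= 1")
  if (strut_tilt < 0 || strut_tilt >= 90)
    stop("ground_truth_params: strut_tilt must be in [0, 90) degrees")
  if (distal_offset <= 0 || distal_ring_diameter <= 0 || strut_thickness <= 0)
    stop("ground_truth_params: all lengths must be positive")
  if (beads_per_strut < 2L)
    stop("ground_truth_params: beads_per_strut must be >= 2")
  if (is.null(scaffold_ring_radius))
    scaffold_ring_radius <- distal_ring_diameter / 2 +
      distal_offset * tan(strut_tilt * pi / 180)
  if (scaffold_ring_radius <= 0)
    stop("ground_truth_params: scaffold_ring_radius must be positive")
  structure(list(n_symmetry = as.integer(n_symmetry), strut_tilt = strut_tilt,
                 distal_offset = distal_offset,
                 distal_ring_diameter = distal_ring_diameter,
                 strut_thickness = strut_thickness,
                 scaffold_ring_radius = scaffold_ring_radius,
                 beads_per_strut = as.integer(beads_per_strut),
                 anchor_chain_lengths = anchor_chain_lengths,
                 seed = as.integer(seed)),
            class = "ground_truth_params")
}

#' Preset synthetic-basket parameters
#'
#' @param preset `"yeast"` (30 degree tilt, 540 A offset, 760 A distal
#'   ring) or `"mouse"` (6 degrees, 630 A, 1000 A).
#' @param ... Overrides passed to [ground_truth_params()].
#' @export
basket_preset <- function(preset = c("yeast", "mouse"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    yeast = list(strut_tilt = 30, distal_offset = 540,
                 distal_ring_diameter = 760),
    mouse = list(strut_tilt = 6, distal_offset = 630,
                 distal_ring_diameter = 1000))
  do.call(ground_truth_params, utils::modifyList(args, list(...)))
}

SYN_BLOB_BEADS <- 3L
SYN_RES_PER_BEAD <- 10L

## specs for the synthetic unit; scaffold carries a source model so it
## becomes a (fixed) rigid body under the standard representation policy
synthetic_specs <- function(params) {
  R <- params$scaffold_ring_radius
  sector <- 2 * pi / params$n_symmetry
  n_res_tier <- 80L
  ang <- -sector / 2 + sector * (seq_len(n_res_tier) - 0.5) / n_res_tier
  tier <- function(z) cbind(R * cos(ang), R * sin(ang), z)
  scaffold_src <- rbind(tier(80), tier(0))   # proximal tier above, strut tier at z = 0
  mlp_res <- (params$beads_per_strut + SYN_BLOB_BEADS) * SYN_RES_PER_BEAD
  seg_cc <- function(n) data.frame(first = 1L, last = as.integer(n),
                                   kind = "coiled-coil")
  specs <- list(
    subunit_spec("NRscaffold", 2L * n_res_tier, copies = 1,
                 segments = data.frame(first = 1L, last = 2L * n_res_tier,
                                       kind = "rigid"),
                 source_model = scaffold_src),
    subunit_spec("Mlp1s", mlp_res, copies = 1, segments = seg_cc(mlp_res)),
    subunit_spec("Mlp2s", mlp_res, copies = 1, segments = seg_cc(mlp_res))
  )
  acl <- params$anchor_chain_lengths
  copies <- c(Nup1s = 1L, Nup60s = 2L, Nup2s = 2L)
  for (nm in names(acl)) {
    cp <- if (nm %in% names(copies)) copies[[nm]] else 1L
    specs[[length(specs) + 1L]] <-
      subunit_spec(nm, acl[[nm]], copies = cp,
                   segments = data.frame(first = 1L, last = as.integer(acl[[nm]]),
                                         kind = "disordered"))
  }
  specs
}

#' Generate the ground-truth synthetic basket (one symmetry unit)
#'
#' Builds the multiscale representation of the synthetic unit and places
#' its beads at the ground-truth geometry: a fixed two-tier scaffold arc,
#' two parallel strut chains of collinear beads tilted by `strut_tilt`
#' from the central (z) axis and terminating in a three-bead distal blob
#' whose centroid sits exactly `distal_offset` below the scaffold plane at
#' the distal-ring radius, plus flexible anchor chains placed as seeded
#' compact walks near the scaffold. Deterministic in `params$seed`.
#'
#' @param params A [ground_truth_params()] object.
#' @param policy Coarse-graining policy (see [cg_policy()]).
#' @return An `assembly_state` with attribute `"synthetic"` carrying the
#'   parameters, strut subunit names and blob size.
#' @export
make_ground_truth <- function(params = basket_preset("yeast"),
                              policy = cg_policy()) {
  stopifnot(inherits(params, "ground_truth_params"))
  state <- build_representation(synthetic_specs(params),
                                policy = policy,
                                n_symmetry = params$n_symmetry)
  # fix the scaffold body
  sc_beads <- which(state$bead$subunit == "NRscaffold")
  for (b in seq_along(state$bodies))
    if (all(state$bodies[[b]] %in% sc_beads)) state$body_fixed[b] <- TRUE

  tilt <- params$strut_tilt * pi / 180
  R <- params$scaffold_ring_radius
  L <- params$distal_offset / cos(tilt)
  d <- c(-sin(tilt), 0, -cos(tilt))           # strut direction, inward + down
  attach <- c(R, 0, 0)
  n_s <- params$beads_per_strut
  state <- with_seed(params$seed, {
    s <- state
    strut_names <- c("Mlp1s", "Mlp2s")
    for (i in seq_along(strut_names)) {
      side <- if (i == 1) 1 else -1
      ychain <- side * params$strut_thickness / 4
      sel <- which(s$bead$subunit == strut_names[i])
      tvals <- seq(16, L - 24, length.out = n_s)
      strut_pos <- t(vapply(tvals, function(t) attach + t * d, numeric(3)))
      strut_pos[, 2] <- strut_pos[, 2] + ychain
      blob_t <- c(L - 12, L, L + 12)
      blob_jog <- c(6, 0, -6)
      blob_pos <- t(vapply(seq_len(SYN_BLOB_BEADS), function(k)
        attach + blob_t[k] * d + c(0, ychain + blob_jog[k], 0), numeric(3)))
      s$coords[sel, ] <- rbind(strut_pos, blob_pos)
    }
    # flexible anchors: compact seeded walks starting just inside the scaffold
    anchors <- setdiff(unique(s$bead$subunit),
                       c("NRscaffold", strut_names))
    start_angles <- list(Nup1s = 8, Nup60s = c(-15, 15), Nup2s = c(-5, 5))
    for (nm in anchors) {
      copies <- unique(s$bead$copy[s$bead$subunit == nm])
      for (cp in copies) {
        sel <- which(s$bead$subunit == nm & s$bead$copy == cp)
        a0 <- if (nm %in% names(start_angles))
          start_angles[[nm]][min(cp, length(start_angles[[nm]]))] * pi / 180
        else runif(1, -0.3, 0.3)
        p <- c((R - 25) * cos(a0), (R - 25) * sin(a0), -10)
        dir0 <- c(-cos(a0), -sin(a0), -1.2)
        dir0 <- dir0 / sqrt(sum(dir0^2))
        pos <- matrix(0, length(sel), 3)
        for (k in seq_along(sel)) {
          pos[k, ] <- p
          step <- dir0 * 13 + rnorm(3, 0, 1.5)
          p <- p + step / sqrt(sum(step^2)) * 13
        }
        s$coords[sel, ] <- pos
      }
    }
    s
  })
  attr(state, "synthetic") <- list(params = params,
                                   strut_subunits = c("Mlp1s", "Mlp2s"),
                                   blob_beads = SYN_BLOB_BEADS)
  state
}

#' Measure the realized geometry of a basket-like state
#'
#' Fits the strut axis of each strut chain (principal axis of its
#' non-blob coarse beads) and reports the mean tilt from the central
#' axis, the axial offset of the distal-blob centroid below the scaffold
#' plane (the z of the lowest scaffold tier), and the distal ring
#' diameter (twice the mean radial distance of per-chain blob centroids).
#'
#' @param state An `assembly_state`, typically from [make_ground_truth()].
#' @param strut_subunits Subunit names of the strut chains; defaults to
#'   the generator's annotation, else names matching `Mlp`/`Tpr`.
#' @param blob_beads Number of trailing blob beads per strut chain.
#' @return List with `strut_tilt` (degrees), `distal_offset` (Angstrom)
#'   and `distal_ring_diameter` (Angstrom).
#' @export
measure_geometry <- function(state, strut_subunits = NULL, blob_beads = NULL) {
  syn <- attr(state, "synthetic")
  if (is.null(strut_subunits))
    strut_subunits <- if (!is.null(syn)) syn$strut_subunits else
      unique(grep("^(Mlp|Tpr)", state$bead$subunit, value = TRUE))
  if (is.null(blob_beads))
    blob_beads <- if (!is.null(syn)) syn$blob_beads else 3L
  sc <- state$coords[state$bead$subunit == "NRscaffold" &
                       state$bead$resolution ==
                         max(state$bead$resolution), , drop = FALSE]
  zs <- sc[, 3]
  z_ref <- min(tapply(zs, round(zs / 20), mean))  # lowest scaffold tier
  tilts <- c(); blob_cent <- list()
  for (nm in strut_subunits) {
    for (cp in unique(state$bead$copy[state$bead$subunit == nm])) {
      sel <- which(state$bead$subunit == nm & state$bead$copy == cp)
      xyz <- state$coords[sel, , drop = FALSE]
      n <- nrow(xyz)
      strut <- xyz[seq_len(n - blob_beads), , drop = FALSE]
      ax <- svd(scale(strut, scale = FALSE))$v[, 1]
      tilts <- c(tilts, acos(abs(ax[3])) * 180 / pi)
      blob_cent[[length(blob_cent) + 1L]] <-
        colMeans(xyz[(n - blob_beads + 1L):n, , drop = FALSE])
    }
  }
  bc <- do.call(rbind, blob_cent)
  list(strut_tilt = mean(tilts),
       distal_offset = z_ref - mean(bc[, 3]),
       distal_ring_diameter = 2 * mean(sqrt(bc[, 1]^2 + bc[, 2]^2)))
}

## beads used for crosslink scoring: the finest-resolution chain of each
## (subunit, copy)
crosslink_level_chains <- function(state) {
  b <- state$bead
  info <- unique(b[, c("chain", "subunit", "copy", "resolution")])
  keep <- unlist(lapply(split(info, paste(info$subunit, info$copy)),
                        function(d) d$chain[which.min(d$resolution)]))
  sort(unname(keep))
}

## beads used for density/excluded-volume: the coarsest chain per copy
coarse_level_chains <- function(state) {
  b <- state$bead
  info <- unique(b[, c("chain", "subunit", "copy", "resolution")])
  keep <- unlist(lapply(split(info, paste(info$subunit, info$copy)),
                        function(d) d$chain[which.max(d$resolution)]))
  sort(unname(keep))
}

#' Beads at the crosslink-scoring (finest) resolution
#' @param state An `assembly_state`.
#' @return Integer bead indices.
#' @export
crosslink_beads <- function(state)
  which(state$bead$chain %in% crosslink_level_chains(state))

#' Beads at the coarse (excluded-volume / density) resolution
#' @param state An `assembly_state`.
#' @return Integer bead indices.
#' @export
coarse_beads <- function(state)
  which(state$bead$chain %in% coarse_level_chains(state))

#' Simulate a DSS-style crosslink table from a ground-truth state
#'
#' Samples `n_true` residue pairs uniformly from pairs whose bead-center
#' distance (at the crosslink-scoring resolution, minimized over
#' equivalent-copy assignments) is within `cutoff`, then appends
#' `floor(n_true * fp_rate / (1 - fp_rate))` false-positive records drawn
#' from pairs whose minimum-over-copies distance exceeds the cutoff, so
#' violation counts are exact. Pairs inside the fixed scaffold and pairs
#' of consecutive beads of one chain are not sampled (they carry no
#' modeling information). Deterministic in `seed`.
#'
#' @param truth Ground-truth `assembly_state`.
#' @param cutoff Distance cutoff in Angstrom (default 35, the usual
#'   C-alpha - C-alpha convention for DSS).
#' @param n_true Number of within-cutoff records.
#' @param fp_rate Fraction of the final table that violates the cutoff.
#' @param seed Integer seed.
#' @return Data frame of class `crosslink_records` with columns
#'   `protein1,residue1,protein2,residue2,linker,multiplicity` and a
#'   logical attribute `truth_violates` marking the false positives.
#' @export
simulate_crosslinks <- function(truth, cutoff = 35, n_true = 150,
                                fp_rate = 0, seed = 1L) {
  stopifnot(cutoff > 0, fp_rate >= 0, fp_rate < 1, n_true >= 1)
  idx <- crosslink_beads(truth)
  b <- truth$bead[idx, ]
  xyz <- truth$coords[idx, , drop = FALSE]
  fixed <- idx %in% fixed_beads(truth)
  n <- length(idx)
  # candidate bead pairs: not both fixed, not same bead, not consecutive
  # beads of one chain
  cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- cand[, 1]; j <- cand[, 2]
  same_chain <- b$chain[i] == b$chain[j]
  consec <- same_chain & abs(match(idx[i], idx) - match(idx[j], idx)) <= 1
  ok <- !(fixed[i] & fixed[j]) & !consec & !(same_chain & i == j)
  i <- i[ok]; j <- j[ok]
  # min-over-equivalent-copies distance for each candidate bead pair
  dmin <- .xl_pair_min_dist(truth, idx, i, j)
  within <- which(dmin <= cutoff)
  beyond <- which(dmin > cutoff)
  if (!length(within))
    stop("simulate_crosslinks: no residue pairs within cutoff ", cutoff, " A")
  n_fp <- floor(n_true * fp_rate / (1 - fp_rate))
  if (n_fp > 0 && !length(beyond))
    stop("simulate_crosslinks: no residue pairs beyond cutoff ", cutoff, " A")
  with_seed(seed, {
    pick_t <- sample(within, n_true, replace = n_true > length(within))
    pick_f <- if (n_fp > 0)
      sample(beyond, n_fp, replace = n_fp > length(beyond)) else integer(0)
    pick <- c(pick_t, pick_f)
    r1 <- mapply(function(a, z) a + sample.int(z - a + 1L, 1L) - 1L,
                 b$res_first[i[pick]], b$res_last[i[pick]])
    r2 <- mapply(function(a, z) a + sample.int(z - a + 1L, 1L) - 1L,
                 b$res_first[j[pick]], b$res_last[j[pick]])
    out <- data.frame(protein1 = b$subunit[i[pick]], residue1 = as.integer(r1),
                      protein2 = b$subunit[j[pick]], residue2 = as.integer(r2),
                      linker = "DSS", multiplicity = 1L)
    attr(out, "truth_violates") <- c(rep(FALSE, n_true), rep(TRUE, n_fp))
    class(out) <- c("crosslink_records", "data.frame")
    out
  })
}

## min-over-copies distance between bead pairs given at the crosslink level:
## for bead pair (i, j) (indices into idx), the distance is minimized over
## all copy combinations of the two subunits at the equivalent residue window
.xl_pair_min_dist <- function(state, idx, i, j) {
  b <- state$bead[idx, ]
  xyz <- state$coords[idx, , drop = FALSE]
  key <- paste(b$subunit, b$res_first, b$res_last)
  copies_of <- split(seq_along(idx), key)
  vapply(seq_along(i), function(k) {
    ii <- copies_of[[key[i[k]]]]
    jj <- copies_of[[key[j[k]]]]
    best <- Inf
    for (a in ii) for (z in jj) {
      if (a == z) next
      dd <- sqrt(sum((xyz[a, ] - xyz[z, ])^2))
      if (dd < best) best <- dd
    }
    best
  }, numeric(1))
}

#' Simulate a noisy Gaussian-mixture density of a ground-truth state
#'
#' One spherical Gaussian per coarse-level bead: width
#' `sigma_scale * bead radius`, weight proportional to the bead's residue
#' count, mean displaced by isotropic Gaussian jitter of the stated
#' magnitude. Deterministic in `seed`.
#'
#' @param truth Ground-truth `assembly_state`.
#' @param sigma_scale Width multiplier (> 0).
#' @param jitter Standard deviation of the mean displacement, Angstrom.
#' @param seed Integer seed.
#' @return A [gaussian_mixture()].
#' @export
simulate_density <- function(truth, sigma_scale = 1, jitter = 0, seed = 1L) {
  stopifnot(sigma_scale > 0, jitter >= 0)
  if (n_beads(truth) == 0L) stop("simulate_density: empty truth state")
  g <- model_to_gmm(truth, sigma_scale = sigma_scale)
  with_seed(seed, {
    if (jitter > 0)
      g$mean <- g$mean + matrix(rnorm(length(g$mean), 0, jitter), ncol = 3)
    g
  })
}

#' Simulate terminal-domain localizations of the strut chains
#'
#' For each strut chain, emits point positional restraints at the true N-
#' and C-terminal bead positions with uncertainty `sigma` (used as the
#' restraint tolerance), emulating immuno-EM localization of terminal
#' domains.
#'
#' @param truth Ground-truth `assembly_state`.
#' @param sigma Localization uncertainty in Angstrom (> 0).
#' @param subunits Strut subunit names; default taken from the generator's
#'   annotation.
#' @return List of [positional_spec()] objects (two per strut chain).
#' @export
simulate_terminal_localizations <- function(truth, sigma = 25,
                                            subunits = NULL) {
  stopifnot(sigma > 0)
  syn <- attr(truth, "synthetic")
  if (is.null(subunits))
    subunits <- if (!is.null(syn)) syn$strut_subunits else
      unique(grep("^(Mlp|Tpr)", truth$bead$subunit, value = TRUE))
  if (!length(subunits) || !any(truth$bead$subunit %in% subunits))
    stop("simulate_terminal_localizations: no strut chains with termini found")
  specs <- list()
  lvl <- crosslink_level_chains(truth)
  for (nm in subunits) {
    for (cp in unique(truth$bead$copy[truth$bead$subunit == nm])) {
      sel <- which(truth$bead$subunit == nm & truth$bead$copy == cp &
                     truth$bead$chain %in% lvl)
      if (!length(sel))
        stop("simulate_terminal_localizations: chain ", nm, " lacks beads")
      nb <- c(sel[1], sel[length(sel)])
      lab <- c("N", "C")
      for (t in 1:2) {
        bd <- truth$bead[nb[t], ]
        specs[[length(specs) + 1L]] <- positional_spec(
          target = truth$coords[nb[t], ], subunit = nm,
          res_first = bd$res_first, res_last = bd$res_last,
          tolerance = sigma, kind = "terminal-localization",
          label = paste0(nm, ".", cp, ".", lab[t]))
      }
    }
  }
  specs
}

#' Generate the complete synthetic input bundle
#'
#' The ground-truth state plus every simulated restraint input:
#' crosslinks, Gaussian-mixture density and terminal-domain
#' localizations. Regenerating with the same parameters and seed
#' reproduces the bundle exactly.
#'
#' @param params A [ground_truth_params()].
#' @param xl_cutoff,n_true,fp_rate Crosslink simulation settings.
#' @param sigma_scale,jitter Density simulation settings.
#' @param term_sigma Terminal-localization uncertainty, Angstrom.
#' @return List of class `ground_truth_bundle` with elements
#'   `truth_state`, `crosslinks`, `density`, `terminal_localizations`,
#'   `params`, `seed`.
#' @export
make_ground_truth_bundle <- function(params = basket_preset("yeast"),
                                     xl_cutoff = 35, n_true = 150,
                                     fp_rate = 0.05, sigma_scale = 1,
                                     jitter = 2, term_sigma = 25) {
  truth <- make_ground_truth(params)
  bundle <- list(
    truth_state = truth,
    crosslinks = simulate_crosslinks(truth, cutoff = xl_cutoff,
                                     n_true = n_true, fp_rate = fp_rate,
                                     seed = params$seed + 1L),
    density = simulate_density(truth, sigma_scale = sigma_scale,
                               jitter = jitter, seed = params$seed + 2L),
    terminal_localizations = simulate_terminal_localizations(truth,
                                                             sigma = term_sigma),
    params = params, seed = params$seed,
    xl_cutoff = xl_cutoff,
    settings = list(xl_cutoff = xl_cutoff, n_true = n_true,
                    fp_rate = fp_rate, sigma_scale = sigma_scale,
                    jitter = jitter, term_sigma = term_sigma))
  class(bundle) <- "ground_truth_bundle"
  bundle
}

#' @export
print.ground_truth_bundle <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth_bundle> %d beads, %d crosslinks, ",
                     "%d density components, %d positional specs (seed %d)\n"),
              n_beads(x$truth_state), nrow(x$crosslinks),
              nrow(x$density$mean), length(x$terminal_localizations),
              x$seed))
  invisible(x)
}
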