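## Scoring terms: crosslink upper bounds, GMM density cross-correlation,
## positional (point / z-slab), domain proximity, chain connectivity,
## excluded volume, inter-species structural equivalence, and their
## weighted sum. All bounds are one-sided harmonics with stiffness k
## (kT per square Angstrom); energies are in kT.

#' Gaussian mixture
#'
#' Weighted spherical Gaussians standing in for a density map or a model.
#'
#' @param weight Nonnegative component weights.
#' @param mean n x 3 matrix of component means (Angstrom).
#' @param sigma Positive component widths (Angstrom).
#' @return Object of class `gaussian_mixture`.
#' @export
gaussian_mixture <- function(weight, mean, sigma) {
  mean <- matrix(as.numeric(mean), ncol = 3)
  weight <- as.numeric(weight); sigma <- as.numeric(sigma)
  if (length(weight) < 1L) stop("gaussian_mixture: at least one component")
  if (any(weight < 0)) stop("gaussian_mixture: weights must be >= 0")
  if (any(sigma <= 0)) stop("gaussian_mixture: sigmas must be > 0")
  stopifnot(nrow(mean) == length(weight), length(sigma) == length(weight))
  structure(list(weight = weight, mean = mean, sigma = sigma),
            class = "gaussian_mixture")
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("<gaussian_mixture> %d components, sigma %.1f-%.1f A\n",
              length(x$weight), min(x$sigma), max(x$sigma)))
  invisible(x)
}

#' Positional restraint specification
#'
#' Either a point target with a tolerance (terminal-domain localization)
#' or a z-slab (membrane anchoring), applied to a residue range of a
#' subunit (optionally a specific copy; otherwise the restraint takes the
#' best-satisfying copy).
#'
#' @param target Point c(x, y, z) in Angstrom, or `NULL` for a slab.
#' @param slab c(z_min, z_max) in Angstrom, or `NULL` for a point.
#' @param subunit,res_first,res_last Domain the restraint applies to.
#' @param copy Optional copy index.
#' @param tolerance Flat-bottom radius for point targets, Angstrom.
#' @param kind `"terminal-localization"` or `"membrane-slab"`.
#' @param label Free-text identifier used in reports.
#' @export
positional_spec <- function(target = NULL, slab = NULL, subunit, res_first,
                            res_last, copy = NULL, tolerance = 0,
                            kind = c("terminal-localization", "membrane-slab"),
                            label = subunit) {
  kind <- match.arg(kind)
  if (is.null(target) == is.null(slab))
    stop("positional_spec: give exactly one of target / slab")
  if (tolerance < 0) stop("positional_spec: tolerance must be >= 0")
  if (!is.null(slab) && slab[1] >= slab[2])
    stop("positional_spec: slab needs z_min < z_max")
  structure(list(target = target, slab = slab, subunit = subunit,
                 res_first = as.integer(res_first),
                 res_last = as.integer(res_last),
                 copy = if (is.null(copy)) NULL else as.integer(copy),
                 tolerance = tolerance, kind = kind, label = label),
            class = "positional_spec")
}

#' Per-term restraint weights
#'
#' Multipliers applied to the raw term scores in [total_score()]. The EM
#' term is `em * (1 - CC)`, so its default is much larger than the
#' harmonic terms: the default was calibrated on the synthetic basket so
#' that the density term resolves the chain-register degeneracy the
#' distance restraints leave open (a ~1% drop in CC then outweighs a few
#' violated crosslinks).
#'
#' @param crosslink,em,positional,proximity,connectivity,excluded_volume,equivalence
#'   Nonnegative multipliers.
#' @export
restraint_weights <- function(crosslink = 1, em = 2000, positional = 1,
                              proximity = 1, connectivity = 1,
                              excluded_volume = 1, equivalence = 1) {
  w <- c(crosslink = crosslink, em = em, positional = positional,
         proximity = proximity, connectivity = connectivity,
         excluded_volume = excluded_volume, equivalence = equivalence)
  if (any(w < 0)) stop("restraint_weights: weights must be >= 0")
  structure(as.list(w), class = "restraint_weights")
}

harm_upper <- function(d, bound, k) ifelse(d > bound, 0.5 * k * (d - bound)^2, 0)
harm_lower <- function(d, bound, k) ifelse(d < bound, 0.5 * k * (bound - d)^2, 0)

## ---- crosslinks ----------------------------------------------------------

## map records to candidate bead pairs (crosslink-level beads, all copy
## combinations); returns a list of m x 2 integer matrices
map_crosslinks <- function(state, links) {
  idx <- crosslink_beads(state)
  b <- state$bead[idx, ]
  lapply(seq_len(nrow(links)), function(r) {
    rec <- links[r, ]
    f1 <- idx[b$subunit == rec$protein1 & b$res_first <= rec$residue1 &
                b$res_last >= rec$residue1]
    f2 <- idx[b$subunit == rec$protein2 & b$res_first <= rec$residue2 &
                b$res_last >= rec$residue2]
    if (!length(f1) || !length(f2))
      stop("crosslink record ", r, " (", rec$protein1, " ", rec$residue1,
           " - ", rec$protein2, " ", rec$residue2,
           ") does not map to any bead pair")
    pairs <- as.matrix(expand.grid(f1, f2))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (!nrow(pairs))
      stop("crosslink record ", r, " is a self-link with no alternative copy")
    dimnames(pairs) <- NULL
    pairs
  })
}

#' Score crosslink upper-bound restraints
#'
#' Each record's effective distance is the minimum bead-center distance
#' over all copy assignments of the two proteins; the penalty is a
#' one-sided harmonic above the cutoff:
#' `0.5 * k * (d - cutoff)^2` for `d > cutoff`, else 0.
#'
#' @param state An `assembly_state`.
#' @param links `crosslink_records` data frame.
#' @param cutoff Upper bound, Angstrom (default 35 for DSS).
#' @param k Stiffness, kT per square Angstrom.
#' @return List with `score`, per-link `distances` and `penalties`.
#' @export
score_crosslinks <- function(state, links, cutoff = 35, k = 1) {
  if (!nrow(links)) return(list(score = 0, distances = numeric(0),
                                penalties = numeric(0)))
  maps <- map_crosslinks(state, links)
  d <- vapply(maps, function(p) {
    dd <- sqrt(rowSums((state$coords[p[, 1], , drop = FALSE] -
                          state$coords[p[, 2], , drop = FALSE])^2))
    min(dd)
  }, numeric(1))
  pen <- harm_upper(d, cutoff, k) * links$multiplicity
  list(score = sum(pen), distances = d, penalties = pen)
}

## ---- EM (GMM cross-correlation) -----------------------------------------

gmm_overlap <- function(a, b) {
  s2 <- outer(a$sigma^2, b$sigma^2, `+`)
  d2 <- outer(rowSums(a$mean^2), rowSums(b$mean^2), `+`) -
    2 * a$mean %*% t(b$mean)
  d2[d2 < 0] <- 0
  sum(outer(a$weight, b$weight) * (2 * pi * s2)^(-1.5) * exp(-d2 / (2 * s2)))
}

#' Cross-correlation between two Gaussian mixtures
#'
#' `CC = <f,g> / sqrt(<f,f><g,g>)` with the analytic Gaussian overlap
#' integral as inner product; in `[0, 1]` for nonnegative weights,
#' symmetric, invariant to scaling either mixture's weights.
#'
#' @param a,b [gaussian_mixture()] objects.
#' @export
gmm_cc <- function(a, b) {
  ff <- gmm_overlap(a, a); gg <- gmm_overlap(b, b)
  if (ff <= 0 || gg <= 0) stop("gmm_cc: zero-norm mixture")
  gmm_overlap(a, b) / sqrt(ff * gg)
}

#' Score the model-to-density fit
#'
#' @param model_gmm,map_gmm [gaussian_mixture()] objects.
#' @param weight Multiplier for the penalty `weight * (1 - CC)`.
#' @return List with `cc` and `score`.
#' @export
score_em <- function(model_gmm, map_gmm, weight = 1) {
  cc <- gmm_cc(model_gmm, map_gmm)
  list(cc = cc, score = weight * (1 - cc))
}

#' Gaussian-mixture representation of a bead model
#'
#' One spherical Gaussian per coarse-level bead: width
#' `sigma_scale * radius`, weight proportional to the bead's residue
#' count.
#'
#' @param state An `assembly_state`.
#' @param sigma_scale Width multiplier (> 0).
#' @return A [gaussian_mixture()] with attribute `sigma_scale`.
#' @export
model_to_gmm <- function(state, sigma_scale = 1) {
  stopifnot(sigma_scale > 0)
  if (n_beads(state) == 0L) stop("model_to_gmm: empty state")
  sel <- coarse_beads(state)
  g <- gaussian_mixture(state$bead$nres[sel],
                        state$coords[sel, , drop = FALSE],
                        sigma_scale * state$radius[sel])
  attr(g, "sigma_scale") <- sigma_scale
  g
}

## ---- positional ----------------------------------------------------------

## beads a positional spec applies to, per candidate copy
map_positional <- function(state, spec) {
  idx <- crosslink_beads(state)
  b <- state$bead[idx, ]
  sel <- b$subunit == spec$subunit & b$res_first <= spec$res_last &
    b$res_last >= spec$res_first
  if (!is.null(spec$copy)) sel <- sel & b$copy == spec$copy
  if (!any(sel))
    stop("positional spec '", spec$label, "' maps to no beads")
  split(idx[sel], b$copy[sel])
}

#' Score positional restraints
#'
#' Point kind: one-sided harmonic on `(distance - tolerance)` between the
#' mapped domain centroid and the target when the distance exceeds the
#' tolerance. Slab kind: harmonic on the centroid's z-excursion outside
#' `[z_min, z_max]`. When no copy is pinned the best-satisfying copy
#' counts.
#'
#' @param state An `assembly_state`.
#' @param specs List of [positional_spec()] objects.
#' @param k Stiffness, kT per square Angstrom.
#' @return List with `score` and per-spec `penalties`.
#' @export
score_positional <- function(state, specs, k = 1) {
  if (inherits(specs, "positional_spec")) specs <- list(specs)
  pen <- vapply(specs, function(sp) {
    by_copy <- map_positional(state, sp)
    vals <- vapply(by_copy, function(bi) {
      cen <- colMeans(state$coords[bi, , drop = FALSE])
      if (!is.null(sp$target)) {
        d <- sqrt(sum((cen - sp$target)^2))
        harm_upper(d, sp$tolerance, k)
      } else {
        dz <- max(sp$slab[1] - cen[3], cen[3] - sp$slab[2], 0)
        0.5 * k * dz^2
      }
    }, numeric(1))
    min(vals)
  }, numeric(1))
  list(score = sum(pen), penalties = pen)
}

## ---- proximity -----------------------------------------------------------

#' Score domain-proximity restraints
#'
#' Per pair of domains, a one-sided harmonic upper bound on the minimum
#' inter-set bead distance, emulating affinity co-purification contacts.
#'
#' @param state An `assembly_state`.
#' @param pairs Data frame with columns `subunit1,first1,last1,
#'   subunit2,first2,last2,max_distance`.
#' @param k Stiffness.
#' @return List with `score`, per-pair `distances` and `penalties`.
#' @export
score_proximity <- function(state, pairs, k = 1) {
  if (is.null(pairs) || !nrow(pairs))
    return(list(score = 0, distances = numeric(0), penalties = numeric(0)))
  idx <- crosslink_beads(state)
  b <- state$bead[idx, ]
  dom <- function(su, f, l) {
    s <- idx[b$subunit == su & b$res_first <= l & b$res_last >= f]
    if (!length(s)) stop("proximity restraint: empty domain ", su,
                         " [", f, "-", l, "]")
    s
  }
  d <- vapply(seq_len(nrow(pairs)), function(r) {
    A <- dom(pairs$subunit1[r], pairs$first1[r], pairs$last1[r])
    B <- dom(pairs$subunit2[r], pairs$first2[r], pairs$last2[r])
    min(vapply(A, function(a)
      min(sqrt(rowSums((state$coords[B, , drop = FALSE] -
                          matrix(state$coords[a, ], length(B), 3,
                                 byrow = TRUE))^2))), numeric(1)))
  }, numeric(1))
  pen <- harm_upper(d, pairs$max_distance, k)
  list(score = sum(pen), distances = d, penalties = pen)
}

## ---- connectivity --------------------------------------------------------

## consecutive bead pairs within each chain with their thresholds; pairs
## held inside one rigid body are omitted (the body preserves them)
connectivity_pairs <- function(state, c_factor = 1.2) {
  out <- list()
  for (ch in unique(state$bead$chain)) {
    sel <- which(state$bead$chain == ch)
    if (length(sel) < 2L) next
    i <- sel[-length(sel)]; j <- sel[-1]
    same_body <- !is.na(state$bead_body[i]) & !is.na(state$bead_body[j]) &
      state$bead_body[i] == state$bead_body[j]
    i <- i[!same_body]; j <- j[!same_body]
    if (!length(i)) next
    out[[length(out) + 1L]] <-
      cbind(i, j, c_factor * (state$radius[i] + state$radius[j]))
  }
  if (!length(out)) return(matrix(0, 0, 3))
  do.call(rbind, out)
}

#' Score chain connectivity
#'
#' One-sided harmonic upper bound on the distance of each consecutive
#' bead pair within a chain, at threshold `c_factor * (r_i + r_j)`;
#' pairs from different chains are never restrained.
#'
#' @param state An `assembly_state`.
#' @param c_factor Threshold multiplier on the sum of radii.
#' @param k Stiffness.
#' @return List with `score` and per-bond `penalties`.
#' @export
score_connectivity <- function(state, c_factor = 1.2, k = 1) {
  cp <- connectivity_pairs(state, c_factor)
  if (!nrow(cp)) return(list(score = 0, penalties = numeric(0)))
  d <- sqrt(rowSums((state$coords[cp[, 1], , drop = FALSE] -
                       state$coords[cp[, 2], , drop = FALSE])^2))
  pen <- harm_upper(d, cp[, 3], k)
  list(score = sum(pen), penalties = pen)
}

## ---- excluded volume -----------------------------------------------------

## non-bonded coarse-bead pairs: excludes consecutive beads of a chain and
## pairs within one rigid body
ev_pairs <- function(state) {
  sel <- coarse_beads(state)
  n <- length(sel)
  if (n < 2L) return(matrix(0, 0, 3))
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- sel[pr[, 1]]; j <- sel[pr[, 2]]
  b <- state$bead
  consec <- b$chain[i] == b$chain[j] & abs(i - j) <= 1L
  same_body <- !is.na(state$bead_body[i]) &
    !is.na(state$bead_body[j]) & state$bead_body[i] == state$bead_body[j]
  keep <- !consec & !same_body
  cbind(i[keep], j[keep], state$radius[i[keep]] + state$radius[j[keep]])
}

#' Score excluded volume
#'
#' Soft-sphere lower-bound harmonic over non-bonded coarse-bead pairs:
#' `0.5 * k * (r_i + r_j - d)^2` when beads interpenetrate. Consecutive
#' beads of a chain and pairs within one rigid body are excluded.
#' Optionally the state is also checked against its two neighboring
#' symmetry images.
#'
#' @param state An `assembly_state`.
#' @param k Stiffness.
#' @param include_symmetry_images Also penalize clashes with the +1
#'   rotational neighbor image (each neighbor pair counted once).
#' @return List with `score` and the number of overlapping pairs.
#' @export
score_excluded_volume <- function(state, k = 1,
                                  include_symmetry_images = FALSE) {
  ep <- ev_pairs(state)
  tot <- 0; nover <- 0L
  if (nrow(ep)) {
    d <- sqrt(rowSums((state$coords[ep[, 1], , drop = FALSE] -
                         state$coords[ep[, 2], , drop = FALSE])^2))
    pen <- harm_lower(d, ep[, 3], k)
    tot <- sum(pen); nover <- sum(pen > 0)
  }
  if (include_symmetry_images && state$n_symmetry > 1L) {
    sel <- coarse_beads(state)
    img <- state$coords[sel, , drop = FALSE] %*%
      t(rot_z(2 * pi / state$n_symmetry))
    dmat <- sqrt(outer(rowSums(state$coords[sel, , drop = FALSE]^2),
                       rowSums(img^2), `+`) -
                   2 * state$coords[sel, , drop = FALSE] %*% t(img))
    bound <- outer(state$radius[sel], state$radius[sel], `+`)
    pen <- harm_lower(dmat, bound, k)
    tot <- tot + sum(pen); nover <- nover + sum(pen > 0)
  }
  list(score = tot, n_overlaps = nover)
}

## ---- structural equivalence ---------------------------------------------

## map alignment rows to beads in a state
map_alignment <- function(state, subunit, residue, copy) {
  idx <- crosslink_beads(state)
  b <- state$bead[idx, ]
  vapply(seq_along(subunit), function(r) {
    s <- idx[b$subunit == subunit[r] & b$res_first <= residue[r] &
               b$res_last >= residue[r] & b$copy == copy[r]]
    if (!length(s)) stop("equivalence alignment row ", r, " (", subunit[r],
                         " ", residue[r], ") maps to no bead")
    s[1]
  }, integer(1))
}

#' Score inter-species structural equivalence
#'
#' Superposition-free distance matching: for every pair of aligned
#' residues, a harmonic on the difference between the intra-model
#' distance in `state` and the corresponding distance in `reference`.
#' Invariant under global rotation/translation of either model.
#'
#' @param state,reference `assembly_state` objects.
#' @param alignment Data frame with columns `subunit,residue,copy,
#'   ref_subunit,ref_residue,ref_copy` (copies default to 1).
#' @param k Stiffness.
#' @return List with `score` and the number of aligned pairs used.
#' @export
score_equivalence <- function(state, reference, alignment, k = 1) {
  if (is.null(alignment) || !nrow(alignment)) {
    warning("score_equivalence: empty alignment, score 0")
    return(list(score = 0, n_pairs = 0L))
  }
  if (is.null(alignment$copy)) alignment$copy <- 1L
  if (is.null(alignment$ref_copy)) alignment$ref_copy <- 1L
  bi <- map_alignment(state, alignment$subunit, alignment$residue,
                      alignment$copy)
  bj <- map_alignment(reference, alignment$ref_subunit,
                      alignment$ref_residue, alignment$ref_copy)
  xs <- state$coords[bi, , drop = FALSE]
  xr <- reference$coords[bj, , drop = FALSE]
  ds <- as.matrix(dist(xs)); dr <- as.matrix(dist(xr))
  up <- upper.tri(ds)
  list(score = sum(0.5 * k * (ds[up] - dr[up])^2),
       n_pairs = sum(up))
}

## ---- total ---------------------------------------------------------------

#' Total restraint score with per-term breakdown
#'
#' Weighted sum of all configured terms. The bundle supplies the data
#' (crosslinks, density, positional specs, optional proximity pairs and
#' equivalence reference); representation priors (connectivity, excluded
#' volume) come from the state itself.
#'
#' @param state An `assembly_state`.
#' @param bundle A `ground_truth_bundle` or a list with any of
#'   `crosslinks`, `density`, `terminal_localizations`, `proximity`,
#'   `equivalence` (list with `reference`, `alignment`), `xl_cutoff`.
#' @param weights A [restraint_weights()].
#' @param k Common harmonic stiffness.
#' @param c_factor Connectivity threshold multiplier.
#' @param include_symmetry_images Passed to [score_excluded_volume()].
#' @return List with `total`, named weighted `terms`, and `details`
#'   (raw per-term outputs).
#' @export
total_score <- function(state, bundle, weights = restraint_weights(), k = 1,
                        c_factor = 1.2, include_symmetry_images = FALSE) {
  cutoff <- if (!is.null(bundle$xl_cutoff)) bundle$xl_cutoff else 35
  details <- list()
  terms <- c(crosslink = 0, em = 0, positional = 0, proximity = 0,
             connectivity = 0, excluded_volume = 0, equivalence = 0)
  if (!is.null(bundle$crosslinks) && nrow(bundle$crosslinks)) {
    details$crosslink <- score_crosslinks(state, bundle$crosslinks,
                                          cutoff = cutoff, k = k)
    terms["crosslink"] <- weights$crosslink * details$crosslink$score
  }
  if (!is.null(bundle$density)) {
    ss <- attr(bundle$density, "sigma_scale")
    if (is.null(ss)) ss <- 1
    details$em <- score_em(model_to_gmm(state, sigma_scale = ss),
                           bundle$density, weight = 1)
    terms["em"] <- weights$em * details$em$score
  }
  if (length(bundle$terminal_localizations)) {
    details$positional <- score_positional(state,
                                           bundle$terminal_localizations,
                                           k = k)
    terms["positional"] <- weights$positional * details$positional$score
  }
  if (!is.null(bundle$proximity) && nrow(bundle$proximity)) {
    details$proximity <- score_proximity(state, bundle$proximity, k = k)
    terms["proximity"] <- weights$proximity * details$proximity$score
  }
  details$connectivity <- score_connectivity(state, c_factor = c_factor, k = k)
  terms["connectivity"] <- weights$connectivity * details$connectivity$score
  details$excluded_volume <-
    score_excluded_volume(state, k = k,
                          include_symmetry_images = include_symmetry_images)
  terms["excluded_volume"] <-
    weights$excluded_volume * details$excluded_volume$score
  if (!is.null(bundle$equivalence)) {
    details$equivalence <- score_equivalence(state,
                                             bundle$equivalence$reference,
                                             bundle$equivalence$alignment,
                                             k = k)
    terms["equivalence"] <- weights$equivalence * details$equivalence$score
  }
  list(total = sum(terms), terms = terms, details = details)
}
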