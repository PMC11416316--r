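## Stage-4 style ensemble validation: good-scoring selection, RMSD with
## copy-permutation minimization, threshold clustering, sampling
## exhaustiveness (score test + cluster-population test over a threshold
## grid), model precision, localization probability densities, and
## restraint-satisfaction reporting.

#' Select good-scoring models from an ensemble
#'
#' Frames passing every criterion: an overall score percentile and/or
#' per-term absolute thresholds.
#'
#' @param ensemble A `model_ensemble`.
#' @param percentile Keep frames with total score at or below this
#'   percentile (100 keeps everything).
#' @param term_max Named numeric vector of per-term maxima (names from
#'   the breakdown columns).
#' @return The filtered ensemble, with attribute `criteria`; if nothing
#'   passes, an empty ensemble flagged `no_good_scoring` (with a warning).
#' @export
select_good_scoring <- function(ensemble, percentile = 100,
                                term_max = NULL) {
  keep <- rep(TRUE, length(ensemble$frames))
  if (!is.null(percentile) && percentile < 100) {
    cut <- stats::quantile(ensemble$scores, percentile / 100)
    keep <- keep & ensemble$scores <= cut
  }
  if (!is.null(term_max)) {
    for (nm in names(term_max)) {
      if (!nm %in% colnames(ensemble$terms))
        stop("select_good_scoring: unknown term '", nm, "'")
      keep <- keep & ensemble$terms[, nm] <= term_max[[nm]]
    }
  }
  out <- ensemble
  out$frames <- ensemble$frames[keep]
  out$scores <- ensemble$scores[keep]
  out$terms <- ensemble$terms[keep, , drop = FALSE]
  out$provenance <- ensemble$provenance[keep, , drop = FALSE]
  attr(out, "criteria") <- list(percentile = percentile,
                                term_max = term_max)
  if (!length(out$frames)) {
    warning("select_good_scoring: no good-scoring models under the given ",
            "criteria")
    attr(out, "no_good_scoring") <- TRUE
  }
  out
}

## copy-equivalence groups: for every subunit with >1 copy, the ordered
## bead indices of each copy (identical layout across copies)
.copy_groups <- function(state) {
  b <- state$bead
  out <- list()
  for (su in unique(b$subunit)) {
    copies <- sort(unique(b$copy[b$subunit == su]))
    if (length(copies) < 2L) next
    out[[su]] <- lapply(copies, function(cp)
      which(b$subunit == su & b$copy == cp))
  }
  out
}

.perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in .perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

#' RMSD between two states in the fixed scaffold frame
#'
#' Root-mean-square deviation over bead centers with no superposition
#' (both models live in the frame defined by the fixed scaffold). With
#' `copy_permutation = TRUE` the deviation is minimized over permutations
#' of equivalent copies of each multi-copy subunit (each subunit
#' minimized independently; contributions are disjoint).
#'
#' @param stateA,stateB `assembly_state` objects (or coordinate matrices
#'   with `stateA` an `assembly_state` providing topology).
#' @param copy_permutation Allow equivalent-copy relabeling.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(stateA, stateB, copy_permutation = FALSE) {
  xa <- if (inherits(stateA, "assembly_state")) stateA$coords else
    as.matrix(stateA)
  xb <- if (inherits(stateB, "assembly_state")) stateB$coords else
    as.matrix(stateB)
  if (!all(dim(xa) == dim(xb)))
    stop("rmsd: states have different topologies")
  ssd <- function(i, j) sum((xa[i, , drop = FALSE] - xb[j, , drop = FALSE])^2)
  total <- sum((xa - xb)^2)
  if (copy_permutation && inherits(stateA, "assembly_state")) {
    for (grp in .copy_groups(stateA)) {
      c0 <- sum(vapply(seq_along(grp), function(t) ssd(grp[[t]], grp[[t]]),
                       numeric(1)))
      best <- c0
      for (p in .perms(length(grp))) {
        cp <- sum(vapply(seq_along(grp), function(t)
          ssd(grp[[t]], grp[[p[t]]]), numeric(1)))
        if (cp < best) best <- cp
      }
      total <- total - c0 + best
    }
  }
  sqrt(total / nrow(xa))
}

## flatten ensemble frames; pairwise no-superposition RMSD matrix
frames_flat <- function(frames) {
  do.call(rbind, lapply(frames, function(f) as.numeric(f)))
}

#' Pairwise RMSD matrix of a set of frames
#' @param frames List of coordinate matrices (shared topology).
#' @return Symmetric matrix of no-superposition RMSDs.
#' @export
rmsd_matrix <- function(frames) {
  fl <- frames_flat(frames)
  as.matrix(dist(fl)) / sqrt(nrow(frames[[1]]))
}

#' Greedy centroid clustering at an RMSD threshold
#'
#' The frame with the largest neighborhood seeds a cluster of all frames
#' within the threshold; the procedure repeats on the remainder. Clusters
#' partition the input.
#'
#' @param frames List of coordinate matrices, a `model_ensemble`, or a
#'   precomputed RMSD matrix (class `dist` or square matrix).
#' @param threshold RMSD threshold, Angstrom.
#' @return List of class `cluster_result`: `clusters` (member indices),
#'   `centroids` (medoid index per cluster), `threshold`.
#' @export
cluster_models <- function(frames, threshold) {
  D <- if (is.matrix(frames) && nrow(frames) == ncol(frames)) frames
  else if (inherits(frames, "model_ensemble")) rmsd_matrix(frames$frames)
  else rmsd_matrix(frames)
  n <- nrow(D)
  remaining <- seq_len(n)
  clusters <- list(); centroids <- integer(0)
  while (length(remaining)) {
    nb <- rowSums(D[remaining, remaining, drop = FALSE] <= threshold)
    seed <- remaining[which.max(nb)]
    memb <- remaining[D[seed, remaining] <= threshold]
    Din <- D[memb, memb, drop = FALSE]
    clusters[[length(clusters) + 1L]] <- memb
    centroids <- c(centroids, memb[which.min(rowSums(Din))])
    remaining <- setdiff(remaining, memb)
  }
  structure(list(clusters = clusters, centroids = centroids,
                 threshold = threshold), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s) at %.1f A; sizes: %s\n",
              length(x$clusters), x$threshold,
              paste(lengths(x$clusters), collapse = ", ")))
  invisible(x)
}

#' Sampling-precision estimate via the two-half exhaustiveness protocol
#'
#' Splits the selected models into two halves by independent run, then
#' applies: (a) a two-sample Kolmogorov-Smirnov test on the score
#' distributions of the halves; (b) for each threshold in the grid, a
#' chi-square test (with Cramer's V effect size) on cluster populations
#' of the two halves after clustering the pooled set; (c) the sampling
#' precision is the smallest threshold at which the populations are
#' statistically indistinguishable (p > 0.05 and V < 0.10).
#'
#' @param ensemble A `model_ensemble` (>= 2 independent runs), or a list
#'   with `frames`, `scores` and a `half` factor via `half`.
#' @param thresholds Ascending RMSD grid; default 10 steps spanning the
#'   observed pairwise RMSD range.
#' @param half Optional logical/integer vector assigning each frame to a
#'   half (overrides the run-based split).
#' @param p_min,v_max Population-test thresholds.
#' @return List: `precision`, `tests` data frame per threshold,
#'   `score_test` (KS statistic and p-value), `halves` sizes.
#' @export
sampling_precision <- function(ensemble, thresholds = NULL, half = NULL,
                               p_min = 0.05, v_max = 0.10) {
  frames <- ensemble$frames
  scores <- ensemble$scores
  if (is.null(half)) {
    runs <- ensemble$provenance$run
    if (length(unique(runs)) < 2L)
      stop("sampling_precision: need >= 2 independent runs to split ",
           "into halves")
    half <- runs <= stats::median(unique(runs))
  }
  half <- as.logical(half)
  D <- rmsd_matrix(frames)
  if (is.null(thresholds)) {
    rng <- range(D[upper.tri(D)])
    thresholds <- seq(max(rng[1], 1e-6), rng[2], length.out = 10)
  }
  ks <- suppressWarnings(ks.test(scores[half], scores[!half]))
  rows <- lapply(thresholds, function(th) {
    cl <- cluster_models(D, th)
    tab <- vapply(cl$clusters, function(m)
      c(sum(half[m]), sum(!half[m])), numeric(2))
    tab <- matrix(tab, nrow = 2)
    if (ncol(tab) < 2L) {
      p <- 1; v <- 0
    } else {
      ct <- suppressWarnings(chisq.test(tab))
      p <- ct$p.value
      v <- sqrt(unname(ct$statistic) /
                  (sum(tab) * (min(dim(tab)) - 1)))
      if (!is.finite(p)) { p <- 1; v <- 0 }
    }
    data.frame(threshold = th, n_clusters = length(cl$clusters),
               chisq_p = p, cramers_v = v,
               pass = p > p_min & v < v_max)
  })
  tests <- do.call(rbind, rows)
  prec <- if (any(tests$pass)) min(tests$threshold[tests$pass]) else NA_real_
  list(precision = prec, tests = tests,
       score_test = list(statistic = unname(ks$statistic),
                         p.value = ks$p.value),
       halves = c(sum(half), sum(!half)))
}

#' Model precision of a cluster
#'
#' Variability of the solutions in a cluster: the average RMSD over all
#' member pairs (primary), with the average RMSD to the medoid also
#' reported.
#'
#' @param frames List of member coordinate matrices, or a
#'   `model_ensemble` plus `members` indices.
#' @param members Optional member indices into `frames`.
#' @return List: `pairwise` (mean pairwise RMSD, Angstrom),
#'   `to_centroid`, `centroid` (medoid index), `n`.
#' @export
model_precision <- function(frames, members = NULL) {
  if (inherits(frames, "model_ensemble")) frames <- frames$frames
  if (!is.null(members)) frames <- frames[members]
  n <- length(frames)
  if (n == 0L) stop("model_precision: empty cluster")
  if (n == 1L) {
    message("model_precision: singleton cluster, precision 0")
    return(list(pairwise = 0, to_centroid = 0, centroid = 1L, n = 1L))
  }
  D <- rmsd_matrix(frames)
  cen <- which.min(rowSums(D))
  list(pairwise = mean(D[upper.tri(D)]),
       to_centroid = mean(D[cen, -cen]),
       centroid = cen, n = n)
}

## permute copy labels of one frame so equivalent copies best match a
## reference frame (bead rows are swapped within each multi-copy subunit)
align_copy_labels <- function(frame, state, reference) {
  for (grp in .copy_groups(state)) {
    best <- NULL; bestv <- Inf
    for (p in .perms(length(grp))) {
      v <- sum(vapply(seq_along(grp), function(t)
        sum((frame[grp[[p[t]]], , drop = FALSE] -
               reference[grp[[t]], , drop = FALSE])^2), numeric(1)))
      if (v < bestv) { bestv <- v; best <- p }
    }
    if (!identical(best, seq_along(grp))) {
      new <- frame
      for (t in seq_along(grp)) new[grp[[t]], ] <- frame[grp[[best[t]]], ]
      frame <- new
    }
  }
  frame
}

#' Centroid model of a cluster
#'
#' The coordinate-wise mean over the cluster members, after relabeling
#' equivalent copies of each member to best match the cluster medoid
#' (so freely exchanging copies do not average into each other). The
#' medoid frame index is also returned.
#'
#' @param frames List of member coordinate matrices or a
#'   `model_ensemble`.
#' @param state Topology template; taken from the ensemble when omitted.
#' @param members Optional member indices.
#' @return List with `state` (an `assembly_state` holding the mean
#'   coordinates), `medoid` (index into the members), and `n`.
#' @export
cluster_centroid <- function(frames, state = NULL, members = NULL) {
  if (inherits(frames, "model_ensemble")) {
    if (is.null(state)) state <- frames$state
    frames <- frames$frames
  }
  if (!is.null(members)) frames <- frames[members]
  D <- rmsd_matrix(frames)
  med <- if (length(frames) > 1L) which.min(rowSums(D)) else 1L
  ref <- frames[[med]]
  aligned <- lapply(frames, align_copy_labels, state = state,
                    reference = ref)
  mean_coords <- Reduce(`+`, aligned) / length(aligned)
  out <- state
  out$coords <- mean_coords
  list(state = out, medoid = med, n = length(frames))
}

#' Localization probability density of a model component
#'
#' For a set of models sharing one topology, the per-voxel probability of
#' observing the selected component there: the fraction of members whose
#' Gaussian-smoothed occupancy (one Gaussian per bead, width = bead
#' radius) reaches at least half its center value at the voxel.
#'
#' @param frames List of member coordinate matrices or a
#'   `model_ensemble`.
#' @param state Topology template (`assembly_state`); taken from the
#'   ensemble when omitted.
#' @param subunits Character vector selecting component subunits.
#' @param voxel Voxel edge, Angstrom.
#' @param pad Padding around the members' bounding box, Angstrom.
#' @return A `voxel_map`: list with 3D `data` in [0, 1], `voxel`,
#'   `origin`.
#' @export
localization_density <- function(frames, state = NULL, subunits, voxel = 10,
                                 pad = NULL) {
  if (inherits(frames, "model_ensemble")) {
    if (is.null(state)) state <- frames$state
    frames <- frames$frames
  }
  if (is.null(state)) stop("localization_density: need a topology state")
  sel <- intersect(coarse_beads(state),
                   which(state$bead$subunit %in% subunits))
  if (!length(sel)) stop("localization_density: selector matches no beads")
  sig <- state$radius[sel]
  if (is.null(pad)) pad <- 3 * max(sig)
  pts <- do.call(rbind, lapply(frames, function(f) f[sel, , drop = FALSE]))
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / voxel)))
  ax <- lapply(1:3, function(d) lo[d] + (seq_len(dims[d]) - 0.5) * voxel)
  acc <- array(0, dims)
  for (f in frames) {
    occ <- array(0, dims)
    for (t in seq_along(sel)) {
      ct <- f[sel[t], ]; s <- sig[t]
      ix <- which(abs(ax[[1]] - ct[1]) <= 3 * s)
      iy <- which(abs(ax[[2]] - ct[2]) <= 3 * s)
      iz <- which(abs(ax[[3]] - ct[3]) <= 3 * s)
      if (!length(ix) || !length(iy) || !length(iz)) next
      gx <- exp(-(ax[[1]][ix] - ct[1])^2 / (2 * s^2))
      gy <- exp(-(ax[[2]][iy] - ct[2])^2 / (2 * s^2))
      gz <- exp(-(ax[[3]][iz] - ct[3])^2 / (2 * s^2))
      blk <- outer(outer(gx, gy), gz)
      occ[ix, iy, iz] <- pmax(occ[ix, iy, iz], blk)
    }
    acc <- acc + (occ >= 0.5)
  }
  structure(list(data = acc / length(frames), voxel = voxel, origin = lo),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  cat(sprintf("<voxel_map> %s voxels of %.1f A, values [%.3f, %.3f]\n",
              paste(dim(x$data), collapse = "x"), x$voxel, min(x$data),
              max(x$data)))
  invisible(x)
}

#' Restraint-satisfaction report for a model ensemble
#'
#' Per crosslink: the best (minimum) effective distance over the members
#' and whether any member satisfies it at the cutoff (ensemble-level
#' satisfaction); plus the mean per-model satisfaction rate, the density
#' cross-correlation of the medoid model, and the medoid's positional
#' violations.
#'
#' @param frames List of member coordinate matrices or a
#'   `model_ensemble`.
#' @param state Topology template; taken from the ensemble when omitted.
#' @param bundle Data bundle with `crosslinks` (and optionally `density`,
#'   `terminal_localizations`).
#' @param cutoff Crosslink cutoff, Angstrom.
#' @return List of class `satisfaction_report`.
#' @export
satisfaction_report <- function(frames, state = NULL, bundle, cutoff = 35) {
  if (inherits(frames, "model_ensemble")) {
    if (is.null(state)) state <- frames$state
    frames <- frames$frames
  }
  links <- bundle$crosslinks
  maps <- map_crosslinks(state, links)
  dm <- vapply(frames, function(f) {
    vapply(maps, function(p) {
      min(sqrt(rowSums((f[p[, 1], , drop = FALSE] -
                          f[p[, 2], , drop = FALSE])^2)))
    }, numeric(1))
  }, numeric(length(maps)))
  dm <- matrix(dm, nrow = length(maps))
  best <- apply(dm, 1, min)
  sat_any <- best <= cutoff
  per_model <- colMeans(dm <= cutoff) * 100
  D <- rmsd_matrix(frames)
  cen <- if (length(frames) > 1L) which.min(rowSums(D)) else 1L
  cen_state <- state; cen_state$coords <- frames[[cen]]
  cc <- NA_real_
  if (!is.null(bundle$density)) {
    ss <- attr(bundle$density, "sigma_scale")
    if (is.null(ss)) ss <- 1
    cc <- gmm_cc(model_to_gmm(cen_state, ss), bundle$density)
  }
  pos_viol <- NULL
  if (length(bundle$terminal_localizations)) {
    sp <- score_positional(cen_state, bundle$terminal_localizations)
    lab <- vapply(bundle$terminal_localizations, `[[`, character(1), "label")
    pos_viol <- data.frame(label = lab, penalty = sp$penalties)[
      sp$penalties > 0, , drop = FALSE]
  }
  structure(list(
    crosslinks = data.frame(links[, c("protein1", "residue1", "protein2",
                                      "residue2")],
                            best_distance = best, satisfied = sat_any),
    pct_satisfied_ensemble = mean(sat_any) * 100,
    pct_satisfied_per_model = per_model,
    centroid = cen, centroid_cc = cc,
    positional_violations = pos_viol, cutoff = cutoff),
    class = "satisfaction_report")
}

#' @export
print.satisfaction_report <- function(x, ...) {
  cat(sprintf(paste0("<satisfaction_report> %d crosslinks: %.1f%% ",
                     "ensemble-level (mean per-model %.1f%%) at %.0f A; ",
                     "centroid CC %.3f\n"),
              nrow(x$crosslinks), x$pct_satisfied_ensemble,
              mean(x$pct_satisfied_per_model), x$cutoff, x$centroid_cc))
  invisible(x)
}
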