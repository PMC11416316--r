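## Replica-exchange Gibbs Monte Carlo over rigid-body and flexible-bead
## degrees of freedom. mc_step() and replica_exchange() are the reference
## implementations used for unit-level checks; run_sampling() drives the
## compiled engine, which is verified against the reference scorers.

#' Monte Carlo move magnitudes
#'
#' Maximum magnitudes of the random transformations proposed each step;
#' each replica scales them by the square root of its temperature. In
#' addition to per-bead translations, each flexible chain is offered one
#' collective translation per sweep: large chain jumps are almost always
#' rejected, but they let a chain cross the high barriers that arise when
#' equivalent copies compete for ambiguous restraints, which per-bead
#' diffusion cannot cross.
#'
#' @param rb_max_rotation Rigid-body rotation, degrees.
#' @param rb_max_translation Rigid-body translation, Angstrom.
#' @param bead_max_translation Flexible-bead translation, Angstrom.
#' @param chain_max_translation Whole-chain translation, Angstrom
#'   (0 disables chain moves).
#' @export
move_set <- function(rb_max_rotation = 10, rb_max_translation = 4,
                     bead_max_translation = 4,
                     chain_max_translation = 40) {
  stopifnot(rb_max_rotation >= 0, rb_max_translation >= 0,
            bead_max_translation >= 0, chain_max_translation >= 0)
  structure(list(rb_max_rotation = rb_max_rotation,
                 rb_max_translation = rb_max_translation,
                 bead_max_translation = bead_max_translation,
                 chain_max_translation = chain_max_translation),
            class = "move_set")
}

#' Replica-exchange configuration
#'
#' @param n_replicas Number of replicas.
#' @param temperature_ladder Strictly ascending temperatures (kT); default
#'   geometric from 1.0 to 2.5.
#' @param swap_interval Steps between exchange attempts.
#' @param n_steps Monte Carlo steps (Gibbs sweeps) per run.
#' @param n_independent_runs Independent runs with distinct seeds.
#' @param seed Base seed.
#' @param frame_interval Steps between recorded frames of the
#'   lowest-temperature replica.
#' @export
replica_config <- function(n_replicas = 4L, temperature_ladder = NULL,
                           swap_interval = 10L, n_steps = 5000L,
                           n_independent_runs = 2L, seed = 1L,
                           frame_interval = 50L) {
  if (is.null(temperature_ladder))
    temperature_ladder <- exp(seq(log(1), log(2.5),
                                  length.out = n_replicas))
  if (length(temperature_ladder) != n_replicas)
    stop("replica_config: ladder length must equal n_replicas")
  if (any(diff(temperature_ladder) <= 0) || any(temperature_ladder <= 0))
    stop("replica_config: ladder must be strictly ascending and positive")
  structure(list(n_replicas = as.integer(n_replicas),
                 temperature_ladder = temperature_ladder,
                 swap_interval = as.integer(swap_interval),
                 n_steps = as.integer(n_steps),
                 n_independent_runs = as.integer(n_independent_runs),
                 seed = as.integer(seed),
                 frame_interval = as.integer(frame_interval)),
            class = "replica_config")
}

#' Axis-aligned bounding region for randomization
#' @param xlim,ylim,zlim Length-2 numeric ranges, Angstrom.
#' @export
bounding_region <- function(xlim, ylim, zlim) {
  lims <- list(xlim = sort(xlim), ylim = sort(ylim), zlim = sort(zlim))
  if (any(vapply(lims, diff, numeric(1)) <= 0))
    stop("bounding_region: all ranges must have positive extent")
  structure(lims, class = "bounding_region")
}

#' Default region: the state's bounding box with padding
#' @param state An `assembly_state`.
#' @param pad Padding in Angstrom.
#' @export
default_region <- function(state, pad = 50) {
  rng <- apply(state$coords, 2, range)
  bounding_region(rng[, 1] + c(-pad, pad), rng[, 2] + c(-pad, pad),
                  rng[, 3] + c(-pad, pad))
}

#' Randomize the movable parts of a state
#'
#' Movable rigid bodies get a uniformly random rotation about their
#' centroid and a centroid placed uniformly in the region; flexible beads
#' are placed uniformly in the region. Fixed scaffold bodies are
#' untouched. Deterministic in `seed`.
#'
#' @param state An `assembly_state`.
#' @param region A [bounding_region()].
#' @param seed Integer seed (`NULL` = use the current RNG stream).
#' @export
randomize_initial <- function(state, region = default_region(state),
                              seed = NULL) {
  doit <- function() {
    s <- state
    runifs <- function(n, lim) runif(n, lim[1], lim[2])
    for (b in seq_along(s$bodies)) {
      if (s$body_fixed[b]) next
      idx <- s$bodies[[b]]
      xyz <- s$coords[idx, , drop = FALSE]
      cen <- colMeans(xyz)
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      th <- runif(1, 0, 2 * pi)
      K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
      Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      newc <- c(runifs(1, region$xlim), runifs(1, region$ylim),
                runifs(1, region$zlim))
      s$coords[idx, ] <- sweep(xyz, 2, cen) %*% t(Rm) +
        matrix(newc, length(idx), 3, byrow = TRUE)
    }
    flex <- setdiff(movable_beads(s), unlist(s$bodies))
    if (length(flex))
      s$coords[flex, ] <- cbind(runifs(length(flex), region$xlim),
                                runifs(length(flex), region$ylim),
                                runifs(length(flex), region$zlim))
    s
  }
  if (is.null(seed)) doit() else with_seed(seed, doit())
}

#' Metropolis acceptance rule
#'
#' Vectorized: accept when the energy change is non-positive, otherwise
#' with probability `exp(-delta_e / temperature)`.
#'
#' @param delta_e Energy changes (kT).
#' @param temperature Temperature (kT).
#' @return Logical vector.
#' @export
metropolis_accept <- function(delta_e, temperature = 1) {
  stopifnot(temperature > 0)
  delta_e <= 0 | runif(length(delta_e)) < exp(-delta_e / temperature)
}

#' One Gibbs Monte Carlo step (reference implementation)
#'
#' A sweep of one Metropolis proposal per movable rigid body and per
#' flexible bead, each accepted at the given temperature against the
#' supplied energy function. Fixed bodies are never touched.
#'
#' @param state An `assembly_state`.
#' @param energy_fn Function `state -> scalar` (kT).
#' @param moveset A [move_set()].
#' @param temperature Temperature (kT).
#' @return List with the updated `state`, logical `accepted` per
#'   proposal, and the final `energy`.
#' @export
mc_step <- function(state, energy_fn, moveset = move_set(),
                    temperature = 1) {
  e <- energy_fn(state)
  accepted <- logical(0)
  for (b in seq_along(state$bodies)) {
    if (state$body_fixed[b]) next
    idx <- state$bodies[[b]]
    trial <- state
    xyz <- state$coords[idx, , drop = FALSE]
    cen <- colMeans(xyz)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, -1, 1) * moveset$rb_max_rotation * pi / 180
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    tr <- runif(3, -1, 1) * moveset$rb_max_translation
    trial$coords[idx, ] <- sweep(xyz, 2, cen) %*% t(Rm) +
      matrix(cen + tr, length(idx), 3, byrow = TRUE)
    e2 <- energy_fn(trial)
    ok <- metropolis_accept(e2 - e, temperature)
    accepted <- c(accepted, ok)
    if (ok) { state <- trial; e <- e2 }
  }
  flex <- setdiff(movable_beads(state), unlist(state$bodies))
  for (i in flex) {
    trial <- state
    trial$coords[i, ] <- state$coords[i, ] +
      runif(3, -1, 1) * moveset$bead_max_translation
    e2 <- energy_fn(trial)
    ok <- metropolis_accept(e2 - e, temperature)
    accepted <- c(accepted, ok)
    if (ok) { state <- trial; e <- e2 }
  }
  if (moveset$chain_max_translation > 0 && length(flex)) {
    for (ch in unname(split(flex, state$bead$chain[flex]))) {
      trial <- state
      shift <- runif(3, -1, 1) * moveset$chain_max_translation
      trial$coords[ch, ] <- sweep(state$coords[ch, , drop = FALSE], 2,
                                  -shift)
      e2 <- energy_fn(trial)
      ok <- metropolis_accept(e2 - e, temperature)
      accepted <- c(accepted, ok)
      if (ok) { state <- trial; e <- e2 }
    }
  }
  list(state = state, accepted = accepted, energy = e)
}

#' Probability of an adjacent replica swap
#'
#' `min(1, exp((beta_i - beta_j) * (E_i - E_j)))`.
#'
#' @param temperature_i,temperature_j Replica temperatures.
#' @param energy_i,energy_j Replica energies.
#' @export
swap_probability <- function(temperature_i, temperature_j, energy_i,
                             energy_j) {
  min(1, exp((1 / temperature_i - 1 / temperature_j) *
               (energy_i - energy_j)))
}

#' Attempt adjacent-pair replica exchanges (reference implementation)
#'
#' Replicas are ordered by temperature slot; each adjacent pair swaps its
#' configurations with the Metropolis exchange probability. The multiset
#' of configurations is preserved.
#'
#' @param replicas List of lists with elements `state`, `temperature`,
#'   `energy`.
#' @param parity 0 attempts pairs (1,2), (3,4), ...; 1 attempts (2,3), ...
#' @return List with the updated `replicas`, and `attempted`/`accepted`
#'   counts.
#' @export
replica_exchange <- function(replicas, parity = 0L) {
  if (length(replicas) < 2L) stop("replica_exchange: need >= 2 replicas")
  attempted <- 0L; accepted <- 0L
  for (a in seq(1L + parity, length(replicas) - 1L, by = 2L)) {
    attempted <- attempted + 1L
    p <- swap_probability(replicas[[a]]$temperature,
                          replicas[[a + 1]]$temperature,
                          replicas[[a]]$energy, replicas[[a + 1]]$energy)
    if (runif(1) < p) {
      tmp <- replicas[[a]]$state
      replicas[[a]]$state <- replicas[[a + 1]]$state
      replicas[[a + 1]]$state <- tmp
      tmpe <- replicas[[a]]$energy
      replicas[[a]]$energy <- replicas[[a + 1]]$energy
      replicas[[a + 1]]$energy <- tmpe
      accepted <- accepted + 1L
    }
  }
  list(replicas = replicas, attempted = attempted, accepted = accepted)
}

## ---- compiled scoring plan ----------------------------------------------

#' Compile a state + data bundle into the engine's scoring plan
#'
#' Flattens every restraint into index arrays consumed by the compiled
#' sampler; `plan_score()` evaluates the identical function from R.
#'
#' @param state An `assembly_state`.
#' @param bundle Data bundle (see [total_score()]).
#' @param weights A [restraint_weights()].
#' @param k Common harmonic stiffness.
#' @param c_factor Connectivity threshold multiplier.
#' @param include_symmetry_images Include neighbor-image excluded volume.
#' @return A plan list.
#' @export
compile_plan <- function(state, bundle, weights = restraint_weights(),
                         k = 1, c_factor = 1.2,
                         include_symmetry_images = FALSE) {
  cutoff <- if (!is.null(bundle$xl_cutoff)) bundle$xl_cutoff else 35
  xl <- list(); xl_mult <- numeric(0)
  if (!is.null(bundle$crosslinks) && nrow(bundle$crosslinks)) {
    xl <- map_crosslinks(state, bundle$crosslinks)
    xl_mult <- as.numeric(bundle$crosslinks$multiplicity)
  }
  conn <- connectivity_pairs(state, c_factor)
  ev <- ev_pairs(state)
  ev <- cbind(ev, rep(1, nrow(ev)), rep(0, nrow(ev)))
  if (include_symmetry_images && state$n_symmetry > 1L) {
    sel <- coarse_beads(state)
    th <- 2 * pi / state$n_symmetry
    pr <- expand.grid(i = sel, j = sel)
    ev <- rbind(ev, cbind(pr$i, pr$j,
                          state$radius[pr$i] + state$radius[pr$j],
                          cos(th), sin(th)))
  }
  pos <- list()
  if (length(bundle$terminal_localizations)) {
    pos <- lapply(bundle$terminal_localizations, function(sp) {
      groups <- map_positional(state, sp)
      list(groups = unname(groups),
           type = if (!is.null(sp$target)) 0L else 1L,
           target = if (!is.null(sp$target)) as.numeric(sp$target)
                    else c(0, 0, 0),
           zmin = if (!is.null(sp$slab)) sp$slab[1] else 0,
           zmax = if (!is.null(sp$slab)) sp$slab[2] else 0,
           tol = sp$tolerance, k = k)
    })
  }
  prox <- list()
  if (!is.null(bundle$proximity) && nrow(bundle$proximity)) {
    idx <- crosslink_beads(state)
    b <- state$bead[idx, ]
    dom <- function(su, f, l) idx[b$subunit == su & b$res_first <= l &
                                    b$res_last >= f]
    prox <- lapply(seq_len(nrow(bundle$proximity)), function(r) {
      p <- bundle$proximity[r, ]
      list(A = dom(p$subunit1, p$first1, p$last1),
           B = dom(p$subunit2, p$first2, p$last2),
           bound = p$max_distance)
    })
  }
  equiv <- matrix(0, 0, 3)
  if (!is.null(bundle$equivalence)) {
    al <- bundle$equivalence$alignment
    if (is.null(al$copy)) al$copy <- 1L
    if (is.null(al$ref_copy)) al$ref_copy <- 1L
    bi <- map_alignment(state, al$subunit, al$residue, al$copy)
    bj <- map_alignment(bundle$equivalence$reference, al$ref_subunit,
                        al$ref_residue, al$ref_copy)
    dr <- as.matrix(dist(bundle$equivalence$reference$coords[bj, ,
                                                             drop = FALSE]))
    up <- which(upper.tri(dr), arr.ind = TRUE)
    equiv <- cbind(bi[up[, 1]], bi[up[, 2]], dr[up])
  }
  has_em <- !is.null(bundle$density)
  em_idx <- integer(0); em_w <- numeric(0); em_s2 <- numeric(0)
  map_mu <- matrix(0, 0, 3); map_w <- numeric(0); map_s2 <- numeric(0)
  if (has_em) {
    ss <- attr(bundle$density, "sigma_scale")
    if (is.null(ss)) ss <- 1
    em_idx <- coarse_beads(state)
    em_w <- as.numeric(state$bead$nres[em_idx])
    em_s2 <- (ss * state$radius[em_idx])^2
    map_mu <- bundle$density$mean
    map_w <- bundle$density$weight
    map_s2 <- bundle$density$sigma^2
  }
  flex <- setdiff(movable_beads(state), unlist(state$bodies))
  mb <- state$bodies[!state$body_fixed]
  chains <- unname(split(flex, state$bead$chain[flex]))
  list(radius = state$radius,
       move_chains = chains,
       conn = conn, conn_k = k, w_conn = weights$connectivity,
       ev = ev, ev_k = k, w_ev = weights$excluded_volume,
       xl = xl, xl_mult = xl_mult, xl_cutoff = cutoff, xl_k = k,
       w_xl = weights$crosslink,
       pos = pos, w_pos = weights$positional,
       prox = prox, prox_k = k, w_prox = weights$proximity,
       equiv = equiv, eq_k = k, w_eq = weights$equivalence,
       has_em = has_em, w_em = weights$em, em_idx = em_idx,
       em_model_w = em_w, em_model_s2 = em_s2,
       map_mu = map_mu, map_w = map_w, map_s2 = map_s2,
       move_beads = flex, move_bodies = mb)
}

#' Score a coordinate set under a compiled plan
#' @param plan From [compile_plan()].
#' @param coords n x 3 coordinate matrix.
#' @return List with `total` and weighted `terms`.
#' @export
plan_score <- function(plan, coords) cpp_score(plan, as.matrix(coords))

## ---- the sampler ----------------------------------------------------------

#' Run replica-exchange Gibbs Monte Carlo sampling
#'
#' Executes `n_independent_runs` runs with distinct seeds. Each run
#' randomizes the movable degrees of freedom (all replicas start from
#' independent randomizations), then samples with the compiled engine and
#' keeps every `frame_interval`-th frame of the lowest-temperature
#' replica with its score and per-term breakdown.
#'
#' @param state An `assembly_state` (topology + fixed scaffold).
#' @param bundle Data bundle (see [total_score()]).
#' @param config A [replica_config()].
#' @param moveset A [move_set()].
#' @param weights A [restraint_weights()].
#' @param region Randomization region; defaults to the state's padded box.
#' @param k,c_factor,include_symmetry_images Scoring options (see
#'   [compile_plan()]).
#' @return A `model_ensemble`: frames, scores, per-term breakdowns and
#'   run/replica/step provenance.
#' @export
run_sampling <- function(state, bundle, config = replica_config(),
                         moveset = move_set(),
                         weights = restraint_weights(),
                         region = default_region(state), k = 1,
                         c_factor = 1.2, include_symmetry_images = FALSE) {
  plan <- compile_plan(state, bundle, weights, k, c_factor,
                       include_symmetry_images)
  frames <- list(); scores <- numeric(0); terms <- NULL
  prov <- data.frame(run = integer(0), replica = integer(0),
                     step = integer(0))
  accept <- list()
  for (run in seq_len(config$n_independent_runs)) {
    res <- with_seed(config$seed + (run - 1L) * 1000L, {
      starts <- lapply(seq_len(config$n_replicas), function(r)
        randomize_initial(state, region)$coords)
      cpp_run_rex(plan, starts, config$temperature_ladder, config$n_steps,
                  config$swap_interval, config$frame_interval,
                  moveset$bead_max_translation, moveset$rb_max_rotation,
                  moveset$rb_max_translation,
                  chain_max_trans = moveset$chain_max_translation)
    })
    frames <- c(frames, res$frames)
    scores <- c(scores, res$scores)
    terms <- rbind(terms, res$terms)
    prov <- rbind(prov, data.frame(run = run, replica = 1L,
                                   step = res$steps))
    accept[[run]] <- res$accept
  }
  structure(list(state = state, frames = frames, scores = scores,
                 terms = terms, provenance = prov, accept = accept,
                 config = config, weights = weights, plan = plan),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<model_ensemble> %d frames from %d run(s); ",
                     "score range [%.2f, %.2f]\n"),
              length(x$frames), max(x$provenance$run), min(x$scores),
              max(x$scores)))
  invisible(x)
}

#' State holding a given ensemble frame's coordinates
#' @param ensemble A `model_ensemble`.
#' @param i Frame index.
#' @export
ensemble_state <- function(ensemble, i) {
  s <- ensemble$state
  s$coords <- ensemble$frames[[i]]
  s
}
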