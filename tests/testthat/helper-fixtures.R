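# Shared fixtures: all built in code, scaled small for speed.

# compact synthetic geometry for unit tests (the full presets are used in
# the acceptance suite)
small_params <- function(seed = 42L, ...) {
  ground_truth_params(strut_tilt = 30, distal_offset = 150,
                      distal_ring_diameter = 200, beads_per_strut = 10L,
                      anchor_chain_lengths = c(Nup1s = 30, Nup60s = 20,
                                               Nup2s = 20),
                      seed = seed, ...)
}

small_bundle <- function(seed = 42L, fp_rate = 0, jitter = 0,
                         n_true = 40L) {
  make_ground_truth_bundle(small_params(seed), fp_rate = fp_rate,
                           jitter = jitter, n_true = n_true)
}

# a bare two-chain state: chain A with `na` beads, chain B with `nb`,
# radius r, coordinates supplied as rows
toy_state <- function(coords_a, coords_b = NULL, r = 5,
                      subunit_b = "B", copies_b = 1L) {
  coords_a <- matrix(coords_a, ncol = 3, byrow = TRUE)
  bead <- data.frame(subunit = "A", copy = 1L, resolution = 10L,
                     res_first = seq_len(nrow(coords_a)) * 10L - 9L,
                     res_last = seq_len(nrow(coords_a)) * 10L,
                     nres = 10L)
  coords <- coords_a
  if (!is.null(coords_b)) {
    coords_b <- matrix(coords_b, ncol = 3, byrow = TRUE)
    nb <- nrow(coords_b) / copies_b
    bead_b <- data.frame(subunit = subunit_b,
                         copy = rep(seq_len(copies_b), each = nb),
                         resolution = 10L,
                         res_first = rep(seq_len(nb) * 10L - 9L, copies_b),
                         res_last = rep(seq_len(nb) * 10L, copies_b),
                         nres = 10L)
    bead <- rbind(bead, bead_b)
    coords <- rbind(coords, coords_b)
  }
  npcbasket:::new_assembly_state(coords, rep(r, nrow(coords)), bead)
}

# frames that are translated copies of a base coordinate set
shifted_frames <- function(base, shifts) {
  lapply(shifts, function(s) sweep(base, 2, -c(s, 0, 0)))
}
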