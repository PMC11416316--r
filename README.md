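# npcbasket

Desk-scale integrative structure modeling of nuclear-basket-like
assemblies: the eight-fold symmetric cage of coiled-coil struts that hangs
from the nuclear ring (NR) of the nuclear pore complex and converges on a
distal ring. The package is aimed at structural bioinformaticians who want
a self-contained, fully testable implementation of the four-stage
integrative workflow — input information, representation + restraints,
configurational sampling, ensemble validation — without cluster-scale
infrastructure or experimental downloads.

## What it implements

**Representation.** Subunit tables (name, length, copies, segment
annotations) become a multiscale bead model of one symmetry unit against a
fixed scaffold: rigid segments with source coordinates are dual-resolution
rigid bodies (1 and 10 residues/bead), flexible segments are strings at 10
residues/bead, FG-repeat segments are excluded, and bead radii are
volume-proportional, r = 3.0·n^(1/3) Å. The shipped stoichiometries build
21 subunits of 12 types per yeast unit and 24 of 12 per mammalian unit.

**Scoring.** One-sided harmonic restraints (stiffness k, kT/Å²) plus a
density term:

* crosslinks: min-over-copies bead distance ≤ 35 Å (DSS convention),
  penalty ½k(d−35)² beyond;
* density: 1 − CC, with CC = ⟨f,g⟩/√(⟨f,f⟩⟨g,g⟩) the normalized analytic
  overlap of two Gaussian mixtures (model mixture: one sphere per coarse
  bead);
* immuno-EM point targets with flat-bottom tolerance and membrane
  z-slabs; domain-proximity upper bounds; chain connectivity at
  1.2(rᵢ+rⱼ); soft-sphere excluded volume; superposition-free
  inter-species distance-matching ("equivalence") restraints.

**Sampling.** Replica-exchange Gibbs Monte Carlo in compiled code:
per-sweep Metropolis proposals for rigid bodies, whole flexible chains and
individual beads, geometric temperature ladder 1.0–2.5, adjacent-pair
configuration swaps with probability min(1, exp((βᵢ−βⱼ)(Eᵢ−Eⱼ))).
Deterministic under a seed.

**Validation.** Good-scoring selection, no-superposition RMSD in the fixed
scaffold frame with exact copy-permutation minimization, greedy threshold
clustering, the two-half sampling-exhaustiveness protocol
(Kolmogorov–Smirnov on scores; chi-square + Cramér's V on cluster
populations over a threshold grid; sampling precision = smallest threshold
with p > 0.05 and V < 0.10), model precision (mean pairwise RMSD),
localization probability densities, and restraint-satisfaction reports.

**Synthetic ground truth.** `make_ground_truth()` builds an idealized
basket with known geometry (yeast preset: 30° strut tilt, 540 Å distal
offset, 760 Å distal ring; mouse preset: 6°, 630 Å, 1000 Å) and simulates
every input: within-cutoff crosslinks plus an exact count of false
positives, a Gaussian-mixture density with optional jitter, and
terminal-domain localizations. Everything regenerates bit-identically from
parameters + seed.

**Spatial statistics.** Per-tomogram pairwise distances and the radial
distribution function g(r) of particle coordinates, with translational
edge correction in each tomogram box and per-tomogram curves averaged
into the final one, plus a Monte-Carlo global CSR envelope.

## Worked example

Build the yeast synthetic truth, simulate noiseless inputs, sample briefly
and validate:

```r
library(npcbasket)
params <- basket_preset("yeast", seed = 1)
truth  <- make_ground_truth(params)
truth
#> <assembly_state> 296 beads, 9 chains, 1 rigid bodies (176 beads fixed), C8 symmetry
measure_geometry(truth)
#> $strut_tilt            30
#> $distal_offset         540
#> $distal_ring_diameter  761.643

bundle <- make_ground_truth_bundle(params, fp_rate = 0, jitter = 0)
round(total_score(truth, bundle)$terms, 4)
#> crosslink em positional proximity connectivity excluded_volume equivalence
#>         0  0          0         0            0               0           0
```

The truth scores exactly zero on every term, and the measured geometry
reproduces the preset (the ring diameter is 1.6 Å wide of 760 because the
two strut chains sit ±25 Å off the mid-plane). A short sampling run from
randomized starts:

```r
cfg <- replica_config(n_replicas = 4, n_steps = 2000,
                      n_independent_runs = 2, seed = 1)
ens <- run_sampling(truth, bundle, cfg)
ens
#> <model_ensemble> 80 frames from 2 run(s); score range [453.03, 9703921.79]
sel <- select_good_scoring(ens, percentile = 20)
cl  <- cluster_models(sel, 30)
top <- cl$clusters[[which.max(lengths(cl$clusters))]]
cen <- cluster_centroid(sel$frames, truth, top)
rmsd(truth, cen$state, copy_permutation = TRUE)
#> 33.86
satisfaction_report(sel$frames[top], truth, bundle, cutoff = 35)
#> <satisfaction_report> 150 crosslinks: 99.3% ensemble-level (mean per-model
#> 90.3%) at 35 A; centroid CC 0.809
```

2,000 sweeps only rough out the architecture (33.9 Å from the truth,
99.3% of crosslinks already satisfied somewhere in the ensemble). The
full-scale experiment — 4 replicas × 20,000 sweeps × 2 independent runs,
about 2.5 minutes on one core — recovers the truth to ~3.9 Å, with 100%
ensemble-level crosslink satisfaction and a centroid density correlation
of 0.95; that is the run the acceptance script performs.

## File formats

Crosslink CSV (`protein1,residue1,protein2,residue2,linker`, 1-based),
Gaussian mixtures as `weight x y z sigma` text tables, bead models as
mmCIF with one pseudo-atom per bead (radius in the B-factor field),
voxel maps as MRC2014 mode 2, configurations as YAML. Particle tables
for g(r) are CSV with `tomogram,x,y,z[,class]` and a declared unit.
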