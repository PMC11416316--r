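---
title: "Integrative modeling of basket-like assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative modeling of basket-like assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcbasket)
```

# The modeling problem

The nuclear basket is an eight-fold symmetric assembly hanging from the
nucleoplasmic face of the nuclear pore complex: coiled-coil struts emanate
from the double nuclear ring (NR) at an angle from the central axis and
converge on a distal ring, with several FG nucleoporins anchored near the
scaffold. `npcbasket` implements the four-stage integrative workflow used
to determine such architectures at desk scale: (1) input information as
data structures, (2) a multiscale bead representation with spatial
restraints, (3) replica-exchange Gibbs Monte Carlo sampling, and (4)
ensemble validation. A synthetic generator with known ground truth stands
in for the experimental inputs, so the entire pipeline is testable
end-to-end.

# Representation

One symmetry unit is modeled against a fixed scaffold; the other seven
units are exact rotations used for export and optional clash checks.
Subunits are declared with [subunit_spec()]: a length, a copy number and a
segment annotation (`rigid`, `coiled-coil`, `disordered`, `excluded`).
Excluded segments (FG repeats) produce no beads. Rigid segments backed by
source coordinates become rigid bodies represented at two resolutions —
one residue per bead for distance restraints and ten residues per bead for
excluded volume — moving as one unit; everything else becomes a flexible
string at ten residues per bead. The schedule is a package choice: one
fine level preserves residue-specific crosslink information where
coordinates exist, one coarse level keeps excluded volume quadratic in a
small bead count. Bead radii grow with the cube root of residue content,
`r = 3.0 * n^(1/3)` Å, i.e. volume-proportional with a one-residue radius
of 3 Å, a standard coarse-graining convention.

The shipped stoichiometry tables give 21 subunits of 12 types for the
yeast basket unit (Mlp1 and Mlp2 carried as generic poly-alanine chains of
Mlp1's length because their individual stoichiometry is ambiguous; one
Nup1; two each of Nup2 and Nup60; two heptameric Nup84 complexes) and 24
subunits of 12 types for the mammalian unit (two each of Tpr, Nup50,
Nup153 and the nonameric Nup107 complex). FG segment boundaries in these
tables are round-number annotations; only lengths and copy numbers affect
the counts.

# Restraints

All data terms are one-sided harmonics with a common stiffness `k`
(default 1 kT/Å<sup>2</sup>); energies are in kT. The terms:

* **Crosslinks.** A record restrains the minimum bead-center distance over
  all copy assignments of its two proteins (an exact minimum, not a
  soft-min, so penalties are reproducible) to an upper bound of 35 Å, the
  usual Cα–Cα working cutoff for DSS.
* **Density.** The model becomes a Gaussian mixture (one spherical
  component per coarse bead, width = bead radius, weight = residue count)
  and is scored by `1 - CC` against the map mixture, where CC is the
  normalized analytic Gaussian overlap. CC is symmetric, lies in [0, 1]
  for nonnegative weights, and is invariant to rescaling either mixture's
  weights.
* **Positional restraints.** Immuno-EM style point targets with a
  flat-bottom tolerance, and z-slabs for membrane-anchored segments.
* **Proximity.** Upper bounds on minimum inter-domain distances from
  affinity co-purification.
* **Connectivity.** Consecutive beads of a chain within
  `1.2 * (r_i + r_j)`; pairs held inside one rigid body are exempt (the
  body preserves them exactly).
* **Excluded volume.** Soft-sphere lower bounds over non-bonded coarse
  bead pairs, optionally against the neighboring symmetry image.
* **Structural equivalence.** Superposition-free matching of intra-model
  distances across aligned residues of two species' models.

Per-term weights are exposed in `restraint_weights()`. The EM weight
deserves a note: the harmonic terms are flat inside their bounds, so with
a 35 Å crosslink cutoff the axial register of a strut chain is only
pinned to about one bead spacing by distances alone. The density term's
per-bead "bumpiness" resolves this register, provided its weight makes a
~1% CC loss comparable to several violated crosslinks. The default
(`em = 2000`) was calibrated on the synthetic basket to cross that
threshold; it is the one deliberately tuned constant in the scoring
function, and it is data-set independent in the sense that only the
relative scale of `1 - CC` against harmonic penalties matters.

# Sampling

Sampling is Gibbs-style Metropolis Monte Carlo with replica exchange:
each step sweeps one proposal per movable rigid body (random rotation
about its centroid plus translation), one collective translation per
flexible chain, and one translation per flexible bead, each accepted by
the Metropolis rule at the replica's temperature; every `swap_interval`
steps adjacent temperature slots attempt configuration swaps with
probability `min(1, exp((β_i − β_j)(E_i − E_j)))`. The default ladder is
geometric from 1.0 to 2.5 over four replicas. Move magnitudes scale with
the square root of temperature.

The whole-chain translation move is the one addition beyond per-body and
per-bead transformations, and it earns its place: with copy-ambiguous
restraints (two equivalent copies of a subunit serving two clusters of
crosslinks), per-bead diffusion cannot carry a chain across the barrier
separating "both copies on one side" from the correct assignment — the
intermediate states violate hundreds of kT of restraints. A rigid chain
jump, almost always rejected, occasionally lands in the correct basin and
is then accepted instantly. In calibration runs the trap occurred in a
substantial fraction of seeds without chain moves and disappeared with
them.

The engine is compiled (C++ via Rcpp), scores proposals by local energy
deltas with cached Gaussian-overlap sums for the density term, and
resynchronizes total energies periodically (measured bookkeeping drift is
at machine precision, ~1e-14 relative). The R-level `mc_step()`,
`replica_exchange()` and all `score_*()` functions are reference
implementations; the test suite asserts exact agreement between the
compiled plan scorer and the reference scorers on randomized states.
Sampling is deterministic given the configuration seed; independent runs
use distinct derived seeds.

# Validation

Good-scoring selection takes a score percentile and/or per-term caps.
RMSD is computed over bead centers in the fixed scaffold frame — no
superposition, since the scaffold never moves — with optional exact
minimization over permutations of equivalent copies (at most two copies
per type here, so enumeration is trivial). Clustering is greedy: the
frame with the most neighbors within the threshold seeds a cluster, and
the procedure repeats on the remainder.

Sampling exhaustiveness follows the two-half protocol: split the selected
models by independent run, compare score distributions
(Kolmogorov–Smirnov), then compare cluster populations of the pooled set
across a threshold grid (chi-square p and Cramér's V); the sampling
precision is the smallest threshold with p > 0.05 and V < 0.10. Model
precision is the average pairwise RMSD within a cluster (average RMSD to
the medoid is reported alongside).

Two centroid notions are distinguished deliberately. The *medoid* (member
minimizing total RMSD to the rest) is a single thermal sample: at kT = 1
with unit stiffness, an equilibrated frame sits several Å from the basin
bottom purely through thermal motion. The *centroid model* returned by
`cluster_centroid()` is the coordinate-wise mean over members after
relabeling equivalent copies to match the medoid; averaging cancels
thermal noise and is the right object to compare against a known truth.

Localization probability densities are per-voxel member fractions: a
member covers a voxel where its Gaussian-smoothed occupancy (width = bead
radius) reaches half its center value, and the map averages the member
indicators, so values live in [0, 1] and the map integral equals the mean
member envelope volume.

# The synthetic generator

`make_ground_truth()` builds an idealized basket: a fixed two-tier
scaffold arc (80 pseudo-residues per tier along the 45° sector), two
parallel strut chains of collinear beads tilted from the central axis and
ending in a three-bead distal blob, and short anchor chains placed as
seeded compact walks near the scaffold. The yeast preset uses the
measured geometry (30° tilt, 540 Å axial offset, 760 Å distal ring
diameter, ~100 Å strut thickness); the mouse preset uses 6°, 630 Å and a
1000 Å distal diameter. Tilt, offset and ring diameter jointly determine
the strut attachment radius, which the preset derives
(`R = D/2 + offset·tan(tilt)`) so the three are consistent by
construction. Strut bead spacing is chosen below the connectivity
threshold so the truth scores zero on every prior, and the blob centroid
sits exactly at the distal offset.

Simulated inputs mirror the real ones: crosslinks are drawn uniformly
from residue pairs whose scoring-resolution bead distance (minimized over
equivalent copies) is within the 35 Å cutoff, with false positives drawn
only from pairs beyond the cutoff so violation counts are exact — the
effective false-positive rate of production crosslink sets at the
modeling stage is generally unreported, so the bundle default of 5% is a
package choice (and the recovery experiment uses 0%).
The density is the truth's own mixture with optional mean jitter;
terminal localizations target the strut chains' terminal beads with a
default 25 Å uncertainty, an immuno-EM-like scale. Crosslinks inside the
immobile scaffold, and between consecutive beads of one chain, are not
sampled: they cannot inform the model. Bundles regenerate bit-identically
from parameters plus seed, which is how bundle directories are read back.

What the generator does *not* emulate: coiled-coil supercoiling and
curvature (struts are straight rods; the restraint mathematics, not
coiled-coil geometry, is under test), FG-repeat polymers, a membrane
surface, density anisotropy or missing wedges, and crosslink false
positives with realistic distance structure. Passing the recovery test
therefore demonstrates the correctness of the restraint/sampling/analysis
machinery, not performance on real cryo-ET data.

# The recovery experiment and problem sizes

The headline experiment samples the yeast preset (296 beads, 121 movable
coarse beads) against 150 noiseless crosslinks, the sharp density and
terminal localizations, with 4 replicas × 20,000 sweeps × 2 independent
runs — sizes chosen so the full experiment completes in minutes on one
core while still being far from trivial (random initial configurations,
~360 movable degrees of freedom). Analysis selects the best-scoring 20%,
estimates sampling precision, clusters at it, and compares the top
cluster's centroid model to the truth; the target is twice the mean bead
radius, with at least 90% of crosslinks satisfied ensemble-level at
35 Å. Production-scale results from real data (tens of Å precision on
real baskets) are outside what a desk-scale synthetic run can or should
reproduce.

# Radial distribution function

`radial_distribution()` treats particle coordinates per tomogram as a 3D
point pattern in the tomogram box: per bin, observed pair counts divide
by the expectation for a homogeneous process of the same intensity in the
same box, with translational edge correction via the box's isotropised
set covariance (evaluated by Fibonacci-sphere quadrature; verified
against brute-force Monte Carlo). The final curve is the unweighted mean
over tomograms, not pooled pairs, and per-tomogram curves are returned.
Coordinates near the curved nuclear envelope are in truth confined to a
2D surface; treating them as a 3D pattern in the box is an approximation
the user should keep in mind at large r. The CSR envelope is a
Monte-Carlo *global* envelope: replicate CSR tables with the observed
boxes and counts are reduced to their maximum studentized deviation from
1, so the whole tested curve stays inside with the stated probability —
a pointwise band would be crossed somewhere by almost every realization.

# Numerical choices and degenerate inputs

Harmonic penalties are exactly zero inside their bounds. CC guards
against zero-norm mixtures. Cluster ties resolve to the
first-encountered maximum neighborhood. A single-member cluster has
precision 0 (with a message). An empty good-scoring selection is an
explicit flagged outcome, not an empty silence. The exhaustiveness
population test treats a single-cluster threshold as indistinguishable
(p = 1, V = 0), which makes duplicated halves pass at the smallest grid
threshold, as they should. Chain moves with magnitude 0 disable the move
class; all moves with magnitude 0 leave the state untouched and accepted
(ΔE = 0).

# Limitations

Restraint weights beyond the EM term are uncalibrated defaults; plain
upper bounds (no Bayesian per-link noise models) are used by design;
sampling at desk scale cannot certify exhaustiveness for production-size
systems — the two-run split test is a necessary, not sufficient,
condition; and the mmCIF/MRC writers cover the subset of those formats
the pipeline itself produces.
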