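---
title: "Methods: characterizing block-copolymer micelles from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing block-copolymer micelles from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micelletools)
```

## The system and the questions

Amphiphilic block copolymers of poly(methyl acrylate) (MA, hydrophobic) and
poly(ethylene oxide) (EO, hydrophilic) self-assemble in water into micelles
with an MA-rich core and a hydrated EO corona. At fixed chemical
composition, the chain *architecture* — linear diblock (MA12-EO30),
MA-terminated triblock (MA6-EO31-MA6), EO-terminated triblock
(EO15-MA12-EO15), or ring (cyclic MA12-EO31) — changes how many chains
aggregate, how spherical the micelle is, how wet its core is, and which
conformations individual chains adopt inside it. `micelletools` implements
the trajectory-analysis stages needed to quantify those differences from
all-atom or coarse-grained MD output, plus a synthetic micelle generator
with planted ground truth that every stage is validated against.

## Polymer model and equivalence classes

A `polymer_spec` maps monomers to atoms and records the chain's bonded
topology. Contact and hydration statistics are pooled over *chemically
equivalent* monomers: MA monomers mapped onto each other by the chain's
topological symmetry. We derive the classes from the bonded distance of
each MA monomer to its nearest EO monomer (wrapping for rings): both
triblocks and the ring map their 12 MA monomers onto six classes MA1..MA6
with MA1 bonded to EO, while the diblock's 12 MA monomers are all
inequivalent (MA1..MA12). This single rule reproduces the symmetric class
structure for every supported architecture, and validation checks that
end-for-end relabeling (composed with a cyclic rotation for rings) leaves
the partition unchanged.

The bundled bead model is deliberately coarse: three beads per MA monomer
(backbone carbons; the carbonyl oxygen, which anchors hydration-shell
counting; the ester methyl group) and two per EO monomer, with bead masses
summing to the monomer formula masses. Every analysis is defined on atom
groups, so fidelity to group structure and masses — not chemistry — is what
the downstream statistics require.

## Aggregate identification

Two polymers are in contact when any pair of their heavy atoms is within a
cutoff under the minimum-image convention; micelles are connected
components of this graph (single linkage), and unimers count as aggregates
of size one. The literature rarely states its grouping rule; we default to
the common heavy-atom 4.5 Å criterion and expose it in every entry point
and in the pipeline config. Aggregates are re-joined across periodic
boundaries before any geometry: each chain is unwrapped along its bonds,
then chains are joined breadth-first over the contact graph, shifting each
by the box image that realizes its minimum distance to an already-placed
neighbor. Only orthorhombic boxes are supported; triclinic inputs are
refused with a clear error.

The aggregation-number distribution is polymer-weighted by default (each
polymer contributes the size of its micelle), which describes micelle size
as experienced per chain; the unweighted per-aggregate variant is always
reported alongside.

## Stationarity (burn-in)

Self-assembly trajectories begin far from steady state. `estimate_burn_in`
slides a window over the largest-aggregate size series and returns the
first frame from which every window mean stays within a tolerance of the
final window's mean (0 for an already-stationary series). If the stationary
tail is shorter than two windows, the estimate falls back to half the
series and is flagged — a deliberately loud failure mode, since averaging a
non-stationary segment silently is the worse error. Defaults: window 20
frames, tolerance 0.5 polymers.

## Shape metrics

The mass-weighted gyration tensor about the aggregate center of mass gives
the radius of gyration as the square root of its trace (an exact identity
against its eigenvalues, asserted on every call). Eccentricity is defined
from the principal moments of inertia as `1 - I_min / I_avg`, the standard
micelle-literature deviation-from-sphere metric: it is zero for a sphere
and, for a uniform prolate ellipsoid with semi-axes (a, a, 2a), equals 0.5
analytically — both limits are tested against independently sampled point
clouds.

## Density profiles, core membership and hydration

Radial profiles histogram component masses (MA, EO, water) by distance from
the aggregate center, divide by exact spherical-shell volumes, and average
over frames; mass densities are reported in g/cm³ with a number-density
toggle recorded in the manifest. The conservation identity
Σ(density × shell volume) = in-range mass holds to machine precision by
construction and is asserted to 1e-6 in tests.

"Core" membership supports two definitions: the radius where EO density
first overtakes MA density going outward (`radial_crossover`), and the
intrinsic interface (`icsi_surface`, below). Core hydration counts distinct
water oxygens within the hydration cutoff (default 3.5 Å, the carbonyl-O to
water-O first-RDF-minimum convention; closed boundary, so a water exactly at
the cutoff counts) of any atom of a core monomer, reported *per core
monomer, frame-averaged* — the denominator is recorded in the output because
tabulated core-hydration quantities in the literature rarely state theirs.
The end-out fraction is the fraction of chains with at least one terminal
MA block whose center of mass lies outside the core — the escape
conformation of flower-like micelles; it is undefined (NA) for
architectures without terminal MA blocks.

## The intrinsic core-shell interface

A micelle's core-corona interface is rough, and measuring density against
the global center smears structure over that roughness. The intrinsic
construction instead builds, per frame, an angular map of the interface
radius: the unit sphere around the aggregate center is divided into
equal-area cells (a grid uniform in cos θ and φ — every cell subtends the
same solid angle, cell lookup is O(1), and the grid's natural adjacency
drives both empty-cell fill-in and the area's tilt correction). Each cell's
anchor is its outermost core-block heavy atom; anchorless cells inherit the
nearest non-empty neighbor value breadth-first. The intrinsic distance of
any particle is its radial distance minus the interface radius in its
direction: negative in the core, zero at the interface, positive outside.

This radial-anchor surface presumes a star-convex aggregate; near-spherical
micelles (eccentricity ≈ 0.1) satisfy this comfortably, and an eccentricity
guard (default 0.35) refuses wormlike aggregates rather than returning
meaningless surfaces. The construction follows the intrinsic core-shell
interface idea as an independent, testable realization; outputs are
"ICSI-compatible" rather than bit-identical to any particular reference
code, and the manifest records every resolution choice.

Surface area integrates `s² dΩ` with a local tilt factor
`sqrt(1 + (∂s/∂θ / s)² + (∂s/∂φ / (s sin θ))²)` from centered finite
differences on the grid. For a spherical anchor set the gradients vanish
and the area is exactly `4πR²`; a raw inscribed triangulation would
undershoot, violating the lower bound by the sphere of radius min s. A
dense independent triangulation oracle agrees within 2% on rough-sphere
fixtures. Intrinsic shell volumes for density normalization are measured by
seeded Monte-Carlo sampling against the same surface (default 1e5 points
per frame; 2e4 in the bundled pipeline config), since the shells of a rough
surface have no closed form; conservation then holds exactly against the
measured volumes.

## Conformational landscape

Per (polymer, frame), the feature vector is the upper triangle of the
monomer center-of-mass pairwise distance matrix — rigid-motion invariant by
construction and exactly the geometry in which micellar chain conformations
differ ("relative extension" of the MA and EO blocks); per-block radius of
gyration and end-to-end distance can be appended. Features are standardized
column-wise and reduced to at most 50 principal components before the
neighbor search.

Dimensionality reduction is a neighbor-graph method in the modern
manifold-learning family, implemented in the package: a fuzzy k-nearest
neighbor graph with locally adaptive kernel widths (per-point bandwidths
solved so the smoothed neighborhood has log2(k) effective members,
symmetrized by probabilistic union), laid out in two dimensions by spectral
initialization on the normalized graph Laplacian and refined by a seeded
attraction-repulsion optimization with a Cauchy low-dimensional kernel.
Clustering is a complete hierarchical density-based implementation:
mutual-reachability distances from k-NN core distances, a Prim minimum
spanning tree, condensation of the single-linkage hierarchy by minimum
cluster size, and excess-of-mass stability selection, with low-density
points labeled noise (−1). Defaults: 15 neighbors, min_dist 0.1, minimum
cluster size max(25, 1% of rows), min_samples equal to the cluster floor
(lower it for small runs — the pipeline's bundled small-system configs do).
Both steps are deterministic for a fixed seed, and identical inputs yield
identical labels.

Cluster occupancies include noise in the denominator (reported as its own
gray bar); medoids minimize summed feature-space distance within their
cluster and are exported as structure files. `localize_clusters` ties the
two halves of the package together: each chain's atoms are assigned to its
row's cluster and profiled against the intrinsic interface, showing where
in the micelle each conformational family lives.

## The synthetic generator: what it emulates, and what it does not

The generator plants everything the analyses are supposed to measure:
aggregate membership (micelles on a grid with a guaranteed minimum-image
center separation), a core of declared radius with EO corona, three
conformational families parameterized by MA- and EO-block extension
fractions (collapsed-MA/extended-EO, intermediate, extended-MA/compact-EO)
at declared proportions, end-out chains, exact hydration-shell water counts
around chosen carbonyls, and a stationarity changepoint (chains that start
dissociated and merge at a declared frame).

Design choices worth knowing:

* **Family templates are deterministic** (a fixed gentle helix of tangential
  offsets for linear chains, a closed ellipse for rings). Within-family
  variation therefore comes from declared noise only. The recommended
  trajectory recipe keeps frozen structural noise small (0.1 Å) and
  per-frame thermal jitter large (0.5 Å), so frame-to-frame conformational
  fluctuation — not per-chain identity — dominates, as in an equilibrated
  trajectory. With the defaults, inter-family template distances exceed
  five times the within-family spread, which is what makes exact
  three-cluster recovery the *correct* answer rather than a lucky one.
* **Connectivity is enforced, not emergent.** A few dozen coarse chains are
  far sparser than an atomistic core, so after placement any disconnected
  chains are rigidly translated into contact (2.8 Å closest approach,
  enforced at a 3.6 Å criterion — safely inside the 4.5 Å analysis cutoff
  under default jitter). Rigid moves leave every conformational feature
  untouched.
* **Burn-in chains are chosen removable**: dissociated chains are peeled
  from the leaves of a distance-weighted spanning tree of the contact
  graph, so the remaining micelle stays connected in the pre-merge phase
  and the planted changepoint is clean.
* **No physics.** There are no energies, no solvent dynamics, and no claim
  that absolute density magnitudes match atomistic systems. Passing the
  recovery tests shows the *analyses* are correct on data with known
  answers; it does not validate force fields, sampling, or any simulation.
  Real trajectories add disorder the generator does not emulate —
  conformational exchange within chains, interface fluctuations with
  realistic spectra, exchanging unimers — which is why every threshold the
  analyses depend on is exposed configuration, not hard-coded.

Problem sizes in the bundled demo and validation runs — 20 chains, 200
frames, a bulk hydration shell of order 10³ waters, 512 angular cells,
2e4-1e5 Monte-Carlo volume samples — were chosen as the smallest systems on
which every planted structure is comfortably resolvable; all scale up
linearly in frames and near-quadratically in chains.

## Numerical choices and degenerate inputs

Seeds flow from one master seed through named sub-streams
(`derive_seed(seed, "stage")`), so any stage re-run in isolation reproduces
its in-pipeline output, and the run manifest records the seed, the full
config snapshot, and an MD5 checksum of every output file; identical config
and seed reproduce bit-identical outputs. Ties and degeneracies: aggregate
labels are canonicalized by lowest member id; embedding eigenvector signs
are fixed deterministically; duplicate feature rows get finite
density-lambdas via a floored merge height; empty clusters, empty frames,
all-noise clusterings, absent crossovers, and non-star-convex aggregates
all raise or warn rather than returning silent zeros. GRO files are written
at 5 decimals (nm) so a write/read round trip stays within 1e-3 Å;
trajectory input formats are DCD, multi-model PDB, and multi-frame GRO.

## Known limitations

Orthorhombic boxes only; star-convex aggregates only (by guard); no
kinetics (fusion/fission, exchange, cluster transitions); distance-only
hydration shells (no hydrogen-bond geometry); the conformational feature
set is the pluggable default described above, not a reconstruction of any
particular published feature list; and the two-dimensional embedding is a
visualization-faithful neighbor-graph method, not a drop-in reimplementation
of any specific library.

## A minimal session

```{r example, eval = FALSE}
library(micelletools)

dm <- demo_micelle_trajectory(build_polymer_spec("diblock"),
                              n_polymers = 20, n_frames = 200,
                              water = TRUE, seed = 1)
nd <- nagg_distribution(dm$ensemble)
sh <- shape_of_aggregate(dm$ensemble)
land <- conformation_landscape(dm$ensemble, seed = 42)
loc <- localize_clusters(land, dm$ensemble, frames = 1)

print(nd); print(sh); print(land)

# or, config-driven with a manifest:
m <- run_pipeline(default_config(), output_dir = "micelle_run")
```
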