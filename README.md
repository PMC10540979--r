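# micelletools

Trajectory analysis for block-copolymer micelle self-assembly.

Amphiphilic block copolymers of poly(methyl acrylate) (MA, hydrophobic) and
poly(ethylene oxide) (EO, hydrophilic) self-assemble in water into micelles
with an MA-rich core and a hydrated EO corona. At fixed composition, the
chain architecture — linear diblock (MA₁₂EO₃₀), MA-terminated triblock
(MA₆EO₃₁MA₆), EO-terminated triblock (EO₁₅MA₁₂EO₁₅), or ring (cyclic
MA₁₂EO₃₁) — controls micelle size, shape, internal structure, and the
conformations individual chains adopt. `micelletools` provides the
analysis stages needed to quantify those effects from MD trajectories, for
polymer physicists and simulators who have trajectories and want numbers:

* **Topology model** — monomer→atom maps, carbonyl oxygens, and
  chemically-equivalent monomer classes (triblocks and rings pool their 12
  MA monomers into classes MA1..MA6; the diblock has no equivalent pairs).
* **I/O** — GRO/PDB structures; DCD, multi-model PDB or multi-frame GRO
  trajectories; YAML polymer specs; CSV outputs and a JSON run manifest.
* **Aggregates** — single-linkage micelle identification (heavy-atom
  minimum-image cutoff, default 4.5 Å), PBC-consistent unwrapping,
  aggregation-number distributions *P(N_agg)* (polymer-weighted and
  unweighted), burn-in/stationarity detection.
* **Shape** — mass-weighted gyration tensor: *R_G* = √tr S, eccentricity
  *ε* = 1 − *I*_min/*I*_avg from the principal moments of inertia
  (0 for a sphere).
* **Internal structure** — component-resolved radial density profiles
  (g/cm³), core composition and hydration, per-class intermolecular MA
  contacts, carbonyl-oxygen hydration-shell coordination numbers (3.5 Å
  first-shell convention).
* **Intrinsic core–shell interface** — an equal-area angular map of the
  interface radius around each micelle; signed intrinsic distances
  *d_I* (< 0 in the core), intrinsic density profiles with Monte-Carlo
  shell volumes, and interface area per polymer.
* **Conformational landscape** — rigid-motion-invariant features per
  (polymer, frame), a neighbor-graph 2-D embedding, hierarchical
  density-based clustering with noise, cluster occupancies, medoid
  structures, and intrinsic localization of each conformational family.
* **Synthetic micelles** — a generator that plants every quantity the
  analyses measure (membership, families, interface radius, hydration
  counts, end-out chains, a burn-in changepoint), so the whole pipeline is
  validated by planted-truth recovery.

## Worked example

Generate the bundled reference system — one diblock micelle of 20 chains
drawn from three planted conformational families at 50/30/20%, with a bulk
hydration shell — and analyse it:

```r
library(micelletools)

dm <- demo_micelle_trajectory(build_polymer_spec("diblock"), n_polymers = 20,
                              n_frames = 60, water = TRUE, seed = 1)

nagg_distribution(dm$ensemble)
#> <aggregate_assignment> 60 frame(s), cutoff 4.50 A
#>   largest aggregate N_agg = 20.00 +/- 0.00
#>   polymer-weighted P(N_agg):
#> 20
#>  1

shape_of_aggregate(dm$ensemble)
#> <shape_metrics> 60 frame(s)
#>   R_G = 25.04 +/- 0.01 A
#>   eccentricity = 0.078 +/- 0.001
#>   N_agg = 20.0 +/- 0.0

conformation_landscape(dm$ensemble, seed = 42)
#> <conformation_landscape> 1200 rows, 3 cluster(s), noise 0.0%
#>   occupancy (%):
#> cluster1 cluster2 cluster3    noise
#>       50       30       20        0

surf <- build_surface(dm$ensemble, frame = 1)
area_per_polymer(surf, 20)
#> [1] 173.3
```

Reading the output: all 20 chains sit in one micelle in every frame
(*P*(20) = 1), the aggregate is approximately spherical (*ε* ≈ 0.08) with
*R_G* ≈ 25 Å, the clustering recovers exactly the three planted
conformational families at their planted 50/30/20% occupancies with no
noise, and the core–shell interface allots ≈ 173 Å² of interface area per
chain. On real trajectories the same calls apply after
`load_ensemble(structure, trajectory, spec_config)`.

The config-driven runner executes every stage and writes CSVs plus a
manifest (config snapshot, seed, per-file MD5 checksums; identical config +
seed reproduce bit-identical outputs):

```r
m <- run_pipeline(default_config(), output_dir = "micelle_run")
```

A thin CLI wrapper lives at `inst/scripts/micelletools-cli.R`
(`run`, `synth`, `config --describe`).

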