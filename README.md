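# porelock

Open-state pore restraints and trajectory annotation for pentameric
ligand-gated ion channels (pLGICs).

## The problem

Putative open-state structures of pLGICs — glycine receptors, nicotinic
acetylcholine receptors, GABA-A receptors and their relatives — tend to
undergo a *hydrophobic collapse* in unrestrained molecular dynamics: the
ring of hydrophobic residues at the 9′ position of the pore-lining M2
helices caves in toward the pore axis and the channel dehydrates and shuts.
A practical remedy during equilibration is to restrain the *cross-pore
distances*: for each pore-lining position, the Cα–Cα distances between
non-adjacent subunits are given a lower-side flat-bottom potential that is
zero at or beyond the distance in the open-state reference structure and
harmonic below it,

```
V(d) = ½ k (d0 − d)²   for d < d0,     V(d) = 0   for d ≥ d0
```

with `d0` the reference Cα–Cα cross distance and `k = 5000 kJ mol⁻¹ nm⁻²`
(so the restoring force is proportional to the distance difference,
500 kJ mol⁻¹ nm⁻¹ at 0.1 nm inside the boundary). A pentamer has five
non-adjacent ("diagonal") subunit pairs, so with the seven standard primed
positions −2′, 2′, 6′, 9′, 13′, 16′, 20′ the generator emits
7 × 5 = 35 restraints. The channel is never simulated by this package; it
*emits* the restraint topology fragments, the staged position-restraint
equilibration schedule (7 stages, force constants
1000/1000/1024/512/256/128/64), and ligand-tether definitions, and it
*annotates* the trajectories produced elsewhere:

- **Pore radius profiles** (HOLE-style): at each axial coordinate `s`
  (9′ ring at `s = 0`, extracellular positive), the largest probe sphere
  that fits in the lumen, `max_c min_i (|c − x_i| − r_vdW,i)`.
- **Hydrophobicity profiles**: Wimley–White interface scale linearly
  rescaled to [−1, 1] (−1 very hydrophilic, +1 very hydrophobic),
  Gaussian-averaged over pore-facing residues.
- **Permeation counting**: a three-compartment state machine
  (below/inside/above the pore, within a 5 Å cylinder of the channel axis)
  counts complete traversals per species and reports anion:cation
  selectivity.
- **Wetting**: per-frame, per-axial-bin water occupancy and dewetted
  stretches.
- **Number densities**: time-averaged 3D grids in particles/nm³ with
  OpenDX export.
- **Conformational metrics**: per-residue Cα RMSF, burial of the 9′
  side chain in its inter-subunit hydrophobic pocket, pairing/asymmetry of
  the −2′ proline ring, representative-frame selection.

A synthetic fixture generator builds idealized 5-fold-symmetric pores and
scripted particle trajectories with known ground truth, so every analysis
is testable without any external data.

## Worked example

```r
library(porelock)

model <- build_toy_pentamer()            # idealized open-state pentamer
rs    <- build_pore_restraints(model, k = 5000)
head(rs[, c("position", "chain_i", "chain_j", "d0", "k", "side")], 3)
#>   position chain_i chain_j       d0    k  side
#> 1       -2       A       C 11.41268 5000 lower
#> 2       -2       B       D 11.41268 5000 lower
#> 3       -2       C       E 11.41268 5000 lower
nrow(rs)
#> [1] 35

fx  <- build_trajectory(trajectory_spec(traversals = c(CL = 52, `NA` = 1),
                                        n_frames = 300, seed = 1), model)
tr  <- axial_traces(fx$traj,
                    select_atoms(fx$traj, resid = c("CL", "NA")),
                    model$axis, fx$cylinder)
count_permeations(tr)
#> permeation events over 300 frames:
#>   CL     52
#>   NA     1
```

The 35 rows are the five pentagon diagonals at each of the seven primed
positions; `d0` is the open-state reference Cα–Cα distance in Å (emitted in
nm in the GROMACS fragment, `write_restraints_itp()`). The permeation
record recovers exactly the 52 chloride and 1 sodium traversals scripted
into the fixture, and `selectivity_ratio()` reports the 52:1 anion
selectivity.

A command-line wrapper is installed at `inst/scripts/porelock`
(subcommands `restraints`, `schedule`, `profile`, `permeation`, `density`,
`rmsf`, `pockets`, `prolines`, `repframe`, `simulate-fixture`).

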