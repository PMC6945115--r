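---
title: "Pore restraints and trajectory annotation for pentameric channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pore restraints and trajectory annotation for pentameric channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porelock)
```

## Scope and model

porelock addresses a specific failure mode of molecular dynamics
simulations of pentameric ligand-gated ion channels: putative open-state
structures collapse at the hydrophobic 9′ gate once positional restraints
are released. The package generates the *cross-pore flat-bottom
restraints* and the *staged equilibration schedule* that hold the pore
open while letting the protein relax, and it annotates the resulting
trajectories (pore geometry, hydration, permeation, conformational
signatures). It deliberately does **not** run any dynamics: force fields,
thermostats, barostats and integrators are the simulation engine's
business; porelock only emits restraint/schedule files and consumes
coordinates.

### Coordinate system

Everything is expressed in an axial coordinate `s` along the channel axis,
in Å, with the centroid of the five 9′ Cα atoms at `s = 0` and the
extracellular side positive (the 20′ ring at `s > 0`). Two axis
definitions are offered, because channel structures do not carry one:

- `ring_centroids` (default): the best-fit line through the seven
  per-ring centroids of the pore-lining Cα atoms. This is robust to an
  asymmetric extracellular domain, because only pore-lining atoms vote.
- `principal`: the smallest-moment principal axis of all 35 pore-lining
  Cα atoms, for cases where individual rings are too distorted for
  centroid fitting.

Both are explicit, documented stand-ins for whatever internal definition a
given pore-profiling program uses; axial coordinates are invariant under
rigid-body motion of the whole system (tested property).

Primed positions follow the standard M2 numbering: primed index `p` maps
to residue `m2_start + p + 2`, so for the human α1 glycine receptor
(`m2_start = 250`) the 9′ gate leucine is residue 261. The rotational
order of subunits is fixed by the angle of the 9′ Cα atoms about the axis
and stored explicitly, which makes "non-adjacent subunits" well defined
regardless of chain labels.

## Restraints

For each primed position the five diagonal subunit pairs `(i, i+2)` in
rotational order receive one lower-side flat-bottom restraint
`V(d) = ½k(d0 − d)²` for `d < d0`, zero otherwise, with `d0` the Cα–Cα
distance in the open-state reference structure. Design notes:

- **Force-constant unit.** The restraint literature sometimes prints
  flat-bottom force constants as kJ mol⁻¹ nm⁻¹ ("force proportional to the
  distance difference"). A harmonic potential dimensionally requires
  kJ mol⁻¹ nm⁻², and that is what porelock stores; with `k = 5000` the
  force 0.1 nm inside the boundary is 500 kJ mol⁻¹ nm⁻¹ and the energy
  25 kJ mol⁻¹.
- **½k convention.** The half-harmonic is taken as `½k(Δd)²` (the GROMACS
  type-10 restraint convention), not `k(Δd)²`. Energies are C¹-continuous
  at `d0` (tested).
- **Emission.** GROMACS `[ bonds ]` function-type-10 lines encode the
  lower-side flat bottom as `low = d0`, `up1 = up2` far away; distances in
  nm at 4 decimals, internal Å kept exact. The emitted files round-trip
  through the package's own reader (tested).
- **Ligand tethers** are the mirror image (upper-side): zero inside a
  threshold distance between ligand Cα and binding-site anchor Cα,
  harmonic beyond. Defaults carry the glycine-receptor thresholds
  10.60 / 10.53 / 9.15 Å to the (+)F207, (−)F63 and (−)S129 Cα atoms.

The seven-stage schedule (100 ps NVT then six NPT stages; restrained
selection relaxing from all heavy atoms to backbone; force constants
1000, 1000, 1024, 512, 256, 128, 64) is emitted as per-stage mdp and
position-restraint fragments plus an indexed table, which is what the
reader parses back.

## Pore radius profiles

At each grid point `s` the pore radius is the clearance of the largest
probe sphere centered in the slice plane:
`max_c min_i (|c − x_i| − r_vdW,i)` over in-plane centers `c`. The
maximization is deliberately **local**: a deterministic hill climb on a
1 Å lattice starting from the axis point, refined by Nelder–Mead, confined
to an 8 Å lateral search box. A global maximum would be wrong — outside
the protein wall the clearance grows without bound, so the probe must
track the lumen basin connected to the axis. Ties break toward the axis
by strict-improvement stepping. Defaults: s grid −40…+40 Å in 0.5 Å
steps, radius cap 10 Å (open bulk), Bondi van der Waals radii. All
defaults are arguments.

Reference radii for dehydrated (1.81 Å) and hydrated (≈3.3 Å) chloride
are shipped as clearly labelled external literature constants
(`chloride_reference_radii()`), not results of this package.

Per-frame profiles aggregate to pointwise mean and sample SD
(`profile_statistics()`), with optional subsampling to `n` equally spaced
frames (e.g. 300 points over a 300 ns run). `classify_gate_geometry()`
reports minimal radii around the 9′ and −2′ gates and flags
hydrophobic-gating risk when the 9′ constriction is below 4 Å (the lower
edge of the ≈4–5 Å local-dehydration regime reported for hydrophobic
pores) *and* the local surface is hydrophobic.

## Hydrophobicity profiles

Residues carry the Wimley–White interface scale (water → POPC interface
transfer free energies) linearly rescaled so Trp (most hydrophobic) → +1
and Glu (most hydrophilic) → −1. The printed convention is −1 = very
hydrophilic, +1 = very hydrophobic; note that on the raw free-energy
scale hydrophobic residues are the *minimum*, so the rescaling flips
sign. A residue is pore-facing at `s` when any heavy atom lies within
`facing_cutoff` (default 4 Å) of the local pore surface (the sphere of
the local radius around the local probe center); the profile is the
Gaussian-weighted average (σ default 2 Å along `s`) of facing residues'
values. Weighted averages of values in [−1, 1] stay in [−1, 1] for any
input (tested property).

## Permeation counting

Particles (water by its oxygen, monatomic ions by their atom) are tracked
in a cylinder of radius 5 Å around the axis between `z_lo` and `z_hi`,
which default to the −2′ and 20′ ring centroids of the reference
structure and are kept **fixed** across frames so the compartment state
machine is well defined. Per particle and frame the compartment is below
(`s < z_lo`), inside, or above (`s > z_hi`); an event is a completed
below→inside→above traversal (direction +1) or the reverse (−1) with all
inside frames within the cylinder. Choices made where the physics leaves
room:

- Excursions outside the 5 Å cylinder while axially inside void the
  traversal by default (`tol_frames = 0`); a tolerance is configurable
  because sampling-rate artifacts can briefly push a permeating ion past
  the nominal radius.
- A direct below→above jump between consecutive frames counts as a
  traversal. This keeps counts invariant under stride coarsening of
  monotone paths and preserves the balance identity
  (#up − #down = net compartment displacement, tested against a
  brute-force re-scan).
- Directions are pooled in totals; with no membrane potential there is no
  preferred direction.
- Periodic unwrapping along the axis uses minimum-image displacements
  between consecutive frames, anchored by the minimum image of the first
  frame about the axis origin. Sampling must satisfy |Δs| < L_z/2 per
  frame.

`selectivity_ratio()` returns anion/cation event counts with `Inf`
(flagged) when no cation event occurred, and an undefined flag at 0/0.
Wetting is per-axial-bin water presence inside the cylinder; a bin with
zero water oxygens at a frame is dewetted, and maximal contiguous
dewetted runs are reported per frame. Densities are time-averaged voxel
counts divided by voxel volume (particles/nm³), and the grid integral
equals the mean in-grid particle count to numerical precision (tested).

## Conformational metrics

- **RMSF**: frames are superposed by least squares (Kabsch, via bio3d)
  over the Cα selection onto a reference frame; RMSF is the root mean
  square deviation from the time-average position. For isotropic Gaussian
  jitter of σ per coordinate the expectation is σ√3; the test suite
  checks convergence within 5% at 2000 frames.
- **Pocket burial**: the number of pocket heavy atoms within 4.5 Å of any
  probe side-chain heavy atom, with ≥10 contacts classified "buried" and
  0 "vacated". The thresholds are operational definitions — the
  underlying observation is qualitative — so raw scores and minimal
  distances are always reported alongside the class.
- **Proline pairing**: side-chain centroids of the five −2′ residues form
  a contact graph (edge below 6 Å); greedy minimum-distance matching
  partitions the ring into pairs and singletons (the partition always
  covers all five, tested). Asymmetry is flagged when the coefficient of
  variation of centroid–axis distances exceeds 0.1 or any pair formed.
- **Representative frame**: the frame with minimal Cα RMSD to the
  time-average structure after superposition, earliest frame on ties
  (ties are resolved within 1e-9 Å to avoid floating-point order
  sensitivity).

## The synthetic fixture generator

`build_toy_pentamer()` produces an exactly 5-fold-symmetric "channel":
five straight M2-like chains whose Cα atoms sit at prescribed ring radii
per primed position (linearly interpolated between rings), a side-chain
centroid atom 1.4 Å inside the Cα radius, and extra wall carbons filling
each subunit's angular sector so the wall is sterically tight. Default
ring radii describe an open-like pore; residue identities default to a
glycine-receptor-like lining (Pro at −2′, Leu at 9′, Thr at 6′).
`build_trajectory()` scripts particle paths: each prescribed traversal is
a monotone axial sweep through the cylinder by a dedicated particle with
lateral jitter kept strictly inside the cylinder radius; distractors
enter and turn back; fill water is static; optional emission wraps z into
[0, L_z) to exercise unwrapping. The scripted event log is the ground
truth that the permeation counter must reproduce exactly (tested over
100 seeds).

What the fixtures do **not** emulate: thermal water structure, realistic
ion kinetics, side-chain rotamers, membrane and solvent atoms, forces of
any kind. Passing tests therefore demonstrate the correctness of the
geometry and counting machinery, not the physical realism of any
simulation; on real trajectories the permeation counts remain sensitive
to the pore-bound and cylinder definitions, which is why those are
explicit parameters rather than constants.

## Problem sizes and numerical choices

The test suite and the acceptance script run on fixtures of a few hundred
atoms and 40–300 frames (2000 frames for the RMSF convergence check),
which keeps the full suite under half a minute on one CPU while still
exercising every code path, including the 100-seed permeation property.
Probe-center optimization uses reltol 1e-12 with at most 500 simplex
iterations; the lattice hill climb is capped at 4× the search range.
Degenerate inputs (empty selections, non-pentamers, missing residues,
zero-size voxels, truncated files) raise errors naming the offending
entity rather than propagating NaN.

## Known limitations

- Trajectory input is multi-model PDB (plus single-frame GRO topologies);
  compressed binary trajectory formats should be converted upstream
  (e.g. `mdconvert`/`gmx trjconv` to multi-model PDB) before annotation.
- Pore profiles are slice-wise spherical-probe clearances; no surface
  triangulation or volume meshing is attempted, and agreement with other
  pore-profiling programs is qualitative since probe and smoothing
  parameters differ between implementations.
- The permeation state machine assumes the channel axis is fixed over the
  trajectory (the protein is expected to be centered/fitted upstream).
- Hydrophobicity requires every residue name in the scale table; modified
  residues need user-supplied entries.
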