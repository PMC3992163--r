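---
title: "Local average distance profiles: model, parameters and design choices"
author: "ladflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local average distance profiles: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladflex)
```

## The problem and the descriptor

Rigid-body structure comparison fails on proteins that undergo large
conformational changes: two conformers of the same chain related by a hinge
bend can have a coordinate RMSD of tens of Angstrom while remaining, to a
biologist, the same protein. The local average distance (LAD) descriptor
addresses this by characterizing each residue only through its *sequence
neighbourhood*: global rearrangements that keep each side of a hinge rigid
barely perturb the descriptor.

The pipeline is:

1. **Backbone extraction.** A chain is reduced to its backbone atoms
   (N, CA, C, O); side chains are ignored so the surface reflects the fold,
   not rotamer states.
2. **Surface meshing.** A closed triangulated surface is built over the
   probe-inflated van der Waals spheres of the backbone atoms
   (`buildSurface()`), then reduced to ~15% of its faces by quadric edge
   collapse (`simplifyMesh()`). Each mesh vertex is assigned to its nearest
   backbone atom (`associateVertices()`); a residue with at least one
   assigned vertex is a *surface residue*.
3. **Averaged residue distances.** For two atoms with M and N associated
   vertices, the geodesic distance is the mean of all M x N vertex-pair
   shortest paths along the surface; residue-level distances average over
   the associated atom pairs (`residueDistanceMatrix()`). The Euclidean
   variant (ED) uses atom-center distances over the *same* atom set, so the
   two metrics are computed over identical residues and stay comparable.
4. **Profile construction.** A sliding window (default 9 residues) converts
   the matrix into one LAD value per surface residue: the mean distance to
   the up-to-8 window neighbours (`buildLADProfile()`). Windows truncate at
   the termini rather than pad — padding would fabricate distances.
5. **Comparison.** Two profiles are aligned by a Smith–Waterman local
   alignment whose substitution score decreases linearly with the absolute
   LAD difference (`alignProfiles()`), and the pair is scored by

   $$LAD_{div} = 1 - \frac{N_e}{\mathrm{mean}(N_Q, N_S)}\cdot
     \frac{1}{1 + (RMSD/D)^{\alpha}} \in [0, 1],$$

   where $N_e$ is the number of aligned residues and $RMSD$ is the RMSD of
   the aligned *LAD values* (Angstrom) — deliberately not a coordinate RMSD.
   Lower means more similar. `structDiv()` provides the companion
   coverage-weighted coordinate-RMSD score
   $RMSD / (N_e/\mathrm{mean}(N_Q,N_S))^{1.5}$ for statistics coming from
   external coordinate aligners; the two RMSDs must not be conflated.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window` | 9 | residues | best-performing odd width in the 3–21 sweep on training data; `ladWindowSweep()` re-runs the sweep |
| `probe_radius` | 1.5 | Å | water-sized probe, the molecular-surface convention |
| `grid_resolution` | 0.7 | Å | isosurface sampling step; smaller is more faithful and slower |
| `face_fraction` | 0.15 | — | keep ~15% of faces, the usual ~85% reduction before geodesics |
| `(D, alpha)` ED | (1, 4.5) | Å, — | grid-search optimum on labeled training pairs |
| `(D, alpha)` GD | (1.1, 5) | Å, — | ditto, for geodesic profiles |
| `s_max`, `m0`, `gap` | 1.0, 1.0 Å, 0.5 | — | alignment scoring; see below |

Van der Waals radii are fixed at N 1.55, C 1.70, O 1.52 Å.

The exact functional form of the alignment score is not uniquely determined
by "inversely proportional to the absolute LAD difference"; we use the
affine form $\sigma(i,j) = s_{max} - |LAD_i - LAD_j|/m_0$ with a linear gap
penalty, which keeps dynamic-programming optimality transparent and lets an
exhaustive-enumeration oracle verify the DP exactly (the test suite does
this for all profile pairs of length ≤ 6). All three constants are exposed.
A consequence worth knowing: published $LAD_{div}$ values can only be
matched approximately except where $N_e \approx \mathrm{mean}(N_Q,N_S)$,
because the original gap model is not recoverable. Consistently, the ED
worked pair (RMSD 0.173, $LAD_{div}$ 0.0004) reproduces exactly at full
coverage, while the GD pair (0.454, 0.02) implies coverage ≈ 0.99.

## Numerical and design choices

**Mesh backend.** The surface is the zero level of the distance field to
the union of probe-inflated atom spheres, sampled on a regular grid and
extracted by marching *tetrahedra* (each grid cube split into six
tetrahedra around its main diagonal). The tetrahedral case table is tiny,
unambiguous, and produces a watertight, conforming triangulation —
properties the geodesic step depends on. Meshes from MSMS can be imported
verbatim (`importMSMS()`) when strict fidelity to that program is wanted;
the built-in backend exists so that nothing in the package requires an
external binary.

**Geodesics.** Vertex-to-vertex distances are Dijkstra shortest paths on
the mesh edge graph *augmented with unfolding edges*: for every interior
edge the two flanking triangles are unfolded into a plane and the opposite
vertices joined whenever the straight unfolded segment crosses the shared
edge. Every such edge corresponds to a genuine on-surface path, so the
result remains an upper bound on the exact polyhedral geodesic, while the
metrication error drops dramatically (antipodal error on a subdivided
icosphere: ~0.04% augmented vs ~6% plain). Distances between mesh
components are reported as `NA`, never as silent infinities.

**Simplification.** Quadric edge collapse with area-weighted plane
quadrics, the standard optimal-position solve (guarded against
near-singular quadrics), and a normal-flip rejection test. On a unit
icosphere reduced from 1280 to 192 faces the vertex-sampled Hausdorff
distance to the original is ~0.03 radii.

**Window space.** The window slides over *surface-residue positions*:
buried residues are skipped, not treated as gaps, keeping profiles dense
and alignable. Residues with some backbone atoms buried contribute only
their vertex-associated atoms to the averages.

**Ties.** Vertex-to-atom association breaks distance ties by residue
order, then by N < CA < C < O; DP traceback prefers diagonal, then up,
then left; retrieval rankings break score ties lexicographically by
subject id. All outputs are deterministic.

**Degenerate inputs.** Chains missing from a PDB file, chains with zero
backbone atoms, single-residue distance matrices (no neighbours to
average), empty profiles, `face_fraction` values that would collapse a
mesh below 4 faces, and atoms without associated vertices in geodesic
averaging all raise explicit errors. An alignment in which no residue pair
scores positively returns $N_e = 0$, $LAD_{div} = 1$ rather than erroring.
Altloc records resolve to the highest occupancy (ties: first altloc
letter); only the first MODEL of multi-model files is read.

## What the synthetic generators emulate

Real morph databases contain groups of conformers of one protein spanning
a hinge motion. The generators mirror that at desk scale:

* `makeToyChain()` builds ideal backbones (helix / extended / zigzag) with
  exactly 3.8 Å consecutive CA spacing (the helix radius is solved from
  the rise and twist so the spacing is exact).
* `applyHingeBend()` rotates everything past a hinge residue rigidly about
  an axis through the hinge CA — the idealization of a hinge motion, with
  each side exactly rigid.
* `makeMorphGroup()` interpolates the bend linearly across frames and adds
  0.05 Å Gaussian coordinate jitter, small against the 3.8 Å backbone
  scale but enough to break exact self-identity, standing in for
  interpolated morph frames. 1–3 hinges are supported, matching the
  prevalence of few-hinge morphs in real data.
* `makeDefaultBenchmark()` assembles 5 groups x 10 frames with distinct
  geometries and lengths (30–100 residues), a reduced-scale analogue of a
  morph database; frame 1 of each group is the representative.
* `makeLabeledPairs()` draws alignment statistics directly (positives:
  RMSD ~ |N(0.3, 0.1)|, coverage ~ Beta(8, 2); negatives: |N(2.0, 0.5)|,
  Beta(2, 5)) to emulate the homologous/non-homologous training sets used
  to fit `(D, alpha)`. Positive pairs share a profile length — conformers
  of one protein — so the coverage distribution survives the clamp of
  $N_e$ to the shorter profile; negatives draw lengths independently.

What the toy data do **not** emulate: side chains, sequence-dependent
radii, buried cores of globular folds, non-rigid (shear, loop) motions,
and the surface self-contacts of real domain swaps. Passing tests on the
synthetic benchmark therefore demonstrate the hinge-invariance mechanism
and the correctness of every pipeline stage, not retrieval performance on
real morph databases, which requires the external datasets.

Problem sizes used by the test-suite benchmark — 50 structures of 30–100
residues, meshed at 0.7 Å and compared with the ED metric — were chosen so
the whole pipeline runs end-to-end in well under five minutes on a single
CPU while still exercising every module.

## The hinge-invariance property, made precise

For a chain bent rigidly at a hinge, with the surface-residue set held
fixed, the ED-based LAD value of any residue whose entire window lies on
one side of the hinge is *identical* between conformers (all pairwise
distances inside a rigid side are preserved exactly); only residues whose
window straddles the hinge can change. The test suite verifies this to
1e-9 Å on a 60-residue helix bent 90 degrees, and verifies at the pipeline
level that the bent pair scores $LAD_{div} < 0.05$ while a
different-geometry chain of equal length scores $> 0.5$. Geodesic profiles
are only approximately hinge-invariant: bending changes which surface
paths exist (the self-connection effect), which is why the ED variant is
the more robust default.

## Known limitations

* The built-in surface is a probe-inflated union-of-spheres isosurface,
  not an exact solvent-excluded surface; geodesic values differ slightly
  from MSMS-derived meshes (import those for fidelity).
* Graph geodesics are upper bounds; after simplification the residual
  overestimate is below meshing noise, but exact polyhedral solvers would
  differ in the third decimal.
* `structDiv()` consumes externally supplied alignment statistics; the
  package deliberately does not superpose coordinates.
* Multi-chain complexes are compared one chain at a time.
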