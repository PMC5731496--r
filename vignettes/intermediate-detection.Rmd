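---
title: "Detecting intermediate conformations by persistent homology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intermediate conformations by persistent homology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathtopo)
```

# The problem and the model

Proteins that switch between two stable states pass through transient
intermediate conformations that are hard to observe experimentally. In a
sampled conformational ensemble these intermediates appear as densely
populated, well-separated regions. `pathtopo` detects them in four stages:
a coarse-grained biased Monte-Carlo search between the two endpoints, a
non-linear projection of the 3N-dimensional conformation vectors to three
coordinates, a persistent-homology analysis of the projected cloud over a
landmark subset, and a barcode-driven hierarchical clustering with
per-cluster RMSD statistics against the endpoints.

The package assumes throughout that a Cα trace is an adequate coarse
description of the protein (one pseudo-atom per residue, virtual bonds of
about 3.8 Å), that conformational change is dominated by pseudo-dihedral
rotations about virtual Cα–Cα bonds, and that RMSD after optimal
(Kabsch) superposition is the relevant metric between conformations.

## Conformational search

Starting from the pool `{start}`, each iteration

1. draws a parent conformation from the pool (uniformly by default);
2. selects a rotatable virtual bond with probability proportional to the
   circular difference `|Δangle| ∈ [0°, 180°]` between the parent's
   pseudo-dihedral and the goal's, skipping angles within
   `skip_angle_tolerance` — this is the bias toward the goal;
3. rotates the C-terminal side by a uniform draw within
   `± rotation_limit` degrees;
4. discards the proposal unless its coarse energy is below
   `energy_threshold`;
5. accepts if `RMSD_new < RMSD_parent`, or if
   `ln r < −(RMSD_new − RMSD_parent)/(a · RMSD_new)` with `r ~ U(0,1)` —
   a Metropolis-type rule whose uphill tolerance is scale-free in the
   RMSD and controlled by `a`.

Accepted conformations join the pool with a parent link, so the result is
a tree-structured pathway rooted at the start.

Several aspects of this scheme admit more than one reading, and the
package fixes them as follows. The draw `r` is a uniform Metropolis draw
(a Boltzmann-weight reading is possible but not implemented). RMSDs in
the acceptance rule are superposed RMSDs, consistent with the rest of the
package. The tie `RMSD_new = RMSD_parent` falls through to the
logarithmic condition, which then accepts for any `r < 1`. A proposal at
exactly zero RMSD is the goal itself and is always accepted. Parent
selection is uniform over the pool by default because nothing in the
scheme requires a particular distribution; a goal-biased policy
(weights `1/(RMSD + 0.1 Å)`) and a greedy policy are provided for
steeper descent.

### The coarse energy

The published Cα potentials this stage would normally use are not
reproduced here; the energy is a pluggable interface
(`energy_fn` in `run_search()`) with a documented default:
a harmonic virtual-bond term about 3.8 Å plus a soft-sphere quadratic
repulsion below 4.0 Å between residues at least three apart. The default
is rigid-motion invariant and zero-bonded on an ideal chain, which is all
the filter needs: its job is to reject self-intersecting or stretched
chains, not to rank near-native states. `energy_threshold = NULL`
resolves at run time to `max(E(start), E(goal)) + 10`, a loose bound that
keeps both endpoints admissible while still rejecting hard clashes.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `max_iterations` | 60,000 | proposals | budget at which the reference transitions saturate; toys use 300–2,000 |
| `rotation_limit` | 5 | degrees | small enough that bond selection, not step size, drives progress |
| `scaling_factor_a` | 1.0 | — | neutral scale for the uphill tolerance; no published value exists |
| `skip_angle_tolerance` | 1 | degrees | "similar" angles are skipped; 1° is below any meaningful dihedral change |
| `goal_rmsd_stop` | 1.5 | Å | conventional convergence radius for Cα traces |

## Dimensionality reduction

Conformation vectors (3N coordinates, superposition *not* removed — the
sampler never translates or rotates the fixed side, so frames stay
comparable) are reduced to `d = 3` coordinates.

**Spherical PCA** projects every data vector onto the unit sphere and then
applies standard PCA. Normalization caps the leverage of any single
observation, which is what makes the method robust to outliers. Whether
rows should be mean-centered *before* the projection is genuinely open:
centering first removes the shared offset that otherwise dominates the
angular distribution (and matches the robust-PCA literature), while
normalizing raw rows makes the method reduce exactly to standard PCA on
data that is already unit-norm. The package centers first by default and
exposes `center_rows = FALSE` for the raw-row variant; the equivalence
tests use the latter, since the equivalence only holds there.

**Isomap** builds the union-symmetrized K-nearest-neighbour graph with the
*minimal K giving one connected component* (`minimal_connected_k()`), so
the neighbourhood size is determined by the data rather than chosen;
edges are weighted by Euclidean distance, all-pairs geodesics are exact
Dijkstra runs, and classical MDS of the geodesic matrix gives the
embedding. Explained-variance fractions are computed over positive MDS
eigenvalues only; a warning is raised if negative eigenvalue mass
dominates (strongly non-Euclidean geodesics). Unlike PCA's projection,
Isomap is an embedding and preserves the topology of the sampled
manifold, which is why it pairs naturally with the homology stage.

## Landmarks, witness filtration, barcodes

All topological computations run on a landmark subset `Z0` of the
embedded cloud `Z`, selected by the sequential **maxmin** scheme: first
landmark random (seeded), every next landmark maximizes its distance to
the chosen set (ties to the lowest index). Maxmin gives far better
coverage per landmark than random selection; the **coverage radius** `R`
is the largest distance from any cloud point to its nearest landmark.

The number of landmarks is chosen by coverage saturation: counts 10, 20,
30, … are scanned (one maxmin run per repetition — prefixes of a single
sequential run, since maxmin is greedy) and a repetition stops at the
first count where `R` improves by less than 5% relative to the previous
count; the reported count is `ceil(mean + 2·sd)` over five seeded
repetitions, capped at the cloud size. A previous `R` of exactly zero
counts as converged (nothing can improve). The 5% rule is scale-free, so
it stops early only when coverage genuinely collapses (duplicated or
atom-sharp clusters); on continuous 3D clouds it settles near
`R(n) ∝ n^{-1/3}` saturation, typically around a hundred landmarks.

The filtration is the **lazy witness** stream `LW^ν(Z, Z0, t)`: an edge
`{z0, z1}` appears at the smallest `t` such that some witness `y ∈ Z`
satisfies `max{d(y,z0), d(y,z1)} ≤ t + d(y)`, where `d(y)` is zero for
`ν = 0` and the distance from `y` to its ν-th closest landmark otherwise.
Per-edge appearance scales are computed once, exhaustively over all
witnesses, and clamped at zero; every scale-dependent question is then
answered from this precomputed stream. Higher simplices come from **flag
expansion** (every clique spans a simplex at the maximum of its edge
scales), which is exact for witness complexes because they are flag
complexes. `ν = 0` is the default for component detection; with
landmarks = cloud and `ν = 0` the witness graph's connectivity at every
scale coincides with the Rips graph's, which is why its H0 deaths equal
single-linkage merge heights exactly — the package's strongest internal
oracle, tested to 1e-9.

Degree-0 barcodes use union-find over edges sorted by appearance scale:
every landmark is born at 0; at each merge the younger component dies
(elder rule — with equal births the tie resolves by vertex order), and
each final component carries one infinite bar. Degree-1 barcodes use the
standard boundary-matrix reduction over the two-element field (the field
choice is free in theory; GF(2) is the convention and needs no
orientation bookkeeping). The reduction is deliberately dense and guarded
at ~2,000 simplices: it is an oracle-scale tool for validating fixtures
(unit square: one bar born 1, dying √2; 12-point circle: one long bar),
not a production persistence engine.

## From barcode to clusters

**Cluster count.** Finite H0 death scales are sorted in decreasing order;
the count is `1 +` the index of the **last gap larger than 0.1** between
consecutive scales, scanning at most the 20 largest (`max_levels`), and 1
if no gap qualifies. The intuition: bars above the last big gap are
persistent components (plus the one infinite bar); everything below is
the intra-cluster noise floor. Counting *every* gap would misread
symmetric data — three equal blobs produce two inter-blob merges within
less than 0.1 of each other, yet clearly form three clusters. The 0.1
threshold is retained as an absolute value in embedding units; because
the embedding scale is data-dependent the threshold is exposed as `gap`
and should be revisited if the reduced coordinates are rescaled.

**Levels.** The partition with exactly `i` components lives on the scale
interval between the `(L−i)`-th and `(L−i+1)`-th merge; the package takes
the midpoint of that plateau (the last merge scale for `i = 1`, where the
plateau is unbounded). Simultaneous merges can make a count unattainable,
in which case the nearest achievable partition is returned with a
warning. All levels are cut from one filtration with one landmark set, so
blocks at consecutive levels are nested *by construction* — the hierarchy
is laminar and `build_hierarchy()` treats any violation as an internal
error.

**Outliers.** Blocks smaller than `min_size` (default 2) at the selected
level are discarded. No published rule exists for this step; block size
is the natural criterion on a barcode, because an isolated landmark that
merges late produces exactly the long-bar signature a real cluster does,
while carrying no population.

**Report.** Per retained cluster: size, mean and *population* standard
deviation (the ± convention here is a choice; member-wise population sd
is used) of member RMSDs to each endpoint, and a representative — the
member closest to the cluster's geometric center in the reduced space
(a reduced-space medoid). Clusters are renumbered in increasing mean RMSD
to the designated (first) endpoint, so cluster 1 is nearest the start and
the numbering sweeps toward the goal.

# The synthetic generators

Three generators make every stage testable offline. `gaussian_blobs()`
(isotropic components on a regular simplex or rejection-placed centers)
exercises cluster-count recovery; the reference condition used in the
tests is 3 blobs × 50 points, separation 1, σ = 0.05 — separation 10×
the bar-gap threshold and 20× the component spread, the regime the
bar-gap rule is designed for. `circle_cloud()` (uniform angles, radial
noise) carries exactly one 1-cycle and validates the degree-1 pipeline.
`toy_chain_pair()` grows a self-avoiding Cα chain with exact 3.8 Å bonds
(clash threshold 4.0 Å between residues ≥ 3 apart, matching the default
energy) and perturbs it by random clash-free dihedral rotations (uniform
within ±90°, large enough that a handful of moves produce a genuine
rearrangement on a short chain). Because independent rotations can
cancel, the generator enforces a minimum endpoint separation of 2 Å —
above the sampler's 1.5 Å convergence radius — so a "transition" fixture
is never already converged; with zero perturbations the endpoints are
identical.

What these fixtures do *not* emulate: rugged realistic energy surfaces,
anisotropic cluster shapes, the strong density gradient a biased sampler
produces along a pathway, or the sheer dimensionality of real
conformation vectors. Passing tests therefore demonstrate the
correctness of the machinery and the recoverability of planted structure,
not that any particular protein's intermediates will form
barcode-separable clusters.

# Numerical choices and degenerate inputs

- Pairing two structures uses the intersection of residue numbers after
  chain selection; insertion codes are unsupported. Fewer than three
  shared residues cannot be superposed and error out.
- Alternate locations resolve to the highest occupancy (first on ties).
- Dihedrals follow the IUPAC right-hand convention, range (−180°, 180°];
  the C-terminal side of a bond moves, the N-terminal side is
  bit-identical after a rotation.
- Angle differences are wrapped to [0°, 180°] before use as selection
  weights.
- Maxmin ties (equidistant candidates) resolve to the lowest index;
  landmark selection is deterministic given the seed of its first pick.
- Witness appearance scales are clamped at zero (for ν = 1 the
  subtraction can go negative).
- Zero-norm rows make spherical PCA undefined and raise an error rather
  than being silently dropped; asking for more components than the rank
  truncates with a warning.
- All stochastic stages consume explicit integer seeds; a pipeline's
  master seed fans out by fixed offsets (sampling: seed; clustering:
  seed + 1), so identical seeds give byte-identical artifacts.

# Problem sizes

The test suite and the acceptance script run entirely on generated data
at desk scale: trajectories of 300–2,000 proposals on 8–12-residue
chains, clouds of 100–2,000 points, landmark sets up to ~220, degree-1
complexes up to 12 points. These sizes were chosen so that the whole
suite exercises every stage, including five-seed and twenty-seed
repetitions, in a few minutes; the defaults embedded in
`pipeline_config()` (60,000 iterations) reflect the regime the method
targets on real proteins.

# Known limitations

- The degree-1 engine is an oracle, not a tool for large complexes; the
  clustering path needs only degree 0, which scales comfortably.
- The bar-gap threshold is absolute in embedding units; embeddings with
  very different scales need a rescaled `gap`.
- The non-lazy witness stream, energy-level stratification of the
  conformational space, and homology above degree 1 are out of scope.
- The sampler explores by single-dihedral moves; concerted motions
  (hinge bending with correlated angles) are reachable but slow, and no
  temperature schedule or replica exchange is provided.
- K-means style baselines are intentionally absent; the package's value
  is the parameter-light topological route, and standard clustering is
  available elsewhere.
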