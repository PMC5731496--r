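# pathtopo

Detecting candidate **intermediate protein conformations** along a
large-scale conformational transition, using persistent homology.

Many proteins function through transitions between two stable states
(open/closed enzymes, chaperonin ring movements, calcium-sensor
rearrangements). The intermediate states along such transitions are
transient, rarely crystallized, and hard to observe; computationally they
show up as **densely populated regions** of the sampled conformational
space. `pathtopo` implements an end-to-end, parameter-light route from two
endpoint structures to a nested set of well-separated clusters of
intermediates:

1. **Biased Monte-Carlo search** over Cα pseudo-dihedrals. Each iteration
   picks a parent from the conformation pool, rotates one virtual Cα–Cα
   bond chosen with probability proportional to its angular distance from
   the goal (near-converged angles are skipped), filters by a
   coarse-grained Cα energy, and accepts by a Metropolis-type rule: accept
   if RMSD<sub>new</sub> < RMSD<sub>parent</sub>, or if

   ln *r* < −(RMSD<sub>new</sub> − RMSD<sub>parent</sub>) / (*a* · RMSD<sub>new</sub>),

   for a uniform draw *r* and scaling factor *a*.
2. **Non-linear dimensionality reduction** of the 3N-dimensional
   conformation vectors: spherical PCA (rows projected to the unit sphere
   before PCA, robust to outliers) or Isomap (geodesic distances over the
   minimal connected K-nearest-neighbour graph, then classical MDS).
3. **Topological clustering** in the reduced space: maxmin landmark
   selection with an automatic coverage-saturation stop; the lazy witness
   filtration over the landmarks; degree-0 persistence barcodes via
   union-find (degree-1 via boundary-matrix reduction over GF(2) at oracle
   scale); the number of clusters from the **bar-gap rule** (bars separated
   from the noise floor by a gap > 0.1 in merge scale); per-level landmark
   partitions, outlier pruning, and a laminar cluster hierarchy.
4. **Reporting**: per-cluster size, mean ± sd Cα RMSD (optimal
   superposition) to each endpoint, and a representative conformation per
   cluster, numbered in increasing RMSD from the designated endpoint.

## A worked example

The clustering core on a labelled synthetic cloud (three Gaussian blobs at
pairwise separation 1, σ = 0.05):

```r
library(pathtopo)

bl <- gaussian_blobs(3, 50, separation = 1, sigma = 0.05, seed = 2)
fit <- topo_cluster(bl$points, seed = 2)
summary(fit)
#> 150 points; 150 landmarks (R = 0), 150 retained after pruning
#> 3 clusters; sizes: 50, 50, 50
#> Largest merge scales: 0.777, 0.761, 0.0552, 0.0489, 0.0488, 0.047
```

The two inter-blob merges (0.777, 0.761) stand above the intra-blob noise
floor (≤ 0.055) by far more than the 0.1 bar-gap threshold, so the rule
reports 1 + 2 = 3 clusters, recovering the generator's labels exactly.
`plot(fit, type = "barcode")`, `plot(fit, type = "dendrogram")` and
`plot(fit, type = "scatter")` show the bars, the nested hierarchy, and the
coloured embedding.

The full pipeline on a self-contained toy transition (10-residue
self-avoiding Cα chain; goal generated by random dihedral perturbations):

```r
pair <- toy_chain_pair(10, 15, seed = 4)
kabsch_rmsd(pair$start, pair$goal)
#> [1] 2.573

cfg <- pipeline_config(pair$start, pair$goal, method = "sphpca",
                       max_iterations = 2000, out_dir = "toy_results",
                       seed = 17)
fit <- run_pipeline(cfg)
#> sampling: 2000 proposals, 1993 accepted (99.7%), best RMSD 2.227 A
#> embedding (sphpca): 1994 points, explained variance 0.639 0.296 0.040
#> landmarks: 117 (coverage R = 0.2096); 116 retained after pruning
#> clusters: 2 by the bar-gap rule; per-level scales: 0.4956, 0.4278
fit
#> Topological hierarchical clustering
#>   1994 points, 117 landmarks (coverage R = 0.2096), 116 retained
#>   2 clusters by the bar-gap rule (gap > 0.1); 1 after outlier pruning
#> Cluster report (RMSD in A vs toy10 / toy10_goal):
#>  cluster size rmsd_toy10 rmsd_toy10_goal representative
#>        1  116 0.17+-0.09      2.52+-0.08           1935
```

Reading the output: the sampler accepted 1993 conformations on its way
from `toy10` toward `toy10_goal`; spherical PCA keeps ~98% of the variance
in three coordinates; 117 maxmin landmarks cover the cloud. The barcode
finds one densely populated region plus an isolated landmark (a long bar
that is pruned as an outlier at the selected level), so this short
diffusive toy pathway reports a single cluster hugging the start (mean
0.17 Å from it) — on real transitions with 60,000 iterations the pool
spreads into several populated regions between the endpoints. Each
`representative` is a model index into `toy_results/traj.pdb`, also
written as `representative_01.pdb`, ...

On real input, pass two PDB paths (Cα traces are extracted automatically,
alternate locations resolved by occupancy, pairing by residue number):

```r
cfg <- pipeline_config("1cll.pdb", "1ctr.pdb", chain = "A",
                       method = "isomap", max_iterations = 60000, seed = 1)
fit <- run_pipeline(cfg)
```

A command-line front end with `synth`, `sample`, `embed`, `cluster` and
`run` subcommands is installed at
`system.file("cli", "pathtopo.R", package = "pathtopo")`.

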