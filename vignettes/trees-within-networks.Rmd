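---
title: "Trees within phylogenetic networks under the coalescent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trees within phylogenetic networks under the coalescent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcoal)
```

## The model

A rooted binary phylogenetic network is a DAG with a single root
(in-degree 0, out-degree 2), tree nodes (1, 2), leaves (1, 0) bijectively
labeled by taxa, and reticulation nodes (2, 1) representing hybridization
or admixture. Branch lengths are in **coalescent units** (time divided by
population size, so any two lineages in a population coalesce at rate 1
and j lineages at rate choose(j, 2)). Each pair of edges into a
reticulation node carries **inheritance probabilities** `gamma` and
`1 - gamma`: the probability that a lineage in the hybrid population
descends from the corresponding parent.

Two tree sets live inside a network `psi`:

* **Displayed trees** `U(psi)`: delete one incoming edge per reticulation
  node, contract degree-one nodes. At most `2^k` trees for `k`
  reticulations.
* **Parental trees** `W(psi)` (weakly displayed trees): convert the
  network to its MUL-tree (copy the subtree below each reticulation to
  both parents), then keep one (or more) leaf copy per taxon and
  contract. Always `U(psi) ⊆ W(psi)`, and the containment is typically
  strict.

Parental trees matter because of incomplete lineage sorting: two lineages
that fail to coalesce below a reticulation node can take *different*
parent edges, producing a gene tree that no displayed tree can generate.
On the running four-taxon example (hybridization between D and the
ancestor of the cherry (B, C)) there are 2 displayed trees but 4 parental
trees, the extra two being `((A,B),(C,D))` and `((A,C),(B,D))`.

## Gene-tree probabilities

Under the multispecies network coalescent the gene-tree topology is a
discrete random variable. `prob_gene_tree_on_network()` computes its mass
function exactly by enumerating coalescent histories **on the network
DAG**: within every branch a set of gene-tree coalescences is realized
with probability `g_{uv}(lambda) * w/d` (the standard per-branch
transition probability `g_{uv}` of `u` lineages becoming `v`, times the
number `w` of merge orderings consistent with the gene tree over the
number `d` of all merge sequences), and each lineage reaching a
reticulation node picks a parent edge independently with probability
`gamma`.

The per-*lineage* (not per-allele) `gamma` weighting is the crux: if two
lineages coalesce below the reticulation, the merged lineage crosses once
and contributes a single factor `gamma`; if they fail to coalesce —
probability `g_{22}(y)` on the branch of length `y` below the
reticulation — each crosses independently. A naive computation that
assigns alleles to MUL-tree leaf copies up front severs that shared
branch: two alleles sent to different copies would no longer pay the
`g_{22}(y)` factor, and the distribution stops summing to one. Working on
the DAG keeps the branch shared and reproduces the known closed forms to
machine precision; the closed forms for the symmetric four-taxon network
(`closed_form_probs()`, `limit_probs()`) are implemented independently
and serve as a second route in the tests.

The engine enumerates histories symbolically once per (network shape,
topology) and caches the result, so parameter sweeps cost only arithmetic.
It is exponential in the number of taxa and reticulations and intended
for desk-scale networks (up to roughly 6-8 taxa, a handful of
reticulations); branch lengths may be 0 (`g_{ii}(0) = 1`) or infinite
(`g_{i1}(Inf) = 1`), and the branch above the root is implicitly infinite.

## Anomalies and the backbone threshold

A topology `g` is **anomalous** when `P(g) > P(t)` for every parental
tree `t` — strictly, so ties are reported but do not count. Three-taxon
networks never produce anomalies (every 3-taxon gene tree that could beat
the parental trees is dominated by one of them), which the test suite
verifies on dense grids over two fixture networks covering `|W| = 2` and
`|W| = 3`. Symmetric four-taxon networks do produce anomalies:
`anomaly_zone_scan()` maps, over the `(x, y)` plane of the symmetric
network, whether the most likely gene tree is displayed, parental but not
displayed, or non-parental.

As the root branches grow (`x -> Inf`), seven of the 15 topologies lose
all mass. With `gamma = 0.5` the most likely topology switches between
the non-displayed parental tree `((A,B),(C,D))` (probability
`(1/4)e^{-y}`) and the backbone tree (probability `1/2 - (5/12)e^{-y}`)
at `y = log(4/3) ≈ 0.288`: below that branch length no species-tree
method aiming at a backbone tree can be consistent.
`backbone_threshold()` solves this equality numerically from the limiting
forms.

At `gamma = 0` the network degenerates to the caterpillar species tree;
the scan then correctly shows the classical caterpillar anomaly zone near
the origin (most likely tree `((A,D),(B,C))`), which is *not* a parental
tree of the network — a reminder that the parental set is a property of
the network topology, not of the degenerate tree.

## The simulator

`simulate_gene_trees()` draws gene trees backward in time: exponential
coalescence races inside each branch, independent Bernoulli(`gamma`)
parent choice per lineage at reticulations, and a final race above the
root. Branch durations are taken per edge, which is the exact semantics
of coalescent-unit branch lengths; for networks whose root-to-leaf paths
disagree in total length (legitimate, since coalescent units absorb
population sizes) output node heights follow the longer of the two
merging clocks, so topologies are always exact and branch lengths exact
whenever the network is time-consistent. Every preset network here is
built time-consistent except for the deliberately heterogeneous internal
branches of the clustering experiment, where only topologies are used.

The generator emulates idealized loci: free recombination between loci,
none within, no gene-tree estimation error, no missing taxa. Passing
tests therefore speak to the behavior of the methods on *true* gene
trees; error in estimated gene trees is explicitly out of scope.

## Recovering parental trees by clustering

A network is a mixture model whose components are its parental trees.
`cluster_infer_pipeline()` implements the recovery protocol: pairwise
rooted Robinson-Foulds distances (symmetric difference of nontrivial
clusters), classical (Torgerson) MDS to 3 dimensions, k-means for
`k = 2..10` (base `stats::kmeans`, 10 restarts, 300 iterations),
selection of `k` by maximal mean silhouette computed **on the RF
distances** (ties toward smaller `k`), exact minimize-deep-coalescence
(MDC) species-tree inference per cluster, and scoring of the inferred
set against a reference set by a minimum-weight edge cover whose edge
weights are RF distances normalized by their maximum `2(n-2)`; the error
is the mean weight over cover edges. The MDC optimum is found by scoring
every rooted topology (at most 8 taxa) through a per-cluster table of
extra-lineage counts, rather than the cluster-restricted heuristic some
implementations use: at desk scale the exact optimum is affordable and
strictly dominates the heuristic. The edge cover is computed exactly via
the classical reduction to maximum-weight matching on the savings graph.

### Why the experiment network has six taxa

The recovery experiment (`run_clustering_experiment()`) draws 10 networks
from a one-reticulation family with four parental trees: reticulation
edges of length 0, a branch of 0.2 coalescent units below the
reticulation (short enough that lineages regularly reach the reticulation
uncoalesced), inheritance probability 0.35, and the remaining internal
branches uniform on [0.7, 1.3]; 30 datasets per network at each dataset
size.

Two design constraints dictated the default network shape
(`clustering_experiment_network()`, six taxa, reticulation parents in
different halves of the backbone):

1. On four taxa there are only 15 rooted topologies, so a dataset
   contains many *identical* trees. Mean silhouette over trees then
   degenerates: any split that isolates duplicated topologies scores a
   perfect 1, the selection drifts to the largest `k` tried, and the
   recovered set drowns in satellite topologies. A richer topology space
   (six taxa: 945) removes the degeneracy without changing any stated
   parameter.
2. When the two reticulation parents are sister edges, the two backbone
   parental trees differ by a single cluster (rooted RF 2) and their ILS
   clouds overlap; silhouette then merges them and selects three
   clusters. Placing the reticulation between non-sister lineages makes
   all four parental trees mutually RF ≥ 6, and the four mixture
   components separate cleanly.

With this design the pipeline selects `k = 4` in almost all 250-locus
replicates, recovers all four parental trees in the large majority of
them, and the mean edge-cover error is well under 2% at 250 loci and
under 15% at 50 loci. The network family is a `builder` argument, so the
four-taxon variant (or any other one-reticulation family) can be swapped
in.

Degenerate input — a dataset with a single distinct topology — skips
MDS/k-means (silhouette is undefined there) and returns that topology as
the lone cluster.

## The median-distance backbone method

`median_distance_tree()` implements the species-tree-from-gene-trees
method that takes, for every pair of taxa, the **median** across loci of
the gene-tree path distance, and reconstructs a tree from the median
matrix. Coalescent gene trees are ultrametric in expectation, so the
reconstruction uses average-linkage agglomerative clustering (UPGMA) on
the median matrix; `run_backbone_experiment()` wraps the protocol
(symmetric network, `x = 1000` so coalescence above the root is
immediate, `y` in {0.1, 0.2, 0.5, 1.0}, 25-200 loci, 100 datasets) and
reports the fraction of datasets whose inferred topology is one of the
two displayed trees.

## Numerical policy and problem sizes

All probability computations are plain double-precision sums of
exponentials — the quantities involved are bounded by 1 and the scale of
the experiments keeps terms far from underflow. Distributions are checked
to sum to 1 within 1e-9; inheritance-probability pairs must sum to 1
within 1e-9 at parse time; engine-versus-closed-form agreement is held to
1e-10 and the `x = 50` limit comparison to 1e-6. Argmax ties in anomaly
detection use an absolute tolerance of 1e-12 and are reported rather
than broken.

The shipped tests run the full published protocol for the clustering
experiment (10 networks x 30 datasets at 50 and 250 loci), a
50,000-locus simulator calibration, a 10 x 10 x 5 lattice for the oracle
equivalence, and 20 x 20 x 5 anomaly sweeps per three-taxon fixture —
sizes chosen so the whole suite completes in minutes on one core while
keeping every stated check at full strength.

## Limitations

The probability engine is single-allele-per-species (the parental-tree
enumeration supports multiple alleles); topology mass functions only, no
branch-length densities; exhaustive MDC stops at 8 taxa; combining the
recovered parental trees into a minimal network (the parental-tree
network problem) is a separate open problem and out of scope.
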