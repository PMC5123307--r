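# netcoal

Trees within phylogenetic networks under the multispecies network
coalescent.

When hybridization or admixture makes a species history a **network**
rather than a tree, most analyses still reason about the trees the
network *displays* (delete one incoming edge per reticulation node). But
under incomplete lineage sorting, gene lineages that fail to coalesce
before reaching a reticulation can take different parent edges, and the
resulting gene tree may match no displayed tree at all. The right tree
set is the larger set of **parental trees** `W(ψ)` (weakly displayed
trees), obtained from the network's MUL-tree by choosing leaf copies.
`netcoal` is a toolkit for working with that insight, aimed at
phylogeneticists studying gene-tree/species-network discordance:

* extended (rich) Newick I/O for networks with inheritance probabilities
  `γ` on reticulation edges, and enumeration of displayed trees,
  MUL-trees and parental trees;
* exact gene-tree topology probabilities `P_{ψ,λ,Γ}(G = g)` under the
  multispecies network coalescent, by coalescent-history enumeration on
  the network (branch lengths `λ` in coalescent units; per-branch factors
  `g_{uv}(λ_b)·w/d`, per-lineage parent choice with probability `γ` at
  reticulations);
* anomaly detection — a topology `g` is anomalous when
  `P(g) > P(t)` for every parental tree `t` — plus anomaly-zone scans
  and the closed-form/limiting distributions of the symmetric four-taxon
  hybridization network;
* a seeded backward-in-time coalescent simulator of gene trees within a
  network;
* inference: the clustering pipeline that recovers a network's parental
  trees from gene trees (rooted RF distances → classical MDS → k-means
  → silhouette selection of `k` → exact minimize-deep-coalescence tree
  per cluster → minimum-weight edge-cover scoring), and a
  median-gene-tree-distance species-tree method for backbone recovery.

## Worked example

The running example is a four-taxon network in which D hybridized with
the ancestor of the cherry (B, C) (inheritance probability 0.3 toward
the A side; branch lengths in coalescent units):

```r
library(netcoal)
net <- parse_network(
  "((A:1.2,((B:1,C:1):0.2)#H1:0::0.3):2,(D:1.2,#H1:0::0.7):2);")

for (t in displayed_trees(net)) cat(canonical_topology(t), "\n")
#> (((B,C),A),D)
#> (((B,C),D),A)

for (t in parental_trees(net)) cat(canonical_topology(t), "\n")
#> (((B,C),A),D)
#> (((B,C),D),A)
#> ((A,B),(C,D))
#> ((A,C),(B,D))
```

Two displayed trees, but four parental trees: `((A,B),(C,D))` and
`((A,C),(B,D))` arise only when the B and C lineages reach the
reticulation uncoalesced (the branch below it is short, 0.2) and split
between the two parents. Those trees carry real probability mass:

```r
round(sort(gene_tree_distribution(net), decreasing = TRUE)[1:5], 4)
#> (((B,C),D),A) ((A,B),(C,D)) ((A,C),(B,D)) (((B,D),C),A) (((C,D),B),A)
#>        0.2356        0.1533        0.1533        0.1227        0.1227
```

With short branches the most likely gene tree is not a parental tree at
all (an anomaly), and in the long-root limit the most likely gene tree
stops being a backbone tree whenever the branch below the reticulation
is shorter than `log(4/3)`:

```r
res <- is_anomalous(symmetric_hybrid_network(x = 0.05, y = 0.05,
                                             w = 0, gamma = 0.5))
res$anomalous          #> TRUE
res$argmax_topologies  #> "((A,D),(B,C))"
round(backbone_threshold(gamma = 0.5), 3)  #> 0.288
```

Simulated gene trees can be clustered to recover the parental trees:

```r
nets <- clustering_experiment_network(c(1, 1.1, 0.9, 1.2))
genes <- simulate_gene_trees(nets, loci = 250, seed = 1)
fit <- cluster_infer_pipeline(genes, reference = parental_trees(nets))
fit$k       # number of clusters selected by silhouette (4)
fit$error   # edge-cover error against the true parental trees (0 here)
```

See the vignette (`vignettes/trees-within-networks.Rmd`) for the model,
the algorithms, and the design choices.

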