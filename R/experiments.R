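# Scripted computational experiments: backbone-tree recovery with the
# median-distance method, and parental-tree recovery by clustering. The
# default parameters are the study conditions these experiments are
# defined under; override them to explore.

#' One-reticulation network used by the clustering experiment
#'
#' A six-taxon network with a single reticulation whose child is the
#' cherry (B, C) and whose two parents lie in different halves of the
#' backbone (next to A and next to D), giving exactly four parental
#' trees. Placing the reticulation between non-sister lineages keeps the
#' four mixture components mutually distant in tree space (pairwise RF 6
#' to 8 between the parental trees), which is what lets the clustering
#' pipeline tell them apart; when the two parents are sisters the two
#' backbone components sit at RF 2 and merge into one cluster.
#'
#' @param internals numeric vector of four internal branch lengths: above
#'   the A-side reticulation parent, the A-clade root branch, above the
#'   D-side reticulation parent, and the D-clade root branch.
#' @param y length of the branch below the reticulation node (default
#'   0.2, short enough that lineages regularly fail to coalesce before
#'   the reticulation).
#' @param w length of the reticulation edges (default 0).
#' @param gamma inheritance probability of the A-side edge (default 0.35).
#' @param pendant pendant length for B and C.
#' @return a `phylo_network` on taxa A..F.
#' @export
clustering_experiment_network <- function(internals = rep(1, 4), y = 0.2,
                                          w = 0, gamma = 0.35,
                                          pendant = 1) {
  stopifnot(length(internals) == 4L)
  fmt <- function(v) format(v, digits = 17, scientific = FALSE)
  hBC <- pendant + y + w
  txt <- sprintf(
    paste0("(((A:%s,((B:%s,C:%s):%s)#H1:%s::%s):%s,E:%s):%s,",
           "((D:%s,#H1:%s::%s):%s,F:%s):%s);"),
    fmt(hBC), fmt(pendant), fmt(pendant), fmt(y), fmt(w), fmt(gamma),
    fmt(internals[1]), fmt(hBC + internals[1]), fmt(internals[2]),
    fmt(hBC), fmt(w), fmt(1 - gamma),
    fmt(internals[3]), fmt(hBC + internals[3]), fmt(internals[4]))
  parse_network(txt)
}

#' Parental-tree recovery experiment
#'
#' Draws `n_networks` networks from the one-reticulation four-parental-tree
#' family (internal branches other than the reticulation edges and the
#' branch below the reticulation sampled uniformly in
#' `internal_range`), simulates `datasets_per_network` datasets of `loci`
#' gene trees within each, runs the clustering pipeline on every dataset
#' against the network's true parental trees, and collects the edge-cover
#' errors.
#'
#' @param loci gene trees per dataset.
#' @param n_networks networks drawn (default 10).
#' @param datasets_per_network datasets per network (default 30).
#' @param seed integer seed controlling every random draw.
#' @param y,w,gamma network parameters (see
#'   [clustering_experiment_network()]).
#' @param internal_range range the internal branch lengths are drawn from.
#' @param builder function taking a vector of four internal branch lengths
#'   plus `y`, `w`, `gamma` and returning a `phylo_network`; swap it to
#'   run the protocol on a different network family.
#' @param kmax,nstart clustering parameters (see
#'   [cluster_infer_pipeline()]).
#' @return data frame with one row per dataset: `network`, `dataset`,
#'   `k` (clusters selected), `n_correct` (true parental trees recovered,
#'   out of 4), and `error` (edge-cover error in `[0,1]`).
#' @export
run_clustering_experiment <- function(loci, n_networks = 10,
                                      datasets_per_network = 30,
                                      seed = 1, y = 0.2, w = 0,
                                      gamma = 0.35,
                                      internal_range = c(0.7, 1.3),
                                      builder = clustering_experiment_network,
                                      kmax = 10, nstart = 10) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_networks)) {
    xs <- stats::runif(4, internal_range[1], internal_range[2])
    net <- builder(xs, y = y, w = w, gamma = gamma)
    W <- parental_trees(net)
    Wkeys <- vapply(W, canonical_topology, "")
    for (j in seq_len(datasets_per_network)) {
      genes <- simulate_gene_trees(net, loci)
      fit <- cluster_infer_pipeline(genes, reference = W, kmax = kmax,
                                    nstart = nstart)
      inf_keys <- vapply(fit$trees, canonical_topology, "")
      rows[[length(rows) + 1L]] <-
        data.frame(network = i, dataset = j, k = fit$k,
                   n_correct = length(intersect(inf_keys, Wkeys)),
                   error = fit$error)
    }
  }
  do.call(rbind, rows)
}

#' Backbone-tree recovery experiment (median-distance method)
#'
#' Simulates gene-tree datasets on the symmetric hybrid network with long
#' root branches (deep coalescence above the root suppressed), infers a
#' species tree per dataset from the median pairwise gene-tree distances,
#' and reports the fraction of datasets whose inferred topology is one of
#' the network's two displayed (backbone) trees.
#'
#' @param y_values values for the branch below the reticulation node.
#' @param loci_counts dataset sizes.
#' @param gamma inheritance probability of the A-side reticulation edge.
#' @param n_datasets datasets per combination (default 100).
#' @param seed integer seed.
#' @param x root-branch length (default 1000).
#' @return data frame with columns `y`, `loci`, `accuracy`.
#' @export
run_backbone_experiment <- function(y_values = c(0.1, 0.2, 0.5, 1.0),
                                    loci_counts = c(25, 50, 100, 200),
                                    gamma = 0.5, n_datasets = 100,
                                    seed = 1, x = 1000) {
  set.seed(seed)
  rows <- list()
  for (y in y_values) {
    net <- symmetric_hybrid_network(x = x, y = y, w = 0, gamma = gamma)
    disp <- displayed_trees(net)
    for (loci in loci_counts) {
      hits <- vapply(seq_len(n_datasets), function(d) {
        genes <- simulate_gene_trees(net, loci)
        inf <- median_distance_tree(genes)$tree
        canonical_topology(inf) %in% vapply(disp, canonical_topology, "")
      }, TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(y = y, loci = loci, accuracy = mean(hits))
    }
  }
  do.call(rbind, rows)
}
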