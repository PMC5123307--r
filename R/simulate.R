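# Backward-in-time coalescent simulation of gene trees within a
# phylogenetic network. Within every branch, the lineages present race to
# coalesce at rate choose(j, 2) per coalescent unit; at a reticulation
# node each lineage independently follows a parent edge with that edge's
# inheritance probability; above the root the race continues to a single
# lineage. Branch lengths are already in coalescent units, so no further
# population-size parameters enter.

#' Simulate one gene tree within a network
#'
#' @param net a `phylo_network`; every internal branch needs a length and
#'   every reticulation an inheritance probability. Missing pendant
#'   lengths are treated as 0.
#' @param samples named allele counts per taxon (see [sample_config()]);
#'   default one allele per species, in which case gene leaves carry the
#'   taxon names (otherwise `taxon_1`, `taxon_2`, ...).
#' @return an `rtree` with branch lengths in coalescent units.
#' @details Node heights are taken as the coalescent time accumulated
#'   along a lineage's own path; for time-consistent (ultrametric)
#'   networks this is exact, and when root-to-leaf paths disagree in total
#'   length the larger of the two merging lineages' clocks is used.
#' @export
simulate_gene_tree <- function(net, samples = NULL) {
  dag <- dag_struct(net)
  taxa <- network_taxa(net)
  if (is.null(samples)) {
    samples <- sample_config(setNames(rep(1L, length(taxa)), taxa))
  }
  n_edges <- nrow(dag$edges)
  delivered <- vector("list", n_edges)
  race <- function(pool, L) {
    # pool: list of lineages, each list(node = rtree node, h = height)
    elapsed <- 0
    k <- length(pool)
    while (k >= 2L) {
      wait <- stats::rexp(1L, rate = k * (k - 1) / 2)
      if (elapsed + wait > L) break
      elapsed <- elapsed + wait
      ij <- sample.int(k, 2L)
      l1 <- pool[[ij[1]]]; l2 <- pool[[ij[2]]]
      H <- max(l1$h, l2$h) + elapsed # clocks carried from segment entry
      c1 <- l1$node; c1$length <- H - l1$node_h
      c2 <- l2$node; c2$length <- H - l2$node_h
      merged <- list(node = new_rnode(children = list(c1, c2)),
                     h = max(l1$h, l2$h), node_h = H)
      pool[[ij[1]]] <- merged
      pool <- pool[-ij[2]]
      k <- k - 1L
    }
    if (is.finite(L)) {
      for (i in seq_along(pool)) pool[[i]]$h <- pool[[i]]$h + L
    }
    pool
  }
  for (v in dag$topo) {
    ces <- dag$child_edges[[v]]
    pool <- if (length(ces) > 0L) {
      unlist(delivered[ces], recursive = FALSE)
    } else {
      tx <- dag$label[v]
      a <- samples[[tx]]
      if (is.null(a)) stop("no allele count for taxon ", tx)
      nm <- if (a == 1L) tx else paste(tx, seq_len(a), sep = "_")
      lapply(nm, function(x) list(node = new_rnode(x), h = 0, node_h = 0))
    }
    pes <- dag$parent_edges[[v]]
    if (length(pes) == 0L) { # root: race to one lineage
      pool <- race(pool, Inf)
      tr <- pool[[1]]$node
      class(tr) <- c("rtree", "list")
      return(tr)
    }
    if (length(pes) == 1L) {
      L <- dag$edges$length[pes]
      if (is.na(L)) L <- 0
      delivered[[pes]] <- race(pool, L)
    } else { # reticulation node
      g1 <- dag$edges$gamma[pes[1]]
      if (is.na(g1)) stop("missing inheritance probability at a reticulation")
      take1 <- stats::runif(length(pool)) < g1
      for (j in 1:2) {
        sub <- pool[if (j == 1L) take1 else !take1]
        L <- dag$edges$length[pes[j]]
        if (is.na(L)) stop("missing length on a reticulation edge")
        delivered[[pes[j]]] <- race(sub, L)
      }
    }
  }
  stop("internal error: root never reached")
}

#' Simulate a dataset of independent gene trees
#'
#' @param net a `phylo_network`.
#' @param loci number of independent gene trees to draw.
#' @param seed integer seed; the draw is fully reproducible.
#' @param samples allele counts (see [simulate_gene_tree()]).
#' @return list of `rtree` objects of length `loci`.
#' @export
#' @examples
#' net <- symmetric_hybrid_network(x = 1, y = 0.5, gamma = 0.3)
#' trees <- simulate_gene_trees(net, loci = 5, seed = 1)
simulate_gene_trees <- function(net, loci, seed = NULL, samples = NULL) {
  stopifnot(loci >= 1)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(loci), function(i) simulate_gene_tree(net, samples))
}

#' Empirical topology frequencies of a set of gene trees
#'
#' @param trees nonempty list of `rtree` objects on a shared leaf set.
#' @return data frame with columns `topology` (canonical string) and
#'   `freq`, sorted by decreasing frequency; frequencies sum to 1.
#' @export
empirical_distribution <- function(trees) {
  if (length(trees) == 0L) stop("empty tree list")
  keys <- vapply(trees, canonical_topology, "")
  tab <- sort(table(keys), decreasing = TRUE)
  data.frame(topology = names(tab),
             freq = as.numeric(tab) / length(trees),
             stringsAsFactors = FALSE)
}
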