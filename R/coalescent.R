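# Exact gene-tree topology probabilities under the multispecies (network)
# coalescent. Histories are enumerated directly on the network DAG: gene
# lineages move leaf-to-root; within each branch, sets of gene-tree
# coalescences are realized with the standard per-branch probability
# g_{uv}(lambda) * w/d (w = orderings consistent with the gene tree, d =
# all merge sequences); at a reticulation node every lineage present
# chooses a parent edge independently, contributing the edge's inheritance
# probability once per *lineage* (not per allele), which is what couples
# the network to coalescence below the reticulation.

#' Probability that i lineages coalesce into j within time t
#'
#' The standard coalescent transition probability (Tavare's closed form):
#' with `i` lineages at the bottom of a population branch of length `t`
#' coalescent units, the number of surviving lineages after time `t` is `j`
#' with this probability. `t = Inf` is allowed (certain coalescence to 1);
#' `t = 0` returns the identity.
#'
#' @param i number of entering lineages (>= 1).
#' @param j number of surviving lineages, `1 <= j <= i`.
#' @param t branch length in coalescent units (nonnegative, may be `Inf`).
#' @return a probability.
#' @export
#' @examples
#' gij(2, 1, 1)       # 1 - exp(-1)
#' sum(sapply(1:3, function(j) gij(3, j, 0.7)))  # 1
gij <- function(i, j, t) {
  stopifnot(length(i) == 1L, length(j) == 1L, length(t) == 1L)
  if (j < 1 || j > i) stop("need 1 <= j <= i")
  if (t < 0) stop("t must be nonnegative")
  if (is.infinite(t)) return(as.numeric(j == 1L))
  if (t == 0) return(as.numeric(i == j))
  s <- 0
  for (k in j:i) {
    rate <- k * (k - 1) / 2
    coef <- (2 * k - 1) * (-1)^(k - j) /
      (factorial(j) * factorial(k - j) * (j + k - 1))
    yy <- seq_len(k) - 1
    prd <- prod((j + yy) * (i - yy) / (i + yy))
    s <- s + exp(-rate * t) * coef * prd
  }
  min(max(s, 0), 1)
}

# ---- gene-side structure ----

# Gene topology on alleles: events in postorder with child lineage ids.
# Lineage ids: 1..A are alleles, A+e is event e.
gene_struct <- function(gene, allele_names) {
  A <- length(allele_names)
  events <- list()
  walk <- function(node) {
    if (is_leaf(node)) {
      a <- match(node$label, allele_names)
      if (is.na(a)) stop("gene leaf '", node$label, "' not among alleles")
      return(a)
    }
    if (length(node$children) != 2L) stop("gene tree must be binary")
    k1 <- walk(node$children[[1]])
    k2 <- walk(node$children[[2]])
    events[[length(events) + 1L]] <<- c(k1, k2)
    A + length(events)
  }
  walk(gene)
  m <- length(events)
  # desc[i, j]: event i is a proper descendant of event j
  desc <- matrix(FALSE, m, m)
  for (j in seq_len(m)) {
    stack <- events[[j]][events[[j]] > A] - A
    while (length(stack)) {
      i <- stack[1]; stack <- stack[-1]
      desc[i, j] <- TRUE
      ce <- events[[i]][events[[i]] > A] - A
      stack <- c(stack, ce)
    }
  }
  list(A = A, events = events, m = m, desc = desc)
}

# All realizable merge outcomes for lineage set S within one branch.
# Returns a list of outcomes: list(done = event ids merged, surv =
# surviving lineage ids, w = number of merge orderings realizing the set).
# Generated by expanding ordered sequences; the multiplicity of an outcome
# set equals its number of linear extensions.
merge_outcomes <- function(S, ge) {
  acc <- new.env(parent = emptyenv())
  rec <- function(S, done) {
    key <- paste0("m", paste(sort(done), collapse = ","))
    hit <- acc[[key]]
    if (is.null(hit)) {
      acc[[key]] <- list(done = done, surv = S, w = 1L)
    } else {
      hit$w <- hit$w + 1L
      acc[[key]] <- hit
    }
    for (e in seq_len(ge$m)) {
      if (e %in% done) next
      kids <- ge$events[[e]]
      if (all(kids %in% S)) {
        rec(c(setdiff(S, kids), ge$A + e), c(done, e))
      }
    }
  }
  rec(S, integer(0))
  as.list(acc)
}

# ---- network DAG structure ----

# Flatten a phylo_network (or rtree species tree) into the arrays the
# engine uses; node order is leaf-to-root topological.
dag_struct <- function(net) {
  e <- net$edges
  n <- length(net$label)
  indeg <- tabulate(e$child, n)
  outdeg <- tabulate(e$parent, n)
  # topological order, children before parents
  order <- integer(0)
  done_out <- integer(n)
  queue <- which(outdeg == 0L)
  remaining <- outdeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (i in which(e$child == v)) {
      p <- e$parent[i]
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) queue <- c(queue, p)
    }
  }
  list(n = n, label = net$label, edges = e, root = net$root,
       topo = order,
       parent_edges = lapply(seq_len(n), function(v) which(e$child == v)),
       child_edges = lapply(seq_len(n), function(v) which(e$parent == v)))
}

rtree_to_net <- function(tree) {
  env <- new.env(parent = emptyenv())
  env$label <- character(0)
  env$edges <- list()
  rec <- function(node) {
    id <- length(env$label) + 1L
    env$label[id] <- if (is_leaf(node)) node$label else NA_character_
    for (ch in node$children) {
      chid <- rec(ch)
      env$edges[[length(env$edges) + 1L]] <-
        list(parent = id, child = chid,
             length = if (is.null(ch$length)) NA_real_ else ch$length,
             gamma = NA_real_)
    }
    id
  }
  rec(tree)
  new_phylo_network(env$label,
                    do.call(rbind, lapply(env$edges, as.data.frame)),
                    1L)
}

dag_signature <- function(dag) {
  paste(paste(dag$edges$parent, dag$edges$child,
              ifelse(is.na(dag$edges$gamma), 0, 1), sep = "."),
        collapse = "|") |>
    paste(paste(ifelse(is.na(dag$label), ".", dag$label), collapse = ","),
          sep = "~")
}

# ---- history enumeration ----

# Enumerate all coalescent histories of `gene` on the network, collecting
# symbolic terms: coefficient (products of w/d), per-edge (u, v) pairs
# requiring a g_{uv}(length) factor, and per-edge gamma exponents. Numeric
# lengths and inheritance probabilities enter only in eval_terms().
history_terms <- function(dag, ge, allele_leaf) {
  terms <- list()
  m_edges <- nrow(dag$edges)
  # pools[[edge]] = lineage ids delivered out of that edge (survivors)
  recurse <- function(step, surv, coef, g_edges, g_u, g_v, gexp) {
    v <- dag$topo[step]
    pool <- if (is.na(dag$label[v]) || length(dag$child_edges[[v]]) > 0L) {
      unlist(surv[dag$child_edges[[v]]], use.names = FALSE)
    } else {
      which(allele_leaf == v) # alleles sitting at this leaf
    }
    pes <- dag$parent_edges[[v]]
    if (length(pes) == 0L) { # root: infinite stem, everything coalesces
      u <- length(pool)
      outs <- merge_outcomes(pool, ge)
      for (o in outs) {
        if (length(o$surv) != 1L) next
        dd <- if (u >= 2L) prod(choose(seq.int(2L, u), 2)) else 1
        terms[[length(terms) + 1L]] <<-
          list(coef = coef * o$w / dd, g_edges = g_edges,
               g_u = g_u, g_v = g_v, gexp = gexp)
      }
      return(invisible())
    }
    routes <- if (length(pes) == 1L) {
      list(setNames(list(pool), pes))
    } else { # reticulation: each lineage picks a parent edge
      k <- length(pool)
      out <- list()
      for (msk in 0:(2^k - 1)) {
        left <- pool[bitwAnd(bitwShiftR(msk, seq_len(k) - 1L), 1L) == 1L]
        right <- setdiff(pool, left)
        out[[length(out) + 1L]] <- setNames(list(left, right), pes)
      }
      out
    }
    for (rt in routes) {
      gexp2 <- gexp
      if (length(pes) == 2L) {
        for (j in seq_along(pes)) {
          gexp2[pes[j]] <- gexp2[pes[j]] + length(rt[[j]])
        }
      }
      # resolve each parent edge's merges; combine outcomes across edges
      edge_opts <- lapply(seq_along(pes), function(j) {
        S <- rt[[j]]
        u <- length(S)
        if (u == 0L) {
          return(list(list(surv = integer(0), add_e = integer(0),
                           add_u = integer(0), add_v = integer(0),
                           coef = 1)))
        }
        outs <- merge_outcomes(S, ge)
        lapply(outs, function(o) {
          vv <- length(o$surv)
          dd <- if (length(o$done)) {
            prod(choose(seq.int(vv + 1L, u), 2))
          } else {
            1
          }
          need_g <- u >= 2L
          list(surv = o$surv,
               add_e = if (need_g) pes[j] else integer(0),
               add_u = if (need_g) u else integer(0),
               add_v = if (need_g) vv else integer(0),
               coef = o$w / dd)
        })
      })
      grid <- do.call(expand.grid,
                      c(lapply(edge_opts, seq_along), KEEP.OUT.ATTRS = FALSE))
      for (r in seq_len(nrow(grid))) {
        surv2 <- surv
        coef2 <- coef
        ge2 <- g_edges; gu2 <- g_u; gv2 <- g_v
        for (j in seq_along(pes)) {
          o <- edge_opts[[j]][[grid[r, j]]]
          surv2[[pes[j]]] <- o$surv
          coef2 <- coef2 * o$coef
          ge2 <- c(ge2, o$add_e); gu2 <- c(gu2, o$add_u)
          gv2 <- c(gv2, o$add_v)
        }
        recurse(step + 1L, surv2, coef2, ge2, gu2, gv2, gexp2)
      }
    }
  }
  recurse(1L, rep(list(integer(0)), m_edges), 1,
          integer(0), integer(0), integer(0), integer(m_edges))
  terms
}

eval_terms <- function(terms, dag) {
  len <- dag$edges$length
  gam <- dag$edges$gamma
  total <- 0
  for (tm in terms) {
    p <- tm$coef
    if (length(tm$g_edges)) {
      for (i in seq_along(tm$g_edges)) {
        t_b <- len[tm$g_edges[i]]
        if (is.na(t_b)) {
          stop("missing branch length on a branch where lineages ",
               "may coalesce")
        }
        p <- p * gij(tm$g_u[i], tm$g_v[i], t_b)
      }
    }
    gx <- which(tm$gexp > 0L)
    if (length(gx)) {
      gv <- gam[gx]
      if (anyNA(gv)) stop("missing inheritance probability on a reticulation")
      p <- p * prod(gv^tm$gexp[gx])
    }
    total <- total + p
  }
  total
}

.plan_cache <- new.env(parent = emptyenv())

cached_terms <- function(dag, ge, allele_leaf, gene_key) {
  key <- paste(dag_signature(dag), paste(allele_leaf, collapse = ","),
               gene_key, sep = "~")
  tm <- .plan_cache[[key]]
  if (is.null(tm)) {
    tm <- history_terms(dag, ge, allele_leaf)
    .plan_cache[[key]] <- tm
  }
  tm
}

#' Gene-tree topology probability on a species tree
#'
#' Exact probability of a rooted gene-tree topology under the multispecies
#' coalescent, by enumeration of coalescent histories (per-branch coalescent
#' transition probabilities times ordering coefficients). One allele per
#' species; gene leaves are matched to species leaves by label.
#'
#' @param species an `rtree` with branch lengths in coalescent units
#'   (pendant lengths may be absent; the branch above the root is infinite).
#' @param gene an `rtree` topology on the same labels.
#' @return a probability.
#' @export
#' @examples
#' sp <- parse_tree("((A:1,B:1):1,C:2);")
#' prob_gene_tree_on_tree(sp, parse_tree("((A,B),C);")) # 1 - 2/3*exp(-1)
prob_gene_tree_on_tree <- function(species, gene) {
  prob_gene_tree_on_network(rtree_to_net(species), gene)
}

#' Gene-tree topology probability on a network
#'
#' Exact probability under the multispecies network coalescent, one allele
#' per species. Coalescent histories are enumerated on the network itself:
#' lineages coalesce within branches at the standard rates, and each
#' lineage reaching a reticulation node picks a parent edge independently
#' with that edge's inheritance probability — so the probability a merged
#' pair crosses together differs from two lineages crossing separately,
#' which is exactly why the network is more than its displayed trees.
#'
#' @param net a `phylo_network` with branch lengths and inheritance
#'   probabilities (a reticulation-free network, i.e. a tree, is allowed).
#' @param gene an `rtree` topology whose leaves are the network's taxa.
#' @return a probability.
#' @export
prob_gene_tree_on_network <- function(net, gene) {
  dag <- dag_struct(net)
  taxa <- network_taxa(net)
  gl <- sort(tree_leaves(gene))
  if (!identical(taxa, gl)) stop("gene leaves must match the network's taxa")
  ge <- gene_struct(gene, taxa)
  leaves <- which(!is.na(dag$label))
  allele_leaf <- integer(length(taxa))
  allele_leaf[match(dag$label[leaves], taxa)] <- leaves
  tm <- cached_terms(dag, ge, allele_leaf, canonical_topology(gene))
  eval_terms(tm, dag)
}

#' Exact gene-tree topology distribution
#'
#' Probability of every rooted topology on the taxa of a network (or tree),
#' one allele per species.
#'
#' @param net a `phylo_network` (zero reticulations allowed).
#' @return named numeric vector of probabilities over all `(2n-3)!!` rooted
#'   topologies; names are canonical topology strings; the attribute
#'   `trees` holds the corresponding `rtree` objects.
#' @export
gene_tree_distribution <- function(net) {
  taxa <- network_taxa(net)
  tops <- enumerate_rooted_topologies(taxa)
  p <- vapply(tops, function(g) prob_gene_tree_on_network(net, g), 0)
  names(p) <- vapply(tops, canonical_topology, "")
  attr(p, "trees") <- tops
  p
}

#' Anomalous gene trees for a network
#'
#' A gene-tree topology is anomalous for a network (with its branch lengths
#' and inheritance probabilities) if it is strictly more probable than every
#' parental tree of the network. Ties at the maximum are reported and do not
#' count as anomalies.
#'
#' @param net a `phylo_network`.
#' @param samples allele counts used for the parental-tree set (default one
#'   per species; the probability computation itself is single-allele).
#' @param tol numeric tolerance for tie detection.
#' @return list with `anomalous` (logical), `argmax_topologies` (canonical
#'   strings of the most probable topologies), `parental` (canonical strings
#'   of the parental-tree set) and the full `distribution`.
#' @export
is_anomalous <- function(net, samples = NULL, tol = 1e-12) {
  p <- gene_tree_distribution(net)
  W <- vapply(parental_trees(net, samples), canonical_topology, "")
  pmax_all <- max(p)
  argmax <- names(p)[p >= pmax_all - tol]
  pmax_parental <- max(p[names(p) %in% W])
  anomalous <- any(p[!(names(p) %in% W)] > pmax_parental + tol)
  list(anomalous = anomalous, argmax_topologies = argmax,
       parental = sort(W), distribution = p)
}
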