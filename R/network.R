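# Rooted binary phylogenetic networks. A network is a DAG with one root
# (in 0 / out 2), internal tree nodes (in 1 / out 2), leaves (in 1 / out 0)
# and reticulation nodes (in 2 / out 1). Branch lengths are in coalescent
# units; each pair of edges into a reticulation node carries inheritance
# probabilities summing to one.

new_phylo_network <- function(label, edges, root) {
  net <- list(label = label, edges = edges, root = root)
  class(net) <- c("phylo_network", "list")
  net
}

#' Read a phylogenetic network from an extended (rich) Newick string
#'
#' Reticulation nodes are written with `#H` tags; the two occurrences of a
#' tag are merged into a single in-degree-2 node. Each reticulation edge may
#' carry an annotation `:length:support:gamma` whose third field is the
#' inheritance probability. If only one of the pair is annotated, the other
#' is set to its complement.
#'
#' @param text rich-Newick string, e.g.
#'   `"((A:1,((B:1,C:1):0.2)#H1:0::0.3):2,(D:1.2,#H1:0::0.7):2);"`.
#' @param strict require an inheritance probability on every reticulation.
#' @return an object of class `phylo_network` with components `label`
#'   (per-node taxon labels, `NA` for internal nodes), `edges` (data frame
#'   with columns `parent`, `child`, `length`, `gamma`) and `root`.
#' @export
parse_network <- function(text, strict = FALSE) {
  parsed <- parse_newick(text)
  env <- new.env(parent = emptyenv())
  env$label <- character(0)
  env$edges <- list()
  env$hybrids <- list() # tag -> node id
  add_node <- function(lab) {
    env$label <- c(env$label, lab)
    length(env$label)
  }
  add_edge <- function(parent, child, length, gamma) {
    env$edges[[length(env$edges) + 1L]] <-
      list(parent = parent, child = child, length = length, gamma = gamma)
  }
  build <- function(node) {
    if (!is.na(node$hybrid)) {
      tag <- node$hybrid
      if (is.null(env$hybrids[[tag]])) {
        env$hybrids[[tag]] <- add_node(NA_character_)
      }
      id <- env$hybrids[[tag]]
      for (ch in node$children) {
        chid <- build(ch)
        add_edge(id, chid, ch$length, NA_real_)
      }
      return(id)
    }
    id <- add_node(node$label)
    for (ch in node$children) {
      chid <- build(ch)
      add_edge(id, chid, ch$length, ch$gamma)
    }
    id
  }
  # gamma annotations live on the child ends of edges; thread the parsed
  # child's own annotation through build() by attaching when adding edges
  root <- build_root(parsed, build, add_node, add_edge, env)
  edges <- do.call(rbind, lapply(env$edges, as.data.frame))
  if (is.null(edges)) stop("network has no edges")
  net <- new_phylo_network(env$label, edges, root)
  validate_network(net, strict = strict)
}

build_root <- function(parsed, build, add_node, add_edge, env) {
  if (!is.na(parsed$hybrid)) stop("root cannot be a reticulation node")
  build(parsed)
}

validate_network <- function(net, strict = FALSE, gamma_tol = 1e-9) {
  e <- net$edges
  n <- length(net$label)
  indeg <- tabulate(e$child, n)
  outdeg <- tabulate(e$parent, n)
  roots <- which(indeg == 0)
  if (length(roots) != 1L) stop("network must have exactly one root")
  if (roots != net$root) stop("internal error: root mismatch")
  if (outdeg[net$root] != 2L) stop("root must have out-degree 2")
  for (v in seq_len(n)[-net$root]) {
    ok <- (indeg[v] == 1 && outdeg[v] %in% c(0L, 2L)) ||
      (indeg[v] == 2 && outdeg[v] == 1L)
    if (!ok) {
      stop("non-binary node: node ", v, " has in-degree ", indeg[v],
           " and out-degree ", outdeg[v])
    }
    if (outdeg[v] == 0 && is.na(net$label[v])) {
      stop("unlabeled leaf node ", v)
    }
  }
  labs <- net$label[!is.na(net$label)]
  if (anyDuplicated(labs)) stop("leaf labels must be distinct")
  # acyclicity by Kahn's algorithm
  deg <- indeg
  queue <- roots
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (w in e$child[e$parent == v]) {
      deg[w] <- deg[w] - 1L
      if (deg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (seen != n) stop("network contains a cycle")
  # reconcile inheritance probabilities per reticulation node
  for (v in which(indeg == 2)) {
    idx <- which(e$child == v)
    g <- e$gamma[idx]
    if (all(is.na(g))) {
      if (strict) stop("reticulation node ", v,
                       " lacks inheritance probabilities")
      next
    }
    if (sum(is.na(g)) == 1L) {
      known <- g[!is.na(g)]
      if (known < 0 || known > 1) {
        stop("inheritance probability outside [0,1]")
      }
      e$gamma[idx[is.na(g)]] <- 1 - known
    } else {
      if (any(g < 0 | g > 1)) stop("inheritance probability outside [0,1]")
      if (abs(sum(g) - 1) > gamma_tol) {
        stop("inheritance probabilities at a reticulation must sum to 1 (got ",
             sum(g), ")")
      }
    }
  }
  net$edges <- e
  net
}

net_children <- function(net, v) net$edges$child[net$edges$parent == v]

net_leaves <- function(net) which(!is.na(net$label))

#' Taxa of a network
#' @param net a `phylo_network`.
#' @return sorted character vector of leaf labels.
#' @export
network_taxa <- function(net) sort(net$label[!is.na(net$label)])

#' Number of reticulation nodes
#' @param net a `phylo_network`.
#' @return integer count of in-degree-2 nodes.
#' @export
n_reticulations <- function(net) {
  sum(tabulate(net$edges$child, length(net$label)) == 2L)
}

reticulation_nodes <- function(net) {
  which(tabulate(net$edges$child, length(net$label)) == 2L)
}

#' Write a network as an extended (rich) Newick string
#'
#' Inverse of [parse_network()] up to node ordering: topology, branch
#' lengths and inheritance probabilities round-trip.
#'
#' @param net a `phylo_network`.
#' @param digits significant digits for numeric fields.
#' @return a rich-Newick string.
#' @export
write_network <- function(net, digits = 12) {
  retics <- reticulation_nodes(net)
  tags <- setNames(paste0("H", seq_along(retics)), retics)
  written <- new.env(parent = emptyenv())
  fmt <- function(x) format(x, digits = digits)
  ann <- function(len, gamma) {
    if (is.na(len) && is.na(gamma)) return("")
    if (is.na(gamma)) return(paste0(":", fmt(len)))
    paste0(":", if (is.na(len)) "0" else fmt(len), "::", fmt(gamma))
  }
  rec <- function(v, len, gamma) {
    if (v %in% retics) {
      tag <- tags[[as.character(v)]]
      if (is.null(written[[tag]])) {
        written[[tag]] <- TRUE
        kids <- net$edges[net$edges$parent == v, , drop = FALSE]
        sub <- rec(kids$child[1], kids$length[1], NA_real_)
        return(paste0("(", sub, ")#", tag, ann(len, gamma)))
      }
      return(paste0("#", tag, ann(len, gamma)))
    }
    kids <- net$edges[net$edges$parent == v, , drop = FALSE]
    body <- if (nrow(kids) == 0L) {
      net$label[v]
    } else {
      paste0("(", paste(vapply(seq_len(nrow(kids)), function(i) {
        rec(kids$child[i], kids$length[i], kids$gamma[i])
      }, ""), collapse = ","), ")")
    }
    paste0(body, ann(len, gamma))
  }
  paste0(rec(net$root, NA_real_, NA_real_), ";")
}

#' @export
print.phylo_network <- function(x, ...) {
  cat("phylogenetic network:", length(network_taxa(x)), "taxa,",
      n_reticulations(x), "reticulation(s)\n")
  cat(write_network(x), "\n")
  invisible(x)
}

#' Trees displayed by a network
#'
#' A displayed tree is obtained by deleting, for each reticulation node,
#' exactly one of its incoming edges, then repeatedly contracting
#' degree-one nodes (branch lengths are summed through contractions). All
#' `2^k` deletion choices are taken and distinct topologies returned, so
#' the result has at most `2^k` trees for `k` reticulations.
#'
#' @param net a `phylo_network`.
#' @return list of `rtree` objects, deduplicated by topology and ordered by
#'   canonical string.
#' @export
displayed_trees <- function(net) {
  retics <- reticulation_nodes(net)
  k <- length(retics)
  choices <- if (k == 0) {
    list(integer(0))
  } else {
    parents_in <- lapply(retics, function(v) which(net$edges$child == v))
    do.call(expand.grid, c(lapply(parents_in, function(ix) ix),
                           KEEP.OUT.ATTRS = FALSE))
  }
  out <- list()
  if (k == 0) {
    out[[1]] <- network_to_rtree(net, keep = seq_len(nrow(net$edges)))
  } else {
    for (r in seq_len(nrow(choices))) {
      drop <- integer(0)
      for (j in seq_len(k)) {
        ix <- which(net$edges$child == retics[j])
        drop <- c(drop, setdiff(ix, choices[r, j]))
      }
      out[[length(out) + 1L]] <-
        network_to_rtree(net, keep = setdiff(seq_len(nrow(net$edges)), drop))
    }
  }
  dedupe_trees(out)
}

# Build an rtree from a network restricted to a subset of edges that forms
# a tree; degree-one nodes are contracted with lengths summed.
network_to_rtree <- function(net, keep) {
  e <- net$edges[keep, , drop = FALSE]
  rec <- function(v, len) {
    kids <- which(e$parent == v)
    if (length(kids) == 0L) return(new_rnode(net$label[v], len))
    if (length(kids) == 1L) {
      ch <- kids[1]
      nl <- if (is.na(len) || is.na(e$length[ch])) NA_real_ else
        len + e$length[ch]
      return(rec(e$child[ch], nl))
    }
    new_rnode(NA_character_, len,
              lapply(kids, function(i) rec(e$child[i], e$length[i])))
  }
  tr <- rec(net$root, NA_real_)
  class(tr) <- c("rtree", "list")
  tr
}

dedupe_trees <- function(trees) {
  keys <- vapply(trees, canonical_topology, "")
  trees <- trees[!duplicated(keys)]
  trees[order(vapply(trees, canonical_topology, ""))]
}

#' Convert a network to its MUL-tree
#'
#' Proceeding root-down, the subtree below each reticulation node is copied
#' to both of its parents and the reticulation edges removed, producing a
#' multi-labeled tree in which a taxon labels one leaf per root-to-leaf
#' path of the network. Degree-one nodes left at former reticulations are
#' contracted (lengths summed).
#'
#' @param net a `phylo_network`.
#' @return an `rtree` whose leaves may repeat labels.
#' @export
to_mul_tree <- function(net) {
  tr <- mul_expand(net, net$root, NA_real_, NA_real_, contract = TRUE)
  class(tr) <- c("rtree", "list")
  tr
}

# contract = FALSE keeps each former reticulation as a degree-one node
# carrying its inheritance probability in field `gamma`; used by the
# probability engine, where the gamma weight applies to lineages entering
# the reticulation edge *after* coalescence below it.
mul_expand <- function(net, v, len, gamma, contract) {
  kids <- which(net$edges$parent == v)
  if (length(kids) == 0L) {
    nd <- new_rnode(net$label[v], len)
    nd$gamma <- gamma
    return(nd)
  }
  if (length(kids) == 1L) { # reticulation node, one copy
    ch <- kids[1]
    if (contract) {
      nl <- if (is.na(len) || is.na(net$edges$length[ch])) NA_real_ else
        len + net$edges$length[ch]
      return(mul_expand(net, net$edges$child[ch], nl, gamma, contract))
    }
    nd <- new_rnode(NA_character_, len,
                    list(mul_expand(net, net$edges$child[ch],
                                    net$edges$length[ch], NA_real_,
                                    contract)))
    nd$gamma <- gamma
    return(nd)
  }
  nd <- new_rnode(NA_character_, len, lapply(kids, function(i) {
    mul_expand(net, net$edges$child[i], net$edges$length[i],
               net$edges$gamma[i], contract)
  }))
  nd$gamma <- gamma
  nd
}

#' Leaf multiplicities of the MUL-tree
#'
#' @param net a `phylo_network`.
#' @return named integer vector: for each taxon, the number of MUL-tree
#'   leaves carrying its label (equivalently, root-to-leaf paths).
#' @export
mul_leaf_multiplicity <- function(net) {
  labs <- tree_leaves(to_mul_tree(net))
  table(labs)[network_taxa(net)]
}

#' Per-species allele counts
#'
#' @param ... named integer arguments, e.g. `sample_config(A = 1, B = 2)`,
#'   or a single named vector.
#' @return named integer vector of allele counts (all at least 1).
#' @export
sample_config <- function(...) {
  args <- list(...)
  x <- if (length(args) == 1L && length(args[[1]]) > 1L) args[[1]] else
    unlist(args)
  x <- vapply(x, as.integer, integer(1))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("allele counts must be named by taxon")
  }
  if (any(x < 1L)) stop("allele counts must be at least 1")
  x
}

# utils::combn treats a scalar n as seq_len(n); guard against that.
combn_safe <- function(x, m) {
  if (length(x) == 1L) {
    if (m != 1L) stop("cannot choose ", m, " from 1 element")
    return(list(x))
  }
  utils::combn(x, m, simplify = FALSE)
}

#' Parental trees of a network
#'
#' The parental (weakly displayed) trees are the trees obtainable from the
#' network's MUL-tree by retaining, for each taxon `x`, between 1 and `a_x`
#' of its leaf copies and contracting. They model gene lineages that fail
#' to coalesce before reaching a reticulation and therefore can follow
#' different parents; the displayed trees are always a subset (single
#' allele per species).
#'
#' @param net a `phylo_network`.
#' @param samples named allele counts per taxon (see [sample_config()]);
#'   default one allele per species.
#' @param distinct return distinct topologies (default); if `FALSE`, one
#'   tree per retained-copy selection (embeddings).
#' @return list of `rtree` objects; the attribute `n_selections` counts the
#'   retained-copy selections enumerated.
#' @export
parental_trees <- function(net, samples = NULL, distinct = TRUE) {
  mul <- to_mul_tree(net)
  labs <- tree_leaves(mul)
  taxa <- network_taxa(net)
  if (is.null(samples)) samples <- sample_config(setNames(rep(1L, length(taxa)),
                                                          taxa))
  if (!all(taxa %in% names(samples))) stop("samples must cover every taxon")
  per_taxon <- lapply(taxa, function(tx) {
    pos <- which(labs == tx)
    sizes <- seq_len(min(samples[[tx]], length(pos)))
    unlist(lapply(sizes, function(s) {
      combn_safe(pos, s)
    }), recursive = FALSE)
  })
  grid <- do.call(expand.grid, c(lapply(per_taxon, seq_along),
                                 KEEP.OUT.ATTRS = FALSE))
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    keep <- unlist(lapply(seq_along(per_taxon), function(j) {
      per_taxon[[j]][[grid[r, j]]]
    }))
    out[[r]] <- prune_to_leaf_ids(mul, keep)
  }
  n_sel <- length(out)
  if (distinct) out <- dedupe_trees(out)
  attr(out, "n_selections") <- n_sel
  out
}
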