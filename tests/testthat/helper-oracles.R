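# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: path counting by DFS, Monte-Carlo coalescent
# races, exhaustive embedding search for deep-coalescence counts, and
# exhaustive enumeration of bipartite edge covers.

# Number of root-to-leaf paths per taxon in a network, by explicit DFS
# over the edge list (oracle for MUL-tree leaf multiplicities).
oracle_path_counts <- function(net) {
  e <- net$edges
  leaves <- which(!is.na(net$label))
  counts <- setNames(integer(length(leaves)), net$label[leaves])
  dfs <- function(v) {
    kids <- e$child[e$parent == v]
    if (length(kids) == 0L) {
      counts[net$label[v]] <<- counts[net$label[v]] + 1L
      return(invisible())
    }
    for (k in kids) dfs(k)
  }
  dfs(net$root)
  counts[sort(names(counts))]
}

# Monte-Carlo estimate of the probability that i lineages coalesce to j
# within time t, by simulating the exponential race.
oracle_gij_mc <- function(i, j, t, n = 1e5) {
  hits <- 0L
  for (r in seq_len(n)) {
    k <- i
    elapsed <- 0
    while (k > 1) {
      elapsed <- elapsed + stats::rexp(1, k * (k - 1) / 2)
      if (elapsed > t) break
      k <- k - 1L
    }
    if (k == j) hits <- hits + 1L
  }
  hits / n
}

# Leaf-label sets of all internal nodes of an rtree, as sorted "|" strings
# (independent of the package's cluster helper).
oracle_clades <- function(tree) {
  out <- list()
  rec <- function(node) {
    if (length(node$children) == 0L) return(node$label)
    below <- unlist(lapply(node$children, rec))
    out[[length(out) + 1L]] <<- sort(below)
    below
  }
  rec(tree)
  vapply(out, paste, "", collapse = "|")
}

# Minimum number of extra lineages of a gene tree in a species tree by
# exhaustive search over coalescent embeddings: every gene coalescence is
# assigned to a species-tree node (itself or an ancestor of the cluster's
# MRCA, consistent with the gene tree's own ordering), and the number of
# lineages entering each non-root species branch, minus one, is summed;
# the minimum over assignments is returned.
oracle_mdc <- function(species, gene) {
  sp_nodes <- list() # list of character vectors (leaf sets), root last
  rec_sp <- function(node) {
    if (length(node$children) == 0L) return(node$label)
    below <- unlist(lapply(node$children, rec_sp))
    sp_nodes[[length(sp_nodes) + 1L]] <<- sort(below)
    below
  }
  all_leaves <- sort(rec_sp(species))
  leaf_nodes <- as.list(all_leaves)
  nodes <- c(leaf_nodes, sp_nodes) # clusters of every species node
  is_root <- vapply(nodes, function(x) identical(sort(x), all_leaves), TRUE)
  supset <- function(a, b) all(b %in% a)
  ge_events <- list()
  rec_ge <- function(node) {
    if (length(node$children) == 0L) return(node$label)
    below <- unlist(lapply(node$children, rec_ge))
    ge_events[[length(ge_events) + 1L]] <<- sort(below) # postorder
    below
  }
  rec_ge(gene)
  m <- length(ge_events)
  cand <- lapply(ge_events, function(cl) {
    which(vapply(nodes, supset, TRUE, b = cl))
  })
  # gene-tree parent relations among events (postorder: parents later)
  parent_of <- rep(NA_integer_, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j && supset(ge_events[[j]], ge_events[[i]]) &&
          length(ge_events[[j]]) > length(ge_events[[i]])) {
        if (is.na(parent_of[i]) ||
            length(ge_events[[j]]) < length(ge_events[[parent_of[i]]])) {
          parent_of[i] <- j
        }
      }
    }
  }
  best <- Inf
  assign <- integer(m)
  try_event <- function(e) {
    if (e > m) {
      xl <- 0L
      for (b in seq_along(nodes)) {
        if (is_root[b]) next
        # lineages exiting the branch above node b: leaves below it minus
        # coalescences that happened at or below it
        exiting <- sum(all_leaves %in% nodes[[b]]) -
          sum(vapply(seq_len(m), function(i) {
            supset(nodes[[b]], nodes[[assign[i]]])
          }, TRUE))
        xl <- xl + (exiting - 1L)
      }
      best <<- min(best, xl)
      return(invisible())
    }
    for (b in cand[[e]]) {
      ok <- TRUE
      for (i in seq_len(e - 1L)) {
        if (!is.na(parent_of[i]) && parent_of[i] == e) {
          if (!supset(nodes[[b]], nodes[[assign[i]]])) { ok <- FALSE; break }
        }
      }
      if (ok) { assign[e] <<- b; try_event(e + 1L) }
    }
  }
  try_event(1L)
  best
}

# Exhaustive minimum total weight over edge covers: every vertex picks one
# incident edge; the union over all pick combinations covers all minimal
# covers, so the minimum is exact.
oracle_edge_cover_weight <- function(W) {
  p <- nrow(W); q <- ncol(W)
  best <- Inf
  grid_rows <- do.call(expand.grid, rep(list(seq_len(q)), p))
  grid_cols <- do.call(expand.grid, rep(list(seq_len(p)), q))
  for (r in seq_len(nrow(grid_rows))) {
    for (cidx in seq_len(nrow(grid_cols))) {
      edges <- unique(rbind(
        cbind(seq_len(p), as.integer(grid_rows[r, ])),
        cbind(as.integer(grid_cols[cidx, ]), seq_len(q))))
      best <- min(best, sum(W[edges]))
    }
  }
  best
}

# Convenient fixtures
example_network_text <- function() {
  "((A:1.2,((B:1,C:1):0.2)#H1:0::0.3):2,(D:1.2,#H1:0::0.7):2);"
}
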