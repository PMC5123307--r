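# Recovering a network's parental trees from gene trees. The network is a
# mixture model whose components are its parental trees; gene trees are
# clustered (RF distances -> 3-D classical MDS -> k-means, with the number
# of clusters chosen by average silhouette on the RF distances), a species
# tree is inferred per cluster by minimizing deep coalescence, and the
# inferred set is scored against a reference set by a minimum-weight edge
# cover with normalized-RF weights.

#' Pairwise rooted Robinson-Foulds distance matrix
#'
#' @param trees list of `rtree` objects on a shared leaf set.
#' @return symmetric integer matrix with zero diagonal.
#' @export
rf_matrix <- function(trees) {
  n <- length(trees)
  keys <- vapply(trees, canonical_topology, "")
  uk <- unique(keys)
  reps <- trees[match(uk, keys)]
  m <- length(uk)
  base <- matrix(0, m, m)
  if (m > 1) {
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        base[i, j] <- base[j, i] <- rooted_rf(reps[[i]], reps[[j]])
      }
    }
  }
  idx <- match(keys, uk)
  D <- base[idx, idx, drop = FALSE]
  dimnames(D) <- NULL
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2/2`, takes the top eigenpairs and scales by the
#' square roots of the eigenvalues; dimensions with non-positive
#' eigenvalues are dropped and padded with zeros so the result always has
#' `dim` columns.
#'
#' @param dist symmetric nonnegative matrix with zero diagonal.
#' @param dim embedding dimension (3 in the parental-tree pipeline).
#' @return numeric matrix, one row per object, `dim` columns.
#' @export
classical_mds <- function(dist, dim = 3) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(dist)
  dim <- min(dim, n - 1)
  if (all(dist == 0)) return(matrix(0, n, max(dim, 1)))
  fit <- stats::cmdscale(stats::as.dist(dist), k = dim, eig = TRUE)
  X <- fit$points
  if (ncol(X) < dim) {
    X <- cbind(X, matrix(0, n, dim - ncol(X)))
  }
  unname(X)
}

#' k-means clustering of embedded gene trees
#'
#' Lloyd's algorithm with multiple random restarts (via [stats::kmeans()]),
#' returning the labeling with the lowest within-cluster sum of squares.
#' Deterministic under a fixed RNG state.
#'
#' @param points numeric matrix of coordinates.
#' @param k number of clusters, `1 <= k <=` number of distinct points.
#' @param nstart random restarts.
#' @param iter.max maximum Lloyd iterations.
#' @return list with `labels` (integer vector) and `wcss`.
#' @export
kmeans_cluster <- function(points, k, nstart = 10, iter.max = 300) {
  n <- nrow(points)
  if (k > n) stop("k cannot exceed the number of points")
  if (k == 1) {
    ctr <- colMeans(points)
    return(list(labels = rep(1L, n),
                wcss = sum(sweep(points, 2, ctr)^2)))
  }
  fit <- suppressWarnings(
    stats::kmeans(points, centers = k, nstart = nstart,
                  iter.max = iter.max))
  list(labels = as.integer(fit$cluster), wcss = fit$tot.withinss)
}

#' Choose the number of clusters by average silhouette on tree distances
#'
#' Clusters are formed by k-means in the MDS embedding for each candidate
#' `k`, but each labeling is scored by its mean silhouette width computed
#' from the original RF distance matrix; the `k` with the maximum mean
#' silhouette wins, ties broken toward smaller `k`.
#'
#' @param points MDS coordinates (rows match `dist`).
#' @param dist RF distance matrix used for the silhouette.
#' @param kmax largest `k` tried (candidates `2..kmax`, capped at the
#'   number of distinct embedded points).
#' @param nstart k-means restarts.
#' @return list with `k`, `labels`, `sil` (mean silhouette per candidate
#'   `k`) and `labelings`.
#' @export
silhouette_select_k <- function(points, dist, kmax = 10, nstart = 10) {
  n <- nrow(points)
  n_distinct <- nrow(unique(points))
  ks <- seq(2L, max(2L, min(kmax, n_distinct, n - 1L)))
  labelings <- list(); sils <- numeric(0)
  for (k in ks) {
    lab <- kmeans_cluster(points, k, nstart = nstart)$labels
    sw <- cluster::silhouette(lab, dmatrix = as.matrix(dist))
    labelings[[as.character(k)]] <- lab
    sils <- c(sils, mean(sw[, "sil_width"]))
  }
  best <- ks[which.max(sils)] # which.max takes the first (smallest k) tie
  list(k = best, labels = labelings[[as.character(best)]],
       sil = setNames(sils, ks), labelings = labelings)
}

#' Deep-coalescence score of a gene tree on a species tree
#'
#' The number of extra lineages: for each nontrivial cluster `C` of the
#' species tree, the number of maximal gene-tree clades whose leaves fall
#' inside `C`, minus one, summed over clusters. Zero iff the (binary,
#' single-allele) topologies agree.
#'
#' @param species,gene `rtree` objects on the same leaf set.
#' @return nonnegative integer.
#' @export
#' @examples
#' mdc_score(parse_tree("((a,b),(c,d));"), parse_tree("((a,c),(b,d));")) # 2
mdc_score <- function(species, gene) {
  ls <- sort(tree_leaves(species))
  if (!identical(ls, sort(tree_leaves(gene)))) stop("leaf sets differ")
  full <- paste(ls, collapse = "|")
  clusters <- setdiff(tree_cluster_strings(species), full)
  total <- 0L
  for (cl in clusters) {
    members <- strsplit(cl, "|", fixed = TRUE)[[1]]
    total <- total + count_max_clades(gene, members) - 1L
  }
  total
}

# Number of maximal clades of `tree` whose leaf sets lie entirely within
# `members` and jointly cover it (= lineages exiting that species branch).
count_max_clades <- function(tree, members) {
  count <- 0L
  rec <- function(node) {
    # returns TRUE if the subtree's leaves are all within `members`
    if (is_leaf(node)) return(node$label %in% members)
    inside <- vapply(node$children, rec, TRUE)
    if (all(inside)) return(TRUE)
    count <<- count + sum(inside)
    FALSE
  }
  if (rec(tree)) count <- count + 1L # whole tree inside (members = all)
  count
}

#' Exact minimize-deep-coalescence species tree
#'
#' Exhaustively scores every rooted binary topology on the gene trees'
#' leaf set and returns one minimizing the total deep-coalescence score.
#' Intended for small taxon sets (at most 8 taxa, `(2n-3)!!` candidates);
#' ties are broken by canonical Newick order and reported.
#'
#' @param genes nonempty list of `rtree` objects on a shared leaf set.
#' @return list with `tree` (the optimum), `score`, and `ties` (canonical
#'   strings of all optima).
#' @export
mdc_species_tree <- function(genes) {
  if (length(genes) == 0L) stop("no gene trees")
  labels <- sort(tree_leaves(genes[[1]]))
  n <- length(labels)
  if (n > 8L) stop("exhaustive MDC limited to 8 taxa")
  # candidate topologies and their nontrivial cluster bitmasks, cached per
  # label set (shared by every call on the same taxa)
  ckey <- paste(labels, collapse = "|")
  cand <- .mdc_cache[[ckey]]
  if (is.null(cand)) {
    trees <- enumerate_rooted_topologies(labels)
    clusters <- lapply(trees, function(tr) {
      masks <- tree_mask_table(tr, labels)
      m <- masks$mask[masks$internal & masks$mask != masks$full]
      m
    })
    cand <- list(trees = trees, clusters = clusters)
    .mdc_cache[[ckey]] <- cand
  }
  # weighted extra-lineage count per candidate species cluster, computed
  # once from the unique gene topologies
  keys <- vapply(genes, canonical_topology, "")
  tab <- table(keys)
  reps <- genes[match(names(tab), keys)]
  gtabs <- lapply(reps, tree_mask_table, labels = labels)
  all_C <- sort(unique(unlist(cand$clusters)))
  XL <- setNames(numeric(length(all_C)), all_C)
  for (gi in seq_along(gtabs)) {
    gt <- gtabs[[gi]]
    w <- as.numeric(tab[gi])
    for (ci in seq_along(all_C)) {
      C <- all_C[ci]
      inC <- bitwAnd(gt$mask, C) == gt$mask
      pout <- is.na(gt$pmask) | bitwAnd(gt$pmask, C) != gt$pmask
      XL[ci] <- XL[ci] + w * (sum(inC & pout) - 1L)
    }
  }
  scores <- vapply(cand$clusters, function(cl) {
    sum(XL[as.character(cl)])
  }, 0)
  best <- min(scores)
  ties <- which(scores == best) # candidates are in canonical order already
  list(tree = cand$trees[[ties[1]]], score = best,
       ties = vapply(cand$trees[ties], canonical_topology, ""))
}

.mdc_cache <- new.env(parent = emptyenv())

# Bitmask table of a tree: one row per node with its leaf-set mask, its
# parent's mask (NA at the root) and whether it is internal.
tree_mask_table <- function(tree, labels) {
  nodes <- list()
  walk <- function(node) {
    if (is_leaf(node)) {
      m <- bitwShiftL(1L, match(node$label, labels) - 1L)
      nodes[[length(nodes) + 1L]] <<- list(mask = m, kids = integer(0))
      return(length(nodes))
    }
    kid_ids <- vapply(node$children, walk, 0L)
    m <- 0L
    for (k in kid_ids) m <- bitwOr(m, nodes[[k]]$mask)
    nodes[[length(nodes) + 1L]] <<- list(mask = m, kids = kid_ids)
    length(nodes)
  }
  root <- walk(tree)
  mask <- vapply(nodes, `[[`, 0L, "mask")
  pmask <- rep(NA_integer_, length(nodes))
  for (i in seq_along(nodes)) {
    for (k in nodes[[i]]$kids) pmask[k] <- mask[i]
  }
  internal <- vapply(nodes, function(x) length(x$kids) > 0L, TRUE)
  list(mask = mask, pmask = pmask, internal = internal,
       full = mask[root])
}

#' Minimum-weight edge-cover error between two tree sets
#'
#' Builds the complete bipartite graph between the inferred and reference
#' sets with edge weights equal to the rooted RF distance normalized by
#' its maximum `2(n-2)`, finds a minimum-weight edge cover exactly (via
#' the classical reduction to maximum-weight matching on the savings
#' graph), and returns the mean weight of the cover's edges.
#'
#' @param inferred,reference nonempty lists of `rtree` objects on a shared
#'   leaf set.
#' @return list with `error` (mean normalized RF over cover edges, in
#'   `[0,1]`), `cover` (two-column matrix of index pairs) and `weight`
#'   (total cover weight).
#' @export
edge_cover_error <- function(inferred, reference) {
  if (length(inferred) == 0L || length(reference) == 0L) {
    stop("tree sets must be nonempty")
  }
  p <- length(inferred); q <- length(reference)
  W <- matrix(0, p, q)
  for (i in seq_len(p)) {
    for (j in seq_len(q)) {
      W[i, j] <- rooted_rf(inferred[[i]], reference[[j]], normalized = TRUE)
    }
  }
  cover <- min_weight_edge_cover(W)
  wt <- sum(W[cover])
  list(error = wt / nrow(cover), cover = cover, weight = wt)
}

# Minimum-weight edge cover of a complete bipartite graph: every minimal
# cover is the union of a matching M and, for each unmatched vertex, its
# cheapest incident edge. So MWEC = sum of per-vertex minima minus the
# best total "savings" over matchings, where matching (i, j) saves
# m_i + n_j - W[i, j].
min_weight_edge_cover <- function(W) {
  p <- nrow(W); q <- ncol(W)
  mi <- apply(W, 1, min); nj <- apply(W, 2, min)
  gain <- outer(mi, nj, "+") - W
  # maximum-weight matching by bitmask DP over the smaller side
  flip <- q > p
  G <- if (flip) t(gain) else gain
  a <- nrow(G); b <- ncol(G)
  memo <- new.env(parent = emptyenv())
  best <- function(i, mask) {
    if (i > a) return(list(val = 0, picks = list()))
    key <- paste0(i, "_", mask)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- best(i + 1L, mask) # leave row i unmatched
    for (j in seq_len(b)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L && G[i, j] > 0) {
        sub <- best(i + 1L, bitwOr(mask, bit))
        if (sub$val + G[i, j] > res$val) {
          res <- list(val = sub$val + G[i, j],
                      picks = c(list(c(i, j)), sub$picks))
        }
      }
    }
    memo[[key]] <- res
    res
  }
  sol <- best(1L, 0L)
  matched <- do.call(rbind, sol$picks)
  if (flip && !is.null(matched)) matched <- matched[, 2:1, drop = FALSE]
  cover <- matrix(integer(0), 0, 2)
  if (!is.null(matched)) cover <- matched
  mrow <- cover[, 1]; mcol <- cover[, 2]
  for (i in setdiff(seq_len(p), mrow)) {
    cover <- rbind(cover, c(i, which.min(W[i, ])))
  }
  for (j in setdiff(seq_len(q), mcol)) {
    cover <- rbind(cover, c(which.min(W[, j]), j))
  }
  cover
}

#' Parental-tree recovery by gene-tree clustering
#'
#' The full pipeline: pairwise rooted RF distances, 3-D classical MDS,
#' k-means for `k = 2..kmax`, silhouette-based selection of `k` (on the RF
#' distances), exact MDC species-tree inference per cluster, and (when a
#' reference set is given) the minimum-weight edge-cover error between the
#' inferred trees and the reference. If the input contains a single
#' distinct topology the clustering step is skipped and that topology is
#' returned as the lone cluster.
#'
#' @param genes list of at least 11 gene trees (topologies suffice).
#' @param reference optional list of reference trees (e.g. the true
#'   parental trees) to score against.
#' @param kmax largest number of clusters tried.
#' @param nstart k-means restarts.
#' @return object of class `cluster_inference`: list with `k`, `labels`,
#'   `sil`, `trees` (per-cluster MDC trees), `scores` (per-cluster MDC
#'   scores), `rf` (distance matrix), `mds` (embedding) and, with a
#'   reference, `error` (edge-cover error in `[0,1]`).
#' @export
cluster_infer_pipeline <- function(genes, reference = NULL, kmax = 10,
                                   nstart = 10) {
  keys <- vapply(genes, canonical_topology, "")
  if (length(unique(keys)) == 1L) {
    res <- list(k = 1L, labels = rep(1L, length(genes)), sil = NULL,
                trees = list(genes[[1]]), scores = 0, rf = NULL, mds = NULL)
  } else {
    if (length(genes) < 11L) {
      stop("need at least 11 gene trees for k up to 10")
    }
    D <- rf_matrix(genes)
    X <- classical_mds(D, dim = 3)
    sel <- silhouette_select_k(X, D, kmax = kmax, nstart = nstart)
    trees <- list(); scores <- numeric(0)
    for (cl in seq_len(sel$k)) {
      fit <- mdc_species_tree(genes[sel$labels == cl])
      trees[[cl]] <- fit$tree
      scores[cl] <- fit$score
    }
    res <- list(k = sel$k, labels = sel$labels, sil = sel$sil,
                trees = trees, scores = scores, rf = D, mds = X)
  }
  if (!is.null(reference)) {
    res$error <- edge_cover_error(res$trees, reference)$error
  }
  class(res) <- c("cluster_inference", "list")
  res
}

#' @export
print.cluster_inference <- function(x, ...) {
  cat("gene-tree clustering inference\n")
  cat("  clusters:", x$k, "\n")
  for (i in seq_along(x$trees)) {
    cat("  tree", i, ":", canonical_topology(x$trees[[i]]),
        "(size", sum(x$labels == i), ")\n")
  }
  if (!is.null(x$error)) cat("  edge-cover error:", x$error, "\n")
  invisible(x)
}

#' Species tree from median gene-tree distances
#'
#' For every pair of taxa, the median over loci of the gene-tree path
#' distance between them is taken, and a tree is built from the median
#' matrix by average-linkage agglomerative clustering (coalescent-unit
#' gene trees are ultrametric in expectation, so a clock-based method
#' fits).
#'
#' @param genes list of gene trees with branch lengths, one allele per
#'   species.
#' @return list with `tree` (an ultrametric `rtree`) and `dist` (the
#'   median distance matrix).
#' @export
median_distance_tree <- function(genes) {
  labs <- sort(tree_leaves(genes[[1]]))
  n <- length(labs)
  stacks <- array(NA_real_, c(n, n, length(genes)))
  for (g in seq_along(genes)) {
    if (!all_lengths_present(genes[[g]])) {
      stop("gene trees must carry branch lengths")
    }
    D <- tree_leaf_distances(genes[[g]])
    stacks[, , g] <- D[labs, labs]
  }
  M <- apply(stacks, c(1, 2), stats::median)
  dimnames(M) <- list(labs, labs)
  hc <- stats::hclust(stats::as.dist(M), method = "average")
  list(tree = hclust_to_rtree(hc), dist = M)
}

all_lengths_present <- function(tree, root = TRUE) {
  if (!root && is.na(tree$length)) return(FALSE)
  all(vapply(tree$children, all_lengths_present, TRUE, root = FALSE))
}

hclust_to_rtree <- function(hc) {
  build <- function(i) {
    if (i < 0) {
      nd <- new_rnode(hc$labels[-i])
      attr(nd, "height") <- 0
      return(nd)
    }
    l <- build(hc$merge[i, 1]); r <- build(hc$merge[i, 2])
    h <- hc$height[i] / 2
    l$length <- h - attr(l, "height")
    r$length <- h - attr(r, "height")
    nd <- new_rnode(children = list(l, r))
    attr(nd, "height") <- h
    nd
  }
  tr <- build(nrow(hc$merge))
  attr(tr, "height") <- NULL
  class(tr) <- c("rtree", "list")
  tr
}

#' Fraction of inferred trees that are displayed by a network
#'
#' The backbone-recovery accuracy measure: the proportion of per-dataset
#' inferred species trees whose topology is one of the network's displayed
#' trees.
#'
#' @param inferred list of `rtree` objects (one per dataset).
#' @param displayed list of displayed trees (see [displayed_trees()]).
#' @return fraction in `[0,1]`.
#' @export
backbone_accuracy <- function(inferred, displayed) {
  disp <- vapply(displayed, canonical_topology, "")
  mean(vapply(inferred, canonical_topology, "") %in% disp)
}
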