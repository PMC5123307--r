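test_that("RF matrices are symmetric with zero diagonal", {
  t1 <- parse_tree("((a,b),(c,d));")
  t2 <- parse_tree("((a,c),(b,d));")
  D0 <- rf_matrix(rep(list(t1), 5))
  expect_true(all(D0 == 0))
  D <- rf_matrix(c(rep(list(t1), 3), rep(list(t2), 2)))
  expect_true(all(D[1:3, 4:5] == 4))
  expect_true(all(D[1:3, 1:3] == 0) && all(D[4:5, 4:5] == 0))
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("classical MDS recovers exactly embeddable configurations", {
  # a unit square is flat: pairwise distances reproduce exactly
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  D <- as.matrix(dist(pts))
  X <- classical_mds(D, dim = 3)
  expect_equal(as.matrix(dist(X)), D, tolerance = 1e-9,
               ignore_attr = TRUE)
  # zero distances collapse to the origin
  expect_true(all(classical_mds(matrix(0, 4, 4), dim = 3) == 0))
  # relabeling the objects relabels the solution (distances preserved)
  perm <- c(3, 1, 4, 2)
  Xp <- classical_mds(D[perm, perm], dim = 3)
  expect_equal(as.matrix(dist(Xp)), D[perm, perm], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("k-means recovers planted blobs and k = 1 is the grand mean", {
  set.seed(4)
  pts <- rbind(matrix(rnorm(40, 0), ncol = 2),
               matrix(rnorm(40, 8), ncol = 2))
  fit <- kmeans_cluster(pts, 2)
  expect_identical(length(unique(fit$labels[1:20])), 1L)
  expect_identical(length(unique(fit$labels[21:40])), 1L)
  expect_false(fit$labels[1] == fit$labels[40])
  one <- kmeans_cluster(pts, 1)
  expect_equal(one$wcss, sum(scale(pts, scale = FALSE)^2))
  expect_error(kmeans_cluster(pts, 41), "exceed")
})

test_that("silhouette selection finds planted topology groups", {
  labels6 <- letters[1:6]
  tops <- enumerate_rooted_topologies(labels6)
  set.seed(13)
  # two balanced distinct topologies: perfect silhouette at k = 2
  genes2 <- c(rep(tops[1], 10), rep(tops[60], 10))
  D2 <- rf_matrix(genes2)
  X2 <- classical_mds(D2, 3)
  sel2 <- silhouette_select_k(X2, D2)
  expect_identical(sel2$k, 2L)
  expect_equal(max(sel2$sil), 1)
  # four well-separated groups (each one exact topology, no noise)
  picks <- c(1, 30, 60, 100)
  genes4 <- unlist(lapply(picks, function(i) rep(tops[i], 8)),
                   recursive = FALSE)
  D4 <- rf_matrix(genes4)
  sel4 <- silhouette_select_k(classical_mds(D4, 3), D4)
  expect_identical(sel4$k, 4L)
})

test_that("deep-coalescence scores match the embedding-search oracle", {
  sp_sym <- parse_tree("((a,b),(c,d));")
  expect_identical(mdc_score(sp_sym, parse_tree("((a,c),(b,d));")), 2L)
  expect_identical(mdc_score(sp_sym, sp_sym), 0L)
  tops <- enumerate_rooted_topologies(letters[1:4])
  for (sp in tops) {
    for (ge in tops) {
      expect_identical(as.integer(mdc_score(sp, ge)),
                       as.integer(oracle_mdc(sp, ge)))
    }
  }
})

test_that("exact MDC species-tree search recovers the truth", {
  t0 <- parse_tree("((a,b),(c,d));")
  fit <- mdc_species_tree(rep(list(t0), 7))
  expect_identical(canonical_topology(fit$tree), canonical_topology(t0))
  expect_identical(fit$score, 0)
  # simulated gene trees on a well-resolved species tree
  tre <- parse_network("(((A:1,B:1):1.2,C:2.2):1.1,D:3.3);")
  genes <- simulate_gene_trees(tre, 250, seed = 17)
  fit2 <- mdc_species_tree(genes)
  expect_identical(canonical_topology(fit2$tree), "(((A,B),C),D)")
  expect_error(mdc_species_tree(list()), "no gene trees")
})

test_that("minimum-weight edge cover matches exhaustive enumeration", {
  t1 <- parse_tree("((a,b),(c,d));")
  t2 <- parse_tree("((a,c),(b,d));")
  expect_equal(edge_cover_error(list(t1), list(t1))$error, 0)
  expect_equal(edge_cover_error(list(t1), list(t2))$error, 1)
  # random weight matrices against the pick-an-edge oracle
  set.seed(23)
  for (r in 1:12) {
    p <- sample(2:4, 1); q <- sample(2:3, 1)
    W <- matrix(round(runif(p * q), 2), p, q)
    cover <- netcoal:::min_weight_edge_cover(W)
    expect_equal(sum(W[cover]), oracle_edge_cover_weight(W),
                 tolerance = 1e-9)
    expect_setequal(unique(cover[, 1]), seq_len(p))
    expect_setequal(unique(cover[, 2]), seq_len(q))
  }
})

test_that("the clustering pipeline separates a clean two-component mixture", {
  tops <- enumerate_rooted_topologies(letters[1:6])
  genes <- c(rep(tops[2], 12), rep(tops[90], 12))
  fit <- cluster_infer_pipeline(genes,
                                reference = c(tops[2], tops[90]))
  expect_identical(fit$k, 2L)
  expect_equal(fit$error, 0)
  expect_setequal(vapply(fit$trees, canonical_topology, ""),
                  c(canonical_topology(tops[[2]]),
                    canonical_topology(tops[[90]])))
  # degenerate single-topology input short-circuits
  solo <- cluster_infer_pipeline(rep(tops[5], 30))
  expect_identical(solo$k, 1L)
  expect_identical(canonical_topology(solo$trees[[1]]),
                   canonical_topology(tops[[5]]))
})

test_that("median-distance reconstruction follows the majority signal", {
  all_same <- simulate_gene_trees(
    parse_network("(((A:1,B:1):1000,C:1001):1000,D:2001);"), 20, seed = 5)
  md <- median_distance_tree(all_same)
  expect_identical(canonical_topology(md$tree), "(((A,B),C),D)")
  expect_true(isSymmetric(md$dist))
  # 60/40 mixture of two topologies with separated node heights: the
  # per-pair medians reflect the 60% component
  conc <- parse_tree("((A:1,(B:0.5,C:0.5):0.5):3,D:4);")
  disc <- parse_tree("(A:4,((B:0.5,C:0.5):1.5,D:2):2);")
  md2 <- median_distance_tree(c(rep(list(conc), 6), rep(list(disc), 4)))
  expect_identical(canonical_topology(md2$tree), "(((B,C),A),D)")
  expect_error(median_distance_tree(list(parse_tree("((A,B),C);"))),
               "branch lengths")
})

test_that("backbone accuracy is a plain fraction", {
  disp <- displayed_trees(symmetric_hybrid_network(1, 0.5, gamma = 0.3))
  inf <- c(disp[1], disp[2], list(parse_tree("((A,D),(B,C));")))
  expect_equal(backbone_accuracy(inf, disp), 2 / 3)
  expect_equal(backbone_accuracy(disp, disp), 1)
})
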