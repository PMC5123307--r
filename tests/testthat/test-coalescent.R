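# The probability engine has two independent routes on the symmetric
# hybrid network: the general history enumeration on the network DAG and
# the hand-written closed forms; they must agree to near machine
# precision everywhere.

test_that("coalescent transition probabilities behave", {
  expect_equal(gij(2, 2, 0), 1)
  expect_equal(gij(2, 1, 1), 1 - exp(-1))
  expect_equal(gij(2, 2, 1), exp(-1))
  expect_equal(gij(2, 1, Inf), 1)
  expect_equal(gij(3, 3, 0.4), exp(-3 * 0.4))
  expect_equal(gij(3, 2, 0.5), 1.5 * (exp(-0.5) - exp(-1.5)))
  for (t in c(0.1, 0.7, 3)) {
    for (i in 2:5) {
      expect_equal(sum(vapply(1:i, function(j) gij(i, j, t), 0)), 1)
    }
  }
  expect_error(gij(2, 3, 1), "j <= i")
  # Monte-Carlo race oracle
  set.seed(31)
  mc <- oracle_gij_mc(3, 2, 0.5, n = 4e4)
  p <- gij(3, 2, 0.5)
  expect_lt(abs(mc - p), 3 * sqrt(p * (1 - p) / 4e4))
})

test_that("species-tree gene-tree probabilities match classical forms", {
  # star tree: all three topologies equally likely
  star <- parse_tree("((A:0,B:0):0,C:0);")
  for (g in enumerate_rooted_topologies(c("A", "B", "C"))) {
    expect_equal(prob_gene_tree_on_tree(star, g), 1 / 3)
  }
  sp <- parse_tree("((A:1,B:1):1,C:2);")
  expect_equal(prob_gene_tree_on_tree(sp, parse_tree("((A,B),C);")),
               1 - 2 / 3 * exp(-1), tolerance = 1e-12)
  expect_equal(prob_gene_tree_on_tree(sp, parse_tree("((A,C),B);")),
               exp(-1) / 3, tolerance = 1e-12)
  # distributions normalize on random 4-taxon species trees
  set.seed(9)
  tops <- enumerate_rooted_topologies(c("A", "B", "C", "D"))
  for (r in 1:3) {
    sp4 <- parse_tree(sprintf("(((A:1,B:1):%.3f,C:2):%.3f,D:3);",
                              runif(1, 0.05, 2), runif(1, 0.05, 2)))
    p <- vapply(tops, function(g) prob_gene_tree_on_tree(sp4, g), 0)
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
})

test_that("network distribution reduces to the displayed tree at gamma 0/1", {
  for (gam in c(0, 1)) {
    net <- symmetric_hybrid_network(x = 0.8, y = 0.4, w = 0.2, gamma = gam)
    keep <- if (gam == 1) "(((B,C),A),D)" else "(((B,C),D),A)"
    disp <- displayed_trees(net)
    tr <- disp[[which(vapply(disp, canonical_topology, "") == keep)]]
    p_net <- gene_tree_distribution(net)
    for (g in attr(p_net, "trees")) {
      expect_equal(prob_gene_tree_on_network(net, g),
                   prob_gene_tree_on_tree(tr, g), tolerance = 1e-12)
    }
  }
})

test_that("engine equals the closed forms on the symmetric network", {
  p_gen <- gene_tree_distribution(
    symmetric_hybrid_network(x = 0.3, y = 0.2, w = 0, gamma = 0.5))
  p_cf <- closed_form_probs(0.3, 0.2, 0.5)
  expect_lt(max(abs(p_gen[names(p_cf)] - p_cf)), 1e-10)
  expect_equal(sum(p_cf), 1, tolerance = 1e-12)
  # closed-form symmetries printed in the table
  for (r in 1:5) {
    set.seed(r)
    p <- closed_form_probs(runif(1, 0.01, 3), runif(1, 0.01, 3), runif(1))
    expect_equal(p[[3]], p[[4]])
    expect_equal(p[[5]], p[[6]])
    expect_equal(p[[7]], p[[8]])
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("closed-form rows specialize correctly at gamma 0 and 1", {
  x <- 0.9; y <- 0.35
  # the (((A,D),B),C)-style row collapses to g22(y) g33(x)/18
  for (gam in c(0, 1)) {
    p <- closed_form_probs(x, y, gam)
    expect_equal(p[[12]], gij(2, 2, y) * gij(3, 3, x) / 6 / 3,
                 tolerance = 1e-12)
  }
  # backbone row at gamma = 1
  p1 <- closed_form_probs(x, y, 1)
  expected <- gij(2, 1, y) * (gij(2, 1, x) + gij(2, 2, x) / 3) +
    gij(2, 2, y) * (gij(3, 1, x) / 3 + gij(3, 2, x) / 9 +
                      gij(3, 3, x) / 18)
  expect_equal(p1[[1]], expected, tolerance = 1e-12)
  # and equals the displayed-tree computation
  disp <- displayed_trees(symmetric_hybrid_network(x = x, y = y, gamma = 1))
  tr <- disp[[which(vapply(disp, canonical_topology, "") ==
                      "(((B,C),A),D)")]]
  expect_equal(p1[[1]],
               prob_gene_tree_on_tree(tr, parse_tree("(((B,C),A),D);")),
               tolerance = 1e-12)
})

test_that("long-root limits match the limiting forms", {
  for (gam in c(0.05, 0.3, 0.5)) {
    for (y in c(0.1, 0.5, 1.5)) {
      expect_lt(max(abs(closed_form_probs(50, y, gam) -
                          limit_probs(y, gam))), 1e-6)
    }
  }
  lim <- limit_probs(0, 0.5)
  expect_equal(lim[[3]], 0.25)       # gamma(1-gamma) e^0
  expect_equal(lim[[9]], 0)          # ((A,D),(B,C)) loses all mass
  expect_equal(limit_probs(30, 0.3)[[1]], 0.3, tolerance = 1e-9)
  expect_equal(sum(limit_probs(0.7, 0.4)), 1, tolerance = 1e-12)
})

test_that("only eight topologies keep mass when the root branches are long", {
  net <- symmetric_hybrid_network(x = 1000, y = 0.5, w = 0, gamma = 0.5)
  p <- gene_tree_distribution(net)
  expect_identical(sum(p > 1e-9), 8L)
  canon <- hybrid_gene_topologies()
  keep <- vapply(canon[1:8], function(s) canonical_topology(parse_tree(s)),
                 "")
  expect_setequal(names(p)[p > 1e-9], unname(keep))
})

test_that("backbone threshold solves the limiting equality", {
  thr <- backbone_threshold(0.5)
  expect_equal(thr, log(4 / 3), tolerance = 1e-9)
  expect_equal(round(thr, 3), 0.288)
  # below the threshold the most likely topology is not a backbone tree
  below <- limit_probs(thr - 0.05, 0.5)
  above <- limit_probs(thr + 0.05, 0.5)
  expect_gt(max(below[3:15]), max(below[1:2]))
  expect_lt(max(above[3:15]), max(above[1:2]))
})

test_that("anomaly detection flags the right regions", {
  # deep in the anomaly zone the cherry-outside topology wins
  res <- is_anomalous(symmetric_hybrid_network(x = 0.05, y = 0.05, w = 0,
                                               gamma = 0.5))
  expect_true(res$anomalous)
  expect_true("((A,D),(B,C))" %in% res$argmax_topologies)
  # long roots and a long reticulation-child branch: a parental tree wins
  res2 <- is_anomalous(symmetric_hybrid_network(x = 50, y = 1, w = 0,
                                                gamma = 0.5))
  expect_false(res2$anomalous)
  expect_true(all(res2$argmax_topologies %in% res2$parental))
})

test_that("three-taxon networks produce no anomalies on a coarse sweep", {
  # full grids are exercised in the acceptance suite; spot-check here
  for (p1 in c(0.05, 0.5, 2)) {
    for (gam in c(0.1, 0.5)) {
      net <- parse_network(sprintf(
        "((A:1,(B:1)#H1:0.1::%f):%f,(C:1,#H1:0.1::%f):%f);",
        gam, p1, 1 - gam, 2.2 - p1))
      expect_false(is_anomalous(net)$anomalous)
    }
  }
})

test_that("anomaly-zone scan classifies the plane qualitatively", {
  tab <- anomaly_zone_scan(xs = c(0.05, 0.5, 1), ys = c(0.05, 0.5, 1),
                           gamma = 0.5)
  expect_identical(nrow(tab), 9L)
  origin <- tab[tab$x == 0.05 & tab$y == 0.05, ]
  expect_identical(origin$class, "non-parental")
  expect_match(origin$argmax, "\\(\\(A,D\\),\\(B,C\\)\\)")
  # gamma = 0 degenerates to the caterpillar species tree (((B,C),D),A);
  # with both internal branches moderately long its own topology wins,
  # while near the origin the classic caterpillar anomaly (the balanced
  # tree grouping the outermost taxa) appears
  tab0 <- anomaly_zone_scan(xs = c(0.05, 0.6), ys = c(0.05, 0.6), gamma = 0)
  far <- tab0[tab0$x == 0.6 & tab0$y == 0.6, ]
  expect_identical(far$class, "displayed")
  expect_identical(far$argmax, "(((B,C),D),A)")
  near <- tab0[tab0$x == 0.05 & tab0$y == 0.05, ]
  expect_identical(near$class, "non-parental")
  expect_match(near$argmax, "\\(\\(A,D\\),\\(B,C\\)\\)")
})
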