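# The running example throughout is the four-taxon network with one
# reticulation: hybridization between D and the ancestor of the (B, C)
# cherry, inheritance probability 0.3 toward the A side.

test_that("rich Newick parsing builds and validates the network", {
  net <- parse_network(example_network_text())
  expect_identical(network_taxa(net), c("A", "B", "C", "D"))
  expect_identical(n_reticulations(net), 1L)
  # a plain tree is a degenerate network
  tre <- parse_network("((A,B),C);")
  expect_identical(n_reticulations(tre), 0L)
  # inheritance probabilities must sum to one
  bad <- "((A:1,((B:1,C:1):1)#H1:0::0.7):1,(D:1,#H1:0::0.2):1);"
  expect_error(parse_network(bad), "sum to 1")
  # a complement is filled in when only one side is annotated
  half <- parse_network("((A:1,((B:1,C:1):1)#H1:0::0.3):1,(D:1,#H1:0):1);")
  expect_equal(sort(half$edges$gamma[!is.na(half$edges$gamma)]),
               c(0.3, 0.7))
  expect_error(parse_network("((A,B,C),D);"), "non-binary")
  expect_error(parse_network("((A,(B)#H1),(C,#H1),(D,E));"), "out-degree")
})

test_that("networks round-trip through write_network", {
  for (txt in c(example_network_text(),
                "((A:0.123456789,B:1):2.5,C:3.5);",
                "(((A:1,((B:1,C:1):0.4)#H1:0.1::0.25):1,(D:1,#H1:0.1::0.75):1):1,E:3.5);")) {
    net <- parse_network(txt)
    back <- parse_network(write_network(net))
    expect_identical(write_network(back), write_network(net))
    expect_equal(sort(back$edges$length), sort(net$edges$length),
                 tolerance = 1e-9)
    expect_equal(sort(back$edges$gamma[!is.na(back$edges$gamma)]),
                 sort(net$edges$gamma[!is.na(net$edges$gamma)]),
                 tolerance = 1e-9)
  }
})

test_that("displayed trees are the per-reticulation edge removals", {
  net <- parse_network(example_network_text())
  disp <- vapply(displayed_trees(net), canonical_topology, "")
  expect_setequal(disp, c("(((B,C),A),D)", "(((B,C),D),A)"))
  # a tree displays only itself
  tre <- parse_network("((A:1,B:1):1,C:2);")
  expect_identical(vapply(displayed_trees(tre), canonical_topology, ""),
                   "((A,B),C)")
  # two reticulations: at most 2^2 distinct topologies
  two <- parse_network(paste0(
    "(((A:1,(B:1)#H1:0::0.5):1,(C:1,#H1:0::0.5):1):1,",
    "((D:1)#H2:0::0.4,(E:1,#H2:0::0.6):1):2);"))
  expect_identical(n_reticulations(two), 2L)
  d2 <- displayed_trees(two)
  expect_lte(length(d2), 4L)
  expect_gte(length(d2), 1L)
})

test_that("MUL-tree conversion duplicates reticulation subtrees", {
  net <- parse_network(example_network_text())
  mul <- to_mul_tree(net)
  expect_identical(canonical_topology(mul), "(((B,C),A),((B,C),D))")
  expect_identical(sort(tree_leaves(mul)),
                   c("A", "B", "B", "C", "C", "D"))
  # multiplicities equal root-to-leaf path counts (independent DFS oracle)
  expect_identical(as.integer(mul_leaf_multiplicity(net)),
                   as.integer(oracle_path_counts(net)))
  nested <- parse_network(paste0(
    "(((A:1,(B:1)#H1:0::0.5):1,(C:1,#H1:0::0.5):1):1,",
    "((D:1)#H2:0::0.4,(E:1,#H2:0::0.6):1):2);"))
  expect_identical(as.integer(mul_leaf_multiplicity(nested)),
                   as.integer(oracle_path_counts(nested)))
  # a tree maps to itself with all multiplicities one
  tre <- parse_network("((A:1,B:1):1,C:2);")
  expect_identical(canonical_topology(to_mul_tree(tre)), "((A,B),C)")
})

test_that("parental trees extend displayed trees", {
  net <- parse_network(example_network_text())
  par1 <- vapply(parental_trees(net), canonical_topology, "")
  expect_setequal(par1, c("(((B,C),A),D)", "(((B,C),D),A)",
                          "((A,B),(C,D))", "((A,C),(B,D))"))
  disp <- vapply(displayed_trees(net), canonical_topology, "")
  expect_true(all(disp %in% par1))
  expect_identical(attr(parental_trees(net), "n_selections"), 4L)
  # multiple alleles keep leaf copies and enlarge the set
  par2 <- parental_trees(net, sample_config(A = 1, B = 2, C = 1, D = 1))
  expect_gt(length(par2), length(par1))
  expect_true(any(vapply(par2, function(t) sum(tree_leaves(t) == "B") == 2,
                         TRUE)))
  # a tree network has itself as only parental tree
  tre <- parse_network("((A:1,B:1):1,C:2);")
  expect_identical(vapply(parental_trees(tre), canonical_topology, ""),
                   "((A,B),C)")
  expect_error(sample_config(A = 0), "at least 1")
  expect_error(sample_config(1, 2), "named")
})

test_that("displayed trees are always parental trees on assorted networks", {
  nets <- list(
    parse_network(example_network_text()),
    parse_network("(((A:1,((B:1,C:1):0.4)#H1:0.1::0.25):1,(D:1,#H1:0.1::0.75):1):1,E:3.5);"),
    parse_network(paste0(
      "(((A:1,(B:1)#H1:0::0.5):1,(C:1,#H1:0::0.5):1):1,",
      "((D:1)#H2:0::0.4,(E:1,#H2:0::0.6):1):2);")))
  for (net in nets) {
    disp <- vapply(displayed_trees(net), canonical_topology, "")
    par <- vapply(parental_trees(net), canonical_topology, "")
    expect_true(all(disp %in% par))
    expect_lte(length(disp), 2^n_reticulations(net))
  }
})
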