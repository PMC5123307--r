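# The symmetric four-taxon hybridization network: taxa A, B, C, D, one
# reticulation whose child is the cherry (B,C) and whose parents sit on the
# A-side and D-side root branches. Parameters: x = length of each branch
# incident with the root, y = branch between the reticulation node and the
# MRCA of B and C, w = length of both reticulation edges, gamma =
# inheritance probability of the A-side ("left") reticulation edge. This
# family admits closed-form gene-tree probabilities (w = 0) and is the
# canonical example of a network whose most likely gene tree need not be a
# parental tree.

#' Symmetric four-taxon hybridization network
#'
#' @param x length (coalescent units) of the two branches incident with the
#'   root.
#' @param y length of the branch between the reticulation node and the MRCA
#'   of B and C.
#' @param w length of both reticulation edges.
#' @param gamma inheritance probability of the A-side reticulation edge.
#' @param pendant length given to the B and C pendant edges (A and D are
#'   extended so leaves are contemporaneous); irrelevant for topology
#'   probabilities, used by the simulator.
#' @return a `phylo_network`.
#' @export
#' @examples
#' net <- symmetric_hybrid_network(x = 1, y = 0.5, gamma = 0.3)
#' length(displayed_trees(net)) # 2
symmetric_hybrid_network <- function(x, y, w = 0, gamma = 0.5, pendant = 1) {
  stopifnot(x >= 0, y >= 0, w >= 0, gamma >= 0, gamma <= 1)
  fmt <- function(v) format(v, digits = 17, scientific = FALSE)
  txt <- sprintf(
    "((A:%s,((B:%s,C:%s):%s)#H1:%s::%s):%s,(D:%s,#H1:%s::%s):%s);",
    fmt(pendant + y + w), fmt(pendant), fmt(pendant), fmt(y), fmt(w),
    fmt(gamma), fmt(x), fmt(pendant + y + w), fmt(w), fmt(1 - gamma),
    fmt(x))
  parse_network(txt)
}

#' The 15 rooted gene-tree topologies on taxa A, B, C, D
#'
#' Returned in the fixed order used by [closed_form_probs()] and
#' [limit_probs()]: the two topologies matching the displayed (backbone)
#' trees first, then the two non-displayed parental trees, then the rest.
#'
#' @return character vector of 15 Newick strings.
#' @export
hybrid_gene_topologies <- function() {
  c("(((B,C),A),D);",
    "(((B,C),D),A);",
    "((A,B),(C,D));",
    "((A,C),(B,D));",
    "(((A,B),C),D);",
    "(((A,C),B),D);",
    "(A,(B,(C,D)));",
    "(((B,D),C),A);",
    "((A,D),(B,C));",
    "(((A,B),D),C);",
    "(B,(A,(C,D)));",
    "(((A,D),B),C);",
    "(((B,D),A),C);",
    "(((A,C),D),B);",
    "(((A,D),C),B);")
}

hybrid_topology_canon <- function() {
  vapply(hybrid_gene_topologies(),
         function(s) canonical_topology(parse_tree(s)), "",
         USE.NAMES = FALSE)
}

#' Closed-form gene-tree probabilities for the symmetric hybrid network
#'
#' Exact probabilities of the 15 rooted topologies for the network of
#' [symmetric_hybrid_network()] with `w = 0`, written directly in terms of
#' the coalescent transition probabilities `g_ij`. Serves as an independent
#' oracle for the general MUL-tree enumeration engine.
#'
#' @param x,y branch lengths in coalescent units (see
#'   [symmetric_hybrid_network()]).
#' @param gamma inheritance probability of the A-side reticulation edge.
#' @return numeric vector of 15 probabilities named by canonical topology,
#'   ordered as [hybrid_gene_topologies()].
#' @export
closed_form_probs <- function(x, y, gamma) {
  g <- gamma
  g21y <- gij(2, 1, y); g22y <- gij(2, 2, y)
  g21x <- gij(2, 1, x); g22x <- gij(2, 2, x)
  g31x <- gij(3, 1, x); g32x <- gij(3, 2, x); g33x <- gij(3, 3, x)
  A <- g31x / 3 + g32x / 9 + g33x / 18
  B <- g32x / 9 + g33x / 18
  C2 <- g22x * g22x / 18          # two separate pairs, 1/6 * 1/3
  FF <- g21x * g22x / 3
  p <- numeric(15)
  # backbone topologies
  p[1] <- g21y * (g * (g21x + g22x / 3) + (1 - g) * (g22x / 3)) +
    g22y * (g^2 * A + (1 - g)^2 * B + 2 * g * (1 - g) * C2)
  p[2] <- g21y * ((1 - g) * (g21x + g22x / 3) + g * (g22x / 3)) +
    g22y * ((1 - g)^2 * A + g^2 * B + 2 * g * (1 - g) * C2)
  # parental but not displayed
  p[3] <- g22y * ((g^2 + (1 - g)^2) * (g32x / 9 + g33x / 9) +
                    g * (1 - g) * (g21x^2 + 2 * FF + g22x^2 / 9) +
                    g * (1 - g) * (g22x^2 / 9))
  p[4] <- p[3]
  # the remaining eleven
  p[5] <- g22y * (g^2 * A + (1 - g)^2 * (g33x / 18) +
                    g * (1 - g) * (FF + C2) + g * (1 - g) * C2)
  p[6] <- p[5]
  p[7] <- g22y * ((1 - g)^2 * A + g^2 * (g33x / 18) +
                    g * (1 - g) * (FF + C2) + g * (1 - g) * C2)
  p[8] <- p[7]
  p[9] <- g21y * (g * g22x / 3 + (1 - g) * g22x / 3) +
    g22y * (g^2 * (g32x / 9 + g33x / 9) +
              (1 - g)^2 * (g32x / 9 + g33x / 9) +
              2 * g * (1 - g) * (g22x^2 / 9))
  p[10] <- g22y * (g^2 * (g32x / 9 + g33x / 18) + (1 - g)^2 * (g33x / 18) +
                     g * (1 - g) * (FF + C2) + g * (1 - g) * C2)
  p[11] <- g22y * ((1 - g)^2 * (g32x / 9 + g33x / 18) + g^2 * (g33x / 18) +
                     g * (1 - g) * (FF + C2) + g * (1 - g) * C2)
  p[12] <- g22y * (g^2 * (g33x / 18) + (1 - g)^2 * (g33x / 18) +
                     2 * g * (1 - g) * C2)
  p[13] <- g22y * (g^2 * (g33x / 18) +
                     (1 - g)^2 * (g32x / 9 + g33x / 18) +
                     g * (1 - g) * C2 + g * (1 - g) * (FF + C2))
  p[14] <- g22y * ((1 - g)^2 * (g33x / 18) +
                     g^2 * (g32x / 9 + g33x / 18) +
                     g * (1 - g) * C2 + g * (1 - g) * (FF + C2))
  p[15] <- g22y * (g^2 * (g33x / 18) + (1 - g)^2 * (g33x / 18) +
                     2 * g * (1 - g) * C2)
  names(p) <- hybrid_topology_canon()
  p
}

#' Limiting gene-tree probabilities as the root branches grow long
#'
#' The `x -> Inf` limits of [closed_form_probs()]: seven topologies lose all
#' mass and only eight retain it.
#'
#' @param y branch length between the reticulation node and the MRCA of B
#'   and C.
#' @param gamma inheritance probability of the A-side reticulation edge.
#' @return numeric vector of 15 probabilities named and ordered as
#'   [closed_form_probs()].
#' @export
limit_probs <- function(y, gamma) {
  g <- gamma
  ey <- exp(-y)
  p <- numeric(15)
  p[1] <- g - (g - g^2 / 3) * ey
  p[2] <- (1 - g) - (-g^2 / 3 - g / 3 + 2 / 3) * ey
  p[3] <- g * (1 - g) * ey
  p[4] <- p[3]
  p[5] <- g^2 / 3 * ey
  p[6] <- p[5]
  p[7] <- (1 - g)^2 / 3 * ey
  p[8] <- p[7]
  # p[9..15] stay 0
  names(p) <- hybrid_topology_canon()
  p
}

#' Backbone threshold branch length
#'
#' In the long-root-branch limit of the symmetric hybrid network, solves for
#' the value of `y` at which the probability of the most likely
#' non-backbone topology equals that of the most likely backbone (displayed)
#' topology. Below the threshold the most likely gene tree is not a
#' backbone tree. For `gamma = 0.5` the solution is `log(4/3) ~= 0.288`.
#'
#' @param gamma inheritance probability.
#' @return threshold value of `y` in coalescent units.
#' @export
backbone_threshold <- function(gamma = 0.5) {
  f <- function(y) {
    p <- limit_probs(y, gamma)
    max(p[3:15]) - max(p[1:2])
  }
  stats::uniroot(f, c(1e-9, 50), tol = 1e-12)$root
}

#' Most-likely-gene-tree scan over the (x, y) plane
#'
#' Evaluates the closed-form topology distribution of the symmetric hybrid
#' network (`w = 0`) on a grid and classifies each cell by where the most
#' likely gene tree falls: a displayed (backbone) tree, a parental tree
#' that is not displayed, or a non-parental tree (the anomaly zone).
#'
#' @param xs,ys grid values for the two branch lengths (default 100 points
#'   each on `(0, 1]`).
#' @param gamma inheritance probability.
#' @param tol tie tolerance for the argmax set.
#' @return data frame with columns `x`, `y`, `argmax` (canonical topology
#'   strings, `;`-separated on ties) and `class` (one of `"displayed"`,
#'   `"parental"`, `"non-parental"`).
#' @export
anomaly_zone_scan <- function(xs = seq(0.01, 1, length.out = 100),
                              ys = seq(0.01, 1, length.out = 100),
                              gamma = 0.5, tol = 1e-9) {
  canon <- hybrid_topology_canon()
  displayed <- canon[1:2]
  parental <- canon[1:4]
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  argmax <- character(nrow(grid))
  cls <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- closed_form_probs(grid$x[i], grid$y[i], gamma)
    am <- canon[p >= max(p) - tol]
    argmax[i] <- paste(am, collapse = ";")
    cls[i] <- if (any(!(am %in% parental))) {
      "non-parental"
    } else if (any(!(am %in% displayed))) {
      "parental"
    } else {
      "displayed"
    }
  }
  data.frame(grid, argmax = argmax, class = cls,
             stringsAsFactors = FALSE)
}
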