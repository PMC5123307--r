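# Rooted trees as nested lists: each node is list(label, length, children),
# where `length` is the branch length to the parent (NA if absent) and
# `children` is a (possibly empty) list of child nodes. Leaves carry labels;
# MUL-trees simply repeat labels.

new_rnode <- function(label = NA_character_, length = NA_real_,
                      children = list()) {
  list(label = label, length = length, children = children)
}

is_leaf <- function(node) length(node$children) == 0L

#' Read a rooted tree from a Newick string
#'
#' Plain Newick with optional branch lengths. Internal node labels and
#' bootstrap-style annotation fields are accepted and ignored for topology
#' purposes. Repeated leaf labels (MUL-trees) are allowed.
#'
#' @param text a single Newick string (trailing `;` optional).
#' @return an object of class `rtree`: a nested list with fields `label`,
#'   `length` (branch to parent) and `children`.
#' @seealso [write_tree()], [parse_network()]
#' @export
#' @examples
#' tr <- parse_tree("((A:1,B:1):0.5,C:1.5);")
#' tree_leaves(tr)
parse_tree <- function(text) {
  parsed <- parse_newick(text)
  if (any_hybrid_tags(parsed)) {
    stop("input contains reticulation (#H) tags; use parse_network()")
  }
  tree <- strip_annotations(parsed)
  class(tree) <- c("rtree", "list")
  tree
}

any_hybrid_tags <- function(node) {
  if (!is.na(node$hybrid)) return(TRUE)
  for (ch in node$children) if (any_hybrid_tags(ch)) return(TRUE)
  FALSE
}

strip_annotations <- function(node) {
  new_rnode(node$label, node$length,
            lapply(node$children, strip_annotations))
}

# Low-level recursive-descent Newick reader shared by trees and networks.
# Annotation grammar per node: [label][#Htag][:length[:support[:gamma]]].
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  s <- sub(";$", "", s)
  env <- new.env(parent = emptyenv())
  env$chars <- strsplit(s, "", fixed = TRUE)[[1]]
  env$pos <- 1L
  node <- parse_nw_node(env)
  if (env$pos <= length(env$chars)) {
    stop("Newick syntax error: trailing characters at position ", env$pos)
  }
  node
}

nw_peek <- function(env) {
  if (env$pos > length(env$chars)) return(NA_character_)
  env$chars[env$pos]
}

nw_take <- function(env) {
  ch <- nw_peek(env)
  env$pos <- env$pos + 1L
  ch
}

nw_name <- function(env) {
  out <- character(0)
  repeat {
    ch <- nw_peek(env)
    if (is.na(ch) || ch %in% c("(", ")", ",", ":", ";", "#")) break
    out <- c(out, nw_take(env))
  }
  paste(out, collapse = "")
}

parse_nw_node <- function(env) {
  children <- list()
  if (identical(nw_peek(env), "(")) {
    nw_take(env)
    repeat {
      children <- c(children, list(parse_nw_node(env)))
      ch <- nw_take(env)
      if (identical(ch, ")")) break
      if (!identical(ch, ",")) {
        stop("Newick syntax error: expected ',' or ')' at position ",
             env$pos - 1L)
      }
    }
  }
  label <- nw_name(env)
  hybrid <- NA_character_
  if (identical(nw_peek(env), "#")) {
    nw_take(env)
    hybrid <- nw_name(env)
    if (!nzchar(hybrid)) stop("Newick syntax error: empty # tag")
  }
  fields <- rep(NA_real_, 3L) # length, support, gamma
  i <- 0L
  while (identical(nw_peek(env), ":") && i < 3L) {
    nw_take(env)
    i <- i + 1L
    num <- nw_name(env)
    if (nzchar(num)) {
      val <- suppressWarnings(as.numeric(num))
      if (is.na(val)) stop("Newick syntax error: bad number '", num, "'")
      fields[i] <- val
    }
  }
  list(label = if (nzchar(label)) label else NA_character_,
       hybrid = hybrid,
       length = fields[1], support = fields[2], gamma = fields[3],
       children = children)
}

#' Write a rooted tree as a Newick string
#'
#' @param tree an `rtree`.
#' @param digits significant digits for branch lengths.
#' @param topology_only drop branch lengths if `TRUE`.
#' @return a Newick string terminated by `;`.
#' @export
write_tree <- function(tree, digits = 12, topology_only = FALSE) {
  paste0(write_nw_node(tree, digits, topology_only), ";")
}

write_nw_node <- function(node, digits, topology_only) {
  body <- if (is_leaf(node)) {
    node$label
  } else {
    paste0("(", paste(vapply(node$children, write_nw_node, "",
                             digits = digits,
                             topology_only = topology_only),
                      collapse = ","), ")")
  }
  if (!topology_only && !is.na(node$length)) {
    body <- paste0(body, ":", format(node$length, digits = digits))
  }
  body
}

#' Leaf labels of a tree
#'
#' @param tree an `rtree`.
#' @return character vector of leaf labels in traversal order (repeated
#'   labels preserved for MUL-trees).
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

#' Canonical topology string
#'
#' Branch lengths are dropped and children sorted lexicographically, so two
#' trees have equal canonical strings iff their rooted topologies (as
#' labelled trees) are equal. Used throughout for set membership.
#'
#' @param tree an `rtree`.
#' @return a character string.
#' @export
canonical_topology <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  kids <- sort(vapply(tree$children, canonical_topology, ""))
  paste0("(", paste(kids, collapse = ","), ")")
}

# All clusters (leaf-label sets of internal nodes), as sorted strings.
# Excludes leaves; the root cluster is included and filtered by callers.
tree_cluster_strings <- function(tree) {
  acc <- character(0)
  rec <- function(node) {
    if (is_leaf(node)) return(node$label)
    below <- unlist(lapply(node$children, rec), use.names = FALSE)
    acc[[length(acc) + 1L]] <<- paste(sort(below), collapse = "|")
    below
  }
  rec(tree)
  acc
}

#' Rooted Robinson-Foulds distance
#'
#' Cardinality of the symmetric difference of the two trees' nontrivial
#' proper clusters (singletons and the full leaf set excluded). Zero iff the
#' rooted topologies agree; at most `2*(n-2)` for `n` leaves.
#'
#' @param t1,t2 `rtree` objects on the same leaf-label set.
#' @param normalized divide by the maximum `2*(n-2)` to give a value in
#'   `[0,1]`.
#' @return a nonnegative number (an even integer when `normalized = FALSE`).
#' @export
#' @examples
#' a <- parse_tree("((a,b),(c,d));"); b <- parse_tree("((a,c),(b,d));")
#' rooted_rf(a, b)
rooted_rf <- function(t1, t2, normalized = FALSE) {
  l1 <- sort(tree_leaves(t1)); l2 <- sort(tree_leaves(t2))
  if (!identical(l1, l2)) stop("trees have different leaf sets")
  n <- length(l1)
  full <- paste(l1, collapse = "|")
  c1 <- setdiff(tree_cluster_strings(t1), full)
  c2 <- setdiff(tree_cluster_strings(t2), full)
  d <- length(setdiff(c1, c2)) + length(setdiff(c2, c1))
  if (normalized) {
    if (n <= 2) return(0)
    d / (2 * (n - 2))
  } else {
    d
  }
}

#' Enumerate all rooted binary labelled topologies
#'
#' There are `(2n-3)!!` rooted binary trees on `n` labelled leaves; they are
#' generated by successively attaching each label to every branch (and above
#' the root) of each smaller tree.
#'
#' @param labels character vector of at least two leaf labels.
#' @return list of `rtree` objects, deduplicated and ordered by canonical
#'   topology string.
#' @export
#' @examples
#' length(enumerate_rooted_topologies(letters[1:4])) # 15
enumerate_rooted_topologies <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("need at least 2 labels")
  if (anyDuplicated(labels)) stop("labels must be distinct")
  trees <- list(new_rnode(children = list(new_rnode(labels[1]),
                                          new_rnode(labels[2]))))
  for (lab in labels[-(1:2)]) {
    nxt <- list()
    for (tr in trees) {
      for (path in node_paths(tr)) {
        nxt[[length(nxt) + 1L]] <- insert_leaf_above(tr, path, lab)
      }
    }
    trees <- nxt
  }
  keys <- vapply(trees, canonical_topology, "")
  trees <- trees[!duplicated(keys)][order(unique(keys))]
  trees <- lapply(trees, function(tr) { class(tr) <- c("rtree", "list"); tr })
  trees
}

# Paths (integer child-index vectors from the root) to every node, root
# included; inserting "above" the root adds a new root.
node_paths <- function(tree) {
  acc <- list(integer(0))
  rec <- function(node, path) {
    for (i in seq_along(node$children)) {
      acc[[length(acc) + 1L]] <<- c(path, i)
      rec(node$children[[i]], c(path, i))
    }
  }
  rec(tree, integer(0))
  acc
}

insert_leaf_above <- function(tree, path, lab) {
  if (length(path) == 0L) {
    return(new_rnode(children = list(tree, new_rnode(lab))))
  }
  rec <- function(node, path) {
    i <- path[1]
    if (length(path) == 1L) {
      node$children[[i]] <- new_rnode(children = list(node$children[[i]],
                                                      new_rnode(lab)))
    } else {
      node$children[[i]] <- rec(node$children[[i]], path[-1])
    }
    node
  }
  rec(tree, path)
}

#' @export
print.rtree <- function(x, ...) {
  cat(write_tree(x), "\n")
  invisible(x)
}

# Prune a tree to a set of leaves identified by position (traversal order of
# tree_leaves), applying forced contractions and summing branch lengths
# through removed degree-one nodes.
prune_to_leaf_ids <- function(tree, keep_ids) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  rec <- function(node) {
    if (is_leaf(node)) {
      counter$i <- counter$i + 1L
      if (counter$i %in% keep_ids) return(node) else return(NULL)
    }
    kids <- Filter(Negate(is.null), lapply(node$children, rec))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) {
      k <- kids[[1]]
      k$length <- if (is.na(node$length) || is.na(k$length)) {
        NA_real_
      } else {
        node$length + k$length
      }
      return(k)
    }
    new_rnode(node$label, node$length, kids)
  }
  out <- rec(tree)
  if (!is.null(out)) class(out) <- c("rtree", "list")
  out
}

# Pairwise leaf-to-leaf path-length distances of a tree with branch lengths.
tree_leaf_distances <- function(tree) {
  labs <- tree_leaves(tree)
  n <- length(labs)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  idx <- new.env(parent = emptyenv()); idx$i <- 0L
  walk <- function(node, depth) {
    if (is_leaf(node)) {
      idx$i <- idx$i + 1L
      return(list(list(id = idx$i, depth = depth)))
    }
    groups <- lapply(node$children, function(ch) {
      el <- if (is.na(ch$length)) 0 else ch$length
      walk(ch, depth + el)
    })
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        for (u in groups[[a]]) {
          for (v in groups[[b]]) {
            d <- (u$depth - depth) + (v$depth - depth)
            D[u$id, v$id] <<- d
            D[v$id, u$id] <<- d
          }
        }
      }
    }
    unlist(groups, recursive = FALSE)
  }
  walk(tree, 0)
  D
}
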