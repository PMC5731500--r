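#' Rooted, fixed-topology species trees
#'
#' A `species_tree` is the central container of the package: a rooted,
#' strictly binary tree with contemporaneous tips (age 0) and an age for
#' every internal node.  Node indexing follows the convention of
#' [ape::read.tree()]: tips are numbered `1:n_leaves` in depth-first
#' left-to-right order as written in the newick string (this ordering also
#' defines the layout of all site-pattern keys downstream), internal nodes
#' are `(n_leaves+1):(2*n_leaves-1)` with the root at `n_leaves + 1`.
#'
#' @section Fields:
#' \describe{
#'   \item{n_leaves, n_nodes}{leaf and total node counts; always
#'     `n_nodes == 2 * n_leaves - 1`.}
#'   \item{parent}{integer vector; `parent[root] == NA`.}
#'   \item{child1, child2}{integer vectors, `NA` at tips; children keep the
#'     order in which they were written.}
#'   \item{ages}{numeric vector of node ages in abstract time units (the
#'     documentation convention is 100 Myr per unit); tips are exactly 0.}
#'   \item{labels}{taxon labels for tips, `NA` for internal nodes.}
#'   \item{postorder}{internal node ids ordered children-before-parents.}
#'   \item{root}{root node id.}
#' }
#' @name species_tree
NULL

new_species_tree <- function(parent, child1, child2, ages, labels, n_leaves) {
  n_nodes <- length(parent)
  stopifnot(n_nodes == 2L * n_leaves - 1L)
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must have exactly one root")
  tr <- list(
    n_leaves = n_leaves, n_nodes = n_nodes, root = root,
    parent = parent, child1 = child1, child2 = child2,
    ages = ages, labels = labels,
    postorder = postorder_internal(parent, child1, child2, n_leaves)
  )
  class(tr) <- "species_tree"
  tr
}

# internal nodes in children-before-parents order
postorder_internal <- function(parent, child1, child2, n_leaves) {
  root <- which(is.na(parent))
  stack <- root
  visit <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    visit <- c(visit, v)
    if (!is.na(child1[v])) stack <- c(stack, child1[v], child2[v])
  }
  rev(visit[!is.na(child1[visit])])
}

#' Parse a rooted binary newick string
#'
#' Branch lengths, when present, are used only to seed initial node ages
#' (age of a node = maximum path length to any leaf below it; leaves are
#' clamped to exactly 0).  Without branch lengths, ages are initialised by
#' an order-preserving spread proportional to node height (edges to the
#' farthest leaf below), with the root at `root_age`.
#'
#' @param text a newick string describing one rooted, strictly binary tree.
#' @param root_age root age used when the newick carries no branch lengths.
#' @return a [species_tree].
#' @export
parse_newick <- function(text, root_age = 1) {
  ph <- ape::read.tree(text = text)
  if (is.null(ph)) stop("could not parse newick string")
  as_species_tree(ph, root_age = root_age)
}

#' Convert an ape "phylo" tree to a species_tree
#'
#' @param ph a rooted, binary `phylo` object.
#' @inheritParams parse_newick
#' @return a [species_tree].
#' @export
as_species_tree <- function(ph, root_age = 1) {
  if (anyDuplicated(ph$tip.label)) stop("duplicate leaf labels in tree")
  n <- length(ph$tip.label)
  if (n < 2L) stop("tree needs at least 2 leaves")
  n_nodes <- n + ph$Nnode
  if (n_nodes != 2L * n - 1L) stop("tree is not strictly binary")
  parent <- rep(NA_integer_, n_nodes)
  child1 <- rep(NA_integer_, n_nodes)
  child2 <- rep(NA_integer_, n_nodes)
  for (i in seq_len(nrow(ph$edge))) {
    p <- ph$edge[i, 1]; ch <- ph$edge[i, 2]
    parent[ch] <- p
    if (is.na(child1[p])) child1[p] <- ch
    else if (is.na(child2[p])) child2[p] <- ch
    else stop("node ", p, " has more than 2 children; tree must be binary")
  }
  if (any(!is.na(child1[(n + 1):n_nodes]) & is.na(child2[(n + 1):n_nodes])))
    stop("unary node found; tree must be strictly binary")
  labels <- c(ph$tip.label, rep(NA_character_, ph$Nnode))

  po <- postorder_internal(parent, child1, child2, n)

  ages <- numeric(n_nodes)
  if (!is.null(ph$edge.length)) {
    blen <- numeric(n_nodes)
    blen[ph$edge[, 2]] <- ph$edge.length
    for (v in po) {
      ages[v] <- max(ages[child1[v]] + blen[child1[v]],
                     ages[child2[v]] + blen[child2[v]])
    }
  } else {
    height <- integer(n_nodes)
    for (v in po) height[v] <- 1L + max(height[child1[v]], height[child2[v]])
    ages <- root_age * height / height[n + 1L]
  }
  new_species_tree(parent, child1, child2, ages, labels, n)
}

#' Serialize a species_tree to newick
#'
#' With `with_ages = TRUE`, branch lengths are written as
#' `age[parent] - age[child]` with enough digits for a lossless round trip
#' through [parse_newick()].
#'
#' @param tree a [species_tree].
#' @param with_ages write branch lengths derived from node ages?
#' @return a newick string ending in ";".
#' @export
write_newick <- function(tree, with_ages = TRUE) {
  rec <- function(v) {
    if (is.na(tree$child1[v])) s <- tree$labels[v]
    else {
      s1 <- rec(tree$child1[v]); s2 <- rec(tree$child2[v])
      s <- paste0("(", s1, ",", s2, ")")
    }
    if (with_ages && !is.na(tree$parent[v])) {
      s <- paste0(s, ":",
                  sprintf("%.17g", tree$ages[tree$parent[v]] - tree$ages[v]))
    }
    s
  }
  paste0(rec(tree$root), ";")
}

#' Check the age ordering invariants of a tree
#'
#' @param tree a [species_tree].
#' @return character vector of violation messages; empty when every parent
#'   is strictly older than each child and all leaves sit at age 0.
#' @export
validate_ages <- function(tree) {
  out <- character(0)
  tips <- seq_len(tree$n_leaves)
  bad_tips <- tips[tree$ages[tips] != 0]
  for (v in bad_tips)
    out <- c(out, sprintf("leaf %s (node %d) has nonzero age %g",
                          tree$labels[v], v, tree$ages[v]))
  for (v in tree$postorder) {
    for (ch in c(tree$child1[v], tree$child2[v])) {
      if (tree$ages[v] <= tree$ages[ch])
        out <- c(out, sprintf(
          "node %d (age %g) not strictly older than child %d (age %g)",
          v, tree$ages[v], ch, tree$ages[ch]))
    }
  }
  out
}

#' Most recent common ancestor of a set of leaves
#'
#' Computed by postorder subtree-leaf counting: the MRCA is the first node
#' in postorder whose subtree contains every requested leaf.
#'
#' @param tree a [species_tree].
#' @param leaves character vector of leaf labels (length >= 1).
#' @return internal (or leaf, for a single label) node id.
#' @export
mrca_node <- function(tree, leaves) {
  ids <- match(leaves, tree$labels[seq_len(tree$n_leaves)])
  if (anyNA(ids))
    stop("unknown leaf label(s): ", paste(leaves[is.na(ids)], collapse = ", "))
  if (length(ids) == 1L) return(ids)
  cnt <- integer(tree$n_nodes)
  cnt[ids] <- 1L
  for (v in tree$postorder) {
    cnt[v] <- cnt[tree$child1[v]] + cnt[tree$child2[v]]
    if (cnt[v] == length(ids)) return(v)
  }
  stop("MRCA not found (corrupt tree)")  # unreachable on a valid tree
}

# leaves (tip ids) below each node, as a list; used by the compression builder
leaves_below <- function(tree) {
  below <- vector("list", tree$n_nodes)
  for (v in seq_len(tree$n_leaves)) below[[v]] <- v
  for (v in tree$postorder)
    below[[v]] <- c(below[[tree$child1[v]]], below[[tree$child2[v]]])
  below
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species_tree: %d leaves, %d internal nodes, root age %.4g\n",
              x$n_leaves, x$n_nodes - x$n_leaves, x$ages[x$root]))
  invisible(x)
}

# depth (edges from root) per node; used by instrumentation tests
node_depths <- function(tree) {
  d <- integer(tree$n_nodes)
  for (v in rev(tree$postorder)) {
    d[tree$child1[v]] <- d[v] + 1L
    d[tree$child2[v]] <- d[v] + 1L
  }
  d
}
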