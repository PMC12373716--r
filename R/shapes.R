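#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble
NULL

# A tree_shape is a recursive list: a leaf is an empty list, an inner vertex a
# list of >= 2 child shapes held in canonical (key-sorted) order. Every shape
# carries its canonical key and leaf count as attributes, so isomorphism
# checks are string comparisons and enumeration can share subtrees freely.

new_leaf <- function() {
  structure(list(), class = "tree_shape", key = "L", n = 1L)
}

new_node <- function(children) {
  if (length(children) < 2L) {
    abort("an inner vertex needs at least two children (no out-degree-one vertices)")
  }
  keys <- vapply(children, function(ch) attr(ch, "key"), character(1))
  ord <- order(keys, method = "radix")
  children <- children[ord]
  structure(
    children,
    class = "tree_shape",
    key = paste0("(", paste(keys[ord], collapse = ","), ")"),
    n = sum(vapply(children, function(ch) attr(ch, "n"), integer(1)))
  )
}

is_leaf <- function(x) length(x) == 0L

#' Number of leaves of a tree shape
#'
#' @param tree A `tree_shape`, `phylo`, or Newick string.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) {
  attr(as_tree_shape(tree), "n")
}

#' Canonical isomorphism key of a rooted tree shape
#'
#' Two rooted trees receive the same key if and only if they are isomorphic as
#' unordered rooted trees. The key is built by recursively sorting child
#' encodings, so it is deterministic and independent of input child order,
#' labels, and branch lengths.
#'
#' @param tree A `tree_shape`, `phylo`, or Newick string.
#' @return A character scalar.
#' @export
canonical_key <- function(tree) {
  attr(as_tree_shape(tree), "key")
}

#' Height of a tree shape
#'
#' @param tree A `tree_shape`, `phylo`, or Newick string.
#' @return Integer: the maximum leaf depth.
#' @export
tree_height <- function(tree) {
  s <- as_tree_shape(tree)
  rec <- function(x) if (is_leaf(x)) 0L else 1L + max(vapply(x, rec, integer(1)))
  rec(s)
}

#' Is the shape binary?
#'
#' @param tree A `tree_shape`, `phylo`, or Newick string.
#' @return `TRUE` if every inner vertex has exactly two children.
#' @export
is_binary_shape <- function(tree) {
  s <- as_tree_shape(tree)
  rec <- function(x) {
    if (is_leaf(x)) return(TRUE)
    length(x) == 2L && all(vapply(x, rec, logical(1)))
  }
  rec(s)
}

#' Convert to a tree shape
#'
#' Converts a `phylo` object or a Newick string to the package's shape
#' representation. Labels and branch lengths are discarded; vertices of
#' out-degree one (which the rooted-tree model forbids) are collapsed with a
#' warning.
#'
#' @param x A `tree_shape`, an [ape::read.tree()] `phylo` object, or a Newick
#'   string.
#' @return A `tree_shape`.
#' @export
as_tree_shape <- function(x) UseMethod("as_tree_shape")

#' @export
as_tree_shape.tree_shape <- function(x) x

#' @export
as_tree_shape.phylo <- function(x) {
  ntip <- length(x$tip.label)
  if (ntip == 0L) abort("tree has no leaves")
  kids <- split(x$edge[, 2], factor(x$edge[, 1], levels = seq_len(ntip + x$Nnode)))
  singles <- 0L
  rec <- function(v) {
    ch <- kids[[v]]
    if (is.null(ch) || length(ch) == 0L) return(new_leaf())
    if (length(ch) == 1L) {
      singles <<- singles + 1L
      return(rec(ch[[1]]))
    }
    new_node(lapply(ch, rec))
  }
  out <- rec(ntip + 1L)
  if (singles > 0L) {
    warn(sprintf("collapsed %d out-degree-one vertex/vertices", singles))
  }
  out
}

#' @export
as_tree_shape.character <- function(x) {
  parse_newick(x)
}

#' Parse a Newick string into a tree shape
#'
#' Reading goes through [ape::read.tree()]; labels and branch lengths are
#' permitted but ignored, and unary chains are collapsed (with a warning) so
#' that no vertex has out-degree one.
#'
#' @param text A single Newick string (terminated by `;`).
#' @return A `tree_shape`.
#' @export
#' @examples
#' parse_newick("((A,B),C);")
parse_newick <- function(text) {
  if (length(text) != 1L || !nzchar(trimws(text))) {
    abort("empty Newick input")
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("malformed Newick: ", conditionMessage(e))),
    warning = function(w) abort(paste0("malformed Newick: ", conditionMessage(w)))
  )
  if (is.null(phy)) abort("malformed Newick input")
  as_tree_shape(phy)
}

#' Write a tree shape as canonical Newick
#'
#' Children appear in canonical (key-sorted) order and leaves are labelled
#' `L1..Ln` left to right; branch lengths are omitted.
#'
#' @param tree A `tree_shape`, `phylo`, or Newick string.
#' @param file Optional path; if given the string is written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- as_tree_shape(tree)
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  rec <- function(x) {
    if (is_leaf(x)) {
      counter$i <- counter$i + 1L
      return(paste0("L", counter$i))
    }
    paste0("(", paste(vapply(x, rec, character(1)), collapse = ","), ")")
  }
  out <- paste0(rec(s), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Convert a tree shape to an ape phylo object
#'
#' @param tree A `tree_shape` with at least 2 leaves (a single vertex cannot
#'   be represented as a `phylo`).
#' @return A `phylo` object with leaves labelled `L1..Ln`.
#' @export
as_phylo_shape <- function(tree) {
  s <- as_tree_shape(tree)
  if (attr(s, "n") < 2L) abort("a single-vertex tree cannot be converted to phylo")
  ape::read.tree(text = write_newick(s))
}

#' @export
print.tree_shape <- function(x, ...) {
  cat(sprintf("<tree_shape: %d leaves, height %d, %s>\n",
              attr(x, "n"), tree_height(x),
              if (is_binary_shape(x)) "binary" else "arbitrary"))
  cat(write_newick(x), "\n")
  invisible(x)
}

#' @export
format.tree_shape <- function(x, ...) write_newick(x)

# Preorder vertex walk. Vertex handles are preorder indices over the
# canonical child order with the root at 1; leaves are included.
walk_vertices <- function(shape, fn) {
  i <- 0L
  rec <- function(x, depth) {
    i <<- i + 1L
    fn(i, x, depth)
    if (!is_leaf(x)) for (ch in x) rec(ch, depth + 1L)
  }
  rec(shape, 0L)
  invisible(i)
}

#' Tabulate the vertices of a tree shape
#'
#' Vertex handles are stable preorder indices (root first, children in
#' canonical key order), which is also the order used by
#' [replace_subtree()].
#'
#' @param tree A `tree_shape`, `phylo`, or Newick string.
#' @return A tibble with columns `vertex`, `depth`, `clade_size`, `is_leaf`,
#'   `out_degree`.
#' @export
vertex_table <- function(tree) {
  s <- as_tree_shape(tree)
  rows <- list()
  walk_vertices(s, function(i, x, depth) {
    rows[[i]] <<- c(i, depth, attr(x, "n"), is_leaf(x), length(x))
  })
  m <- do.call(rbind, rows)
  tibble(
    vertex = as.integer(m[, 1]), depth = as.integer(m[, 2]),
    clade_size = as.integer(m[, 3]), is_leaf = as.logical(m[, 4]),
    out_degree = as.integer(m[, 5])
  )
}

#' Extract the pending subtree at a vertex
#'
#' @param tree A `tree_shape`, `phylo`, or Newick string.
#' @param v Preorder vertex handle (see [vertex_table()]).
#' @return The `tree_shape` rooted at `v`.
#' @export
subtree_at <- function(tree, v) {
  s <- as_tree_shape(tree)
  found <- NULL
  i <- 0L
  rec <- function(x) {
    i <<- i + 1L
    if (i == v) {
      found <<- x
      return(TRUE)
    }
    if (!is_leaf(x)) for (ch in x) if (rec(ch)) return(TRUE)
    FALSE
  }
  rec(s)
  if (is.null(found)) abort(sprintf("no vertex with handle %d", v))
  found
}

#' Replace a pending subtree
#'
#' Replaces the subtree rooted at vertex `v` by `replacement`, which must
#' have the same number of leaves, so that all depths outside the replaced
#' subtree are unchanged.
#'
#' @param tree A `tree_shape`, `phylo`, or Newick string.
#' @param v Preorder vertex handle (see [vertex_table()]).
#' @param replacement A tree shape with `n_leaves(subtree_at(tree, v))`
#'   leaves.
#' @return The modified `tree_shape`.
#' @export
replace_subtree <- function(tree, v, replacement) {
  s <- as_tree_shape(tree)
  r <- as_tree_shape(replacement)
  old <- subtree_at(s, v)
  if (attr(old, "n") != attr(r, "n")) {
    abort(sprintf("replacement has %d leaves but the subtree at vertex %d has %d",
                  attr(r, "n"), v, attr(old, "n")))
  }
  i <- 0L
  rec <- function(x) {
    i <<- i + 1L
    if (i == v) return(r)
    if (is_leaf(x)) return(x)
    new_node(lapply(x, rec))
  }
  rec(s)
}
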