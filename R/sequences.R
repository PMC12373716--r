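# The three ascending tree-shape sequences: balance values (binary only),
# clade sizes, and leaf depths. A shape_seq is an integer vector with a
# `kind` and the leaf count `n` of its source tree, so higher-order
# functionals can access n and the number of inner vertices without
# re-walking the tree.

seq_kinds <- c(balance_values = "B", clade_sizes = "N", leaf_depths = "D")

norm_kind <- function(kind) {
  kind <- as.character(kind[1])
  if (kind %in% c("B", "balance", "balance_values", "b")) return("B")
  if (kind %in% c("N", "clade", "clade_sizes", "n")) return("N")
  if (kind %in% c("D", "depth", "leaf_depths", "delta", "d")) return("D")
  rlang::abort(sprintf("unknown sequence kind '%s' (use B, N, or D)", kind))
}

#' Construct a shape sequence
#'
#' @param x Non-negative integers (sorted ascending on construction).
#' @param kind `"B"` (balance values), `"N"` (clade sizes), or `"D"` (leaf
#'   depths).
#' @param n Leaf count of the source tree.
#' @return A `shape_seq`.
#' @export
shape_seq <- function(x, kind, n) {
  structure(sort(as.integer(x)), kind = norm_kind(kind), n = as.integer(n),
            class = "shape_seq")
}

#' @export
print.shape_seq <- function(x, ...) {
  lab <- names(seq_kinds)[match(attr(x, "kind"), seq_kinds)]
  cat(sprintf("<shape_seq %s, n = %d> (%s)\n", lab, attr(x, "n"),
              paste(unclass(x), collapse = ",")))
  invisible(x)
}

#' Tree shape sequences
#'
#' `balance_sequence()` lists the balance values `|n_v1 - n_v2|` of all
#' inner vertices of a binary tree; `clade_size_sequence()` lists the clade
#' sizes `n_v` of all inner vertices; `leaf_depth_sequence()` lists the
#' depths of all leaves. All three are sorted ascending. For the
#' single-vertex tree the balance and clade size sequences are empty and the
#' leaf depth sequence is `(0)`.
#'
#' @param tree A `tree_shape`, `phylo`, or Newick string.
#' @param kind For [tree_sequence()]: `"B"`, `"N"`, or `"D"`.
#' @return A `shape_seq`.
#' @export
#' @examples
#' balance_sequence(cat_tree(5))     # 0 1 2 3
#' clade_size_sequence(cat_tree(6))  # 2 3 4 5 6
#' leaf_depth_sequence(fb_tree(2))   # 2 2 2 2
tree_sequence <- function(tree, kind) {
  kind <- norm_kind(kind)
  switch(kind,
    B = balance_sequence(tree),
    N = clade_size_sequence(tree),
    D = leaf_depth_sequence(tree)
  )
}

#' @rdname tree_sequence
#' @export
balance_sequence <- function(tree) {
  s <- as_tree_shape(tree)
  vals <- integer(0)
  pos <- 0L
  rec <- function(x) {
    pos <<- pos + 1L
    if (is_leaf(x)) return(invisible(NULL))
    if (length(x) != 2L) {
      rlang::abort(sprintf(
        "balance values are defined for binary trees only; vertex %d has out-degree %d",
        pos, length(x)))
    }
    vals[[length(vals) + 1L]] <<- abs(attr(x[[1]], "n") - attr(x[[2]], "n"))
    for (ch in x) rec(ch)
  }
  rec(s)
  shape_seq(vals, "B", attr(s, "n"))
}

#' @rdname tree_sequence
#' @export
clade_size_sequence <- function(tree) {
  s <- as_tree_shape(tree)
  vals <- integer(0)
  rec <- function(x) {
    if (is_leaf(x)) return(invisible(NULL))
    vals[[length(vals) + 1L]] <<- attr(x, "n")
    for (ch in x) rec(ch)
  }
  rec(s)
  shape_seq(vals, "N", attr(s, "n"))
}

#' @rdname tree_sequence
#' @export
leaf_depth_sequence <- function(tree) {
  s <- as_tree_shape(tree)
  vals <- integer(0)
  rec <- function(x, depth) {
    if (is_leaf(x)) {
      vals[[length(vals) + 1L]] <<- depth
      return(invisible(NULL))
    }
    for (ch in x) rec(ch, depth + 1L)
  }
  rec(s, 0L)
  shape_seq(vals, "D", attr(s, "n"))
}

#' Ordered union of two shape sequences
#'
#' Merges two ascending sequences of the same kind into one ascending
#' sequence of combined length; the leaf counts add.
#'
#' @param a,b `shape_seq` objects of the same kind.
#' @return A `shape_seq`.
#' @export
#' @examples
#' ordered_union(shape_seq(c(1, 4, 5, 13), "N", 5),
#'               shape_seq(c(2, 2, 4, 7, 8), "N", 5))
ordered_union <- function(a, b) {
  if (!inherits(a, "shape_seq") || !inherits(b, "shape_seq")) {
    rlang::abort("ordered_union expects two shape_seq objects")
  }
  if (attr(a, "kind") != attr(b, "kind")) {
    rlang::abort(sprintf("cannot union sequences of kinds %s and %s",
                         attr(a, "kind"), attr(b, "kind")))
  }
  shape_seq(c(unclass(a), unclass(b)), attr(a, "kind"),
            attr(a, "n") + attr(b, "n"))
}

#' Shift a shape sequence
#'
#' Adds a constant to every entry, preserving order.
#'
#' @param a A `shape_seq`.
#' @param amount Non-negative integer.
#' @return A `shape_seq`.
#' @export
seq_shift <- function(a, amount) {
  if (!inherits(a, "shape_seq")) rlang::abort("seq_shift expects a shape_seq")
  if (amount < 0) rlang::abort("shift amount must be non-negative")
  shape_seq(unclass(a) + as.integer(amount), attr(a, "kind"), attr(a, "n"))
}
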