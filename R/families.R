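# Constructors for the special tree families. Each family is unique up to
# isomorphism at a given leaf count, and every pending subtree of a family
# member belongs to the same family.

#' Construct a special tree
#'
#' Builds one of the named tree families:
#' \describe{
#'   \item{caterpillar}{binary, exactly one cherry; the most imbalanced
#'     shape.}
#'   \item{fully_balanced}{binary of height `h` with all `2^h` leaves at
#'     depth `h`; here `size` is the height `h >= 0`.}
#'   \item{maximally_balanced}{binary with every inner vertex balanced
#'     (balance value at most 1), built by the recursive
#'     ceiling/floor split.}
#'   \item{greedy_from_bottom}{binary tree obtained by repeatedly joining
#'     the two trees of currently minimal leaf count, starting from `n`
#'     single vertices.}
#'   \item{star}{all `n` leaves attached to the root.}
#' }
#'
#' @param family One of `"caterpillar"`, `"fully_balanced"`,
#'   `"maximally_balanced"`, `"greedy_from_bottom"`, `"star"` (or the
#'   shorthands `"cat"`, `"fb"`, `"mb"`, `"gfb"`, `"star"`).
#' @param size Number of leaves (`>= 1`), except for `fully_balanced` where
#'   it is the height (`>= 0`).
#' @return A `tree_shape`.
#' @export
#' @examples
#' make_tree("gfb", 6)
#' make_tree("fb", 3)
make_tree <- function(family, size) {
  family <- match.arg(family, c(
    "caterpillar", "fully_balanced", "maximally_balanced",
    "greedy_from_bottom", "star", "cat", "fb", "mb", "gfb"
  ))
  switch(family,
    caterpillar = , cat = cat_tree(size),
    fully_balanced = , fb = fb_tree(size),
    maximally_balanced = , mb = mb_tree(size),
    greedy_from_bottom = , gfb = gfb_tree(size),
    star = star_tree(size)
  )
}

check_size <- function(n, min = 1L) {
  if (length(n) != 1L || is.na(n) || n < min || n != as.integer(n)) {
    rlang::abort(sprintf("size must be a single integer >= %d", min))
  }
  as.integer(n)
}

#' @rdname make_tree
#' @param n Number of leaves.
#' @export
cat_tree <- function(n) {
  n <- check_size(n)
  s <- new_leaf()
  while (n > 1L) {
    s <- new_node(list(s, new_leaf()))
    n <- n - 1L
  }
  s
}

#' @rdname make_tree
#' @param h Height (`>= 0`); the tree has `2^h` leaves.
#' @export
fb_tree <- function(h) {
  h <- check_size(h, min = 0L)
  s <- new_leaf()
  for (i in seq_len(h)) s <- new_node(list(s, s))
  s
}

#' @rdname make_tree
#' @export
mb_tree <- function(n) {
  n <- check_size(n)
  if (n == 1L) return(new_leaf())
  new_node(list(mb_tree(ceiling(n / 2)), mb_tree(floor(n / 2))))
}

#' @rdname make_tree
#' @export
gfb_tree <- function(n) {
  n <- check_size(n)
  pool <- replicate(n, new_leaf(), simplify = FALSE)
  while (length(pool) > 1L) {
    sizes <- vapply(pool, function(s) attr(s, "n"), integer(1))
    keys <- vapply(pool, function(s) attr(s, "key"), character(1))
    # join the two smallest trees; among equal sizes take the ones with
    # lexicographically smallest canonical keys, for determinism
    ord <- order(sizes, keys, method = "radix")
    joined <- new_node(pool[ord[1:2]])
    pool <- c(pool[-ord[1:2]], list(joined))
  }
  pool[[1]]
}

#' @rdname make_tree
#' @export
star_tree <- function(n) {
  n <- check_size(n)
  if (n == 1L) return(new_leaf())
  new_node(replicate(n, new_leaf(), simplify = FALSE))
}

# Alternative gfb construction: take the fully balanced tree of height
# h_n - 1 and attach p = n - 2^(h_n - 1) cherries to its leftmost leaves.
# Used as an independent cross-check on the greedy joining above.
gfb_tree_via_cherries <- function(n) {
  n <- check_size(n)
  if (n == 1L) return(new_leaf())
  h <- ceiling(log2(n))
  p <- n - 2^(h - 1)
  attach_left <- function(x, k) {
    # replace the k leftmost leaves of x by cherries; returns list(shape, left)
    if (k == 0L) return(list(x, 0L))
    if (is_leaf(x)) {
      return(list(new_node(list(new_leaf(), new_leaf())), k - 1L))
    }
    kids <- vector("list", length(x))
    for (i in seq_along(x)) {
      res <- attach_left(x[[i]], k)
      kids[[i]] <- res[[1]]
      k <- res[[2]]
    }
    list(new_node(kids), k)
  }
  attach_left(fb_tree(h - 1L), as.integer(p))[[1]]
}

#' Trees minimizing the Sackin index, constructed directly
#'
#' For leaf count `n` with `h = ceiling(log2(n))`, the Sackin-minimal binary
#' trees are exactly those obtained from the fully balanced tree of height
#' `h - 1` by attaching `n - 2^(h-1)` cherries to its leaves. This
#' constructs all of them (one representative per isomorphism class), which
#' is the `argmin S(T)` minimizer target of the recommendation logic.
#'
#' @param n Number of leaves (`>= 1`).
#' @return A list of `tree_shape` objects, one per isomorphism class.
#' @export
argmin_sackin_set <- function(n) {
  n <- check_size(n)
  if (n == 1L) return(list(new_leaf()))
  h <- ceiling(log2(n))
  if (n == 2^h) return(list(fb_tree(h)))
  base_leaves <- 2^(h - 1)
  p <- n - base_leaves
  fb <- fb_tree(h - 1L)
  out <- new.env(parent = emptyenv())
  for (subset in utils::combn(base_leaves, p, simplify = FALSE)) {
    i <- 0L
    rec <- function(x) {
      if (is_leaf(x)) {
        i <<- i + 1L
        if (i %in% subset) return(new_node(list(new_leaf(), new_leaf())))
        return(x)
      }
      new_node(lapply(x, rec))
    }
    s <- rec(fb)
    assign(attr(s, "key"), s, envir = out)
  }
  unname(as.list(out))
}

#' Trees minimizing the Colless index, constructed directly
#'
#' The Colless-minimal binary trees are the subset of the Sackin-minimal
#' trees ([argmin_sackin_set()]) whose Colless index equals the closed-form
#' minimum [colless_min()].
#'
#' @param n Number of leaves (`>= 1`).
#' @return A list of `tree_shape` objects.
#' @export
argmin_colless_set <- function(n) {
  cands <- argmin_sackin_set(n)
  cmin <- colless_min(n)
  Filter(function(s) colless(s) == cmin, cands)
}
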