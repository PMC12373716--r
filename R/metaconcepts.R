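# Sequence functionals Phi^Seq_f: sum a shape function over a tree's
# balance value, clade size, or leaf depth sequence. All classical indices
# below are instances of phi() with the appropriate f; each is also
# implemented directly from its defining sequence so that the two routes
# can be cross-checked.

#' Evaluate a sequence functional on a tree
#'
#' Computes `sum_{s in Seq(T)} f(s, n, ninner)` where `Seq` is the balance
#' value (`"B"`, binary trees only), clade size (`"N"`), or leaf depth
#' (`"D"`) sequence. An empty sequence sums to 0. Higher-order shape
#' functions receive the tree's leaf count `n` and number of inner vertices
#' `ninner` as extras.
#'
#' @param tree A `tree_shape`, `phylo`, or Newick string.
#' @param kind `"B"`, `"N"`, or `"D"`.
#' @param f A `shape_fun`, plain function of x, or expression string.
#' @return A number.
#' @export
#' @examples
#' phi(gfb_tree(5), "B", sf_log(base = 2, scale = 0.5, shift = 1)) # ~1.17
#' phi(fb_tree(2), "D", sf_expr("x / (x + 0.5)"))                  # 3.2
phi <- function(tree, kind, f) {
  s <- as_tree_shape(tree)
  kind <- norm_kind(kind)
  f <- as_shape_fun(f)
  sq <- tree_sequence(s, kind)
  vals <- unclass(sq)
  if (length(vals) == 0L) return(0)
  if (any(vals < f$domain_min)) {
    bad <- vals[vals < f$domain_min][1]
    rlang::abort(sprintf(
      "shape function '%s' is undefined at sequence entry %d (domain starts at %g)",
      f$label, bad, f$domain_min))
  }
  n <- attr(sq, "n")
  ninner <- length(unclass(clade_size_sequence(s)))
  sum(f$fn(vals, n = n, ninner = ninner))
}

#' Evaluate a functional over many trees
#'
#' @param trees A list of trees (any representation accepted by
#'   [as_tree_shape()]).
#' @param kind `"B"`, `"N"`, or `"D"`.
#' @param f A `shape_fun`, function, or expression string.
#' @return A tibble with columns `tree` (canonical key), `n`, and `value`.
#' @export
phi_table <- function(trees, kind, f) {
  f <- as_shape_fun(f)
  shapes <- lapply(trees, as_tree_shape)
  tibble(
    tree = vapply(shapes, function(s) attr(s, "key"), character(1)),
    n = vapply(shapes, function(s) attr(s, "n"), integer(1)),
    value = vapply(shapes, function(s) phi(s, kind, f), numeric(1))
  )
}

#' Classical imbalance indices
#'
#' Direct implementations of the classical indices that the sequence
#' functionals generalize. `sackin()` is the sum of all leaf depths (equal
#' to the sum of all inner clade sizes); `avg_leaf_depth()` divides by the
#' leaf count; `s_hat()` sums `log(n_v - 1)` over inner vertices;
#' `total_cophenetic()` sums `choose(n_v, 2)` over non-root inner vertices
#' (equivalently, the depth of the lowest common ancestor over all leaf
#' pairs). `colless()`, `corrected_colless()` and `quadratic_colless()` sum
#' the balance values, their normalized form (`0` for `n <= 2` by
#' convention), and their squares; these require binary trees.
#'
#' @param tree A `tree_shape`, `phylo`, or Newick string.
#' @param base Logarithm base for `s_hat()` (the choice only rescales the
#'   index and never changes tree rankings).
#' @return A number.
#' @export
sackin <- function(tree) {
  sum(unclass(leaf_depth_sequence(tree)))
}

#' @rdname sackin
#' @export
avg_leaf_depth <- function(tree) {
  s <- as_tree_shape(tree)
  sackin(s) / attr(s, "n")
}

#' @rdname sackin
#' @export
s_hat <- function(tree, base = exp(1)) {
  nv <- unclass(clade_size_sequence(tree))
  sum(log(nv - 1, base = base))
}

#' @rdname sackin
#' @export
total_cophenetic <- function(tree) {
  s <- as_tree_shape(tree)
  nv <- unclass(clade_size_sequence(s))
  n <- attr(s, "n")
  if (n < 2L) return(0)
  sum(choose(nv, 2)) - choose(n, 2)
}

#' @rdname sackin
#' @export
colless <- function(tree) {
  sum(unclass(balance_sequence(tree)))
}

#' @rdname sackin
#' @export
corrected_colless <- function(tree) {
  s <- as_tree_shape(tree)
  n <- attr(s, "n")
  C <- colless(s)
  if (n <= 2L) return(0)
  2 * C / ((n - 1) * (n - 2))
}

#' @rdname sackin
#' @export
quadratic_colless <- function(tree) {
  sum(unclass(balance_sequence(tree))^2)
}

#' All classical indices for a set of trees
#'
#' @param trees A list of trees.
#' @return A tibble with one row per tree and one column per index (the
#'   Colless family columns are `NA` for non-binary shapes).
#' @export
tree_indices <- function(trees) {
  shapes <- lapply(trees, as_tree_shape)
  purrr::map_dfr(shapes, function(s) {
    bin <- is_binary_shape(s)
    tibble(
      tree = attr(s, "key"),
      n = attr(s, "n"),
      sackin = sackin(s),
      avg_leaf_depth = avg_leaf_depth(s),
      s_hat = s_hat(s),
      total_cophenetic = total_cophenetic(s),
      colless = if (bin) colless(s) else NA_real_,
      corrected_colless = if (bin) corrected_colless(s) else NA_real_,
      quadratic_colless = if (bin) quadratic_colless(s) else NA_real_
    )
  })
}

#' Recursive evaluation of a sequence functional
#'
#' Evaluates `phi()` through the standard-decomposition recursions: for the
#' balance value functional, `Phi(T) = Phi(T1) + Phi(T2) + f(|n1 - n2|)`;
#' for the clade size functional, `Phi(T) = sum_i Phi(Ti) + f(n)`; for the
#' leaf depth functional (affine `f` with zero intercept only),
#' `Phi(T) = sum_i Phi(Ti) + n * m`. The result equals the direct
#' evaluation exactly, up to floating-point accumulation.
#'
#' @inheritParams phi
#' @return A number.
#' @export
recursive_phi <- function(tree, kind, f) {
  s <- as_tree_shape(tree)
  kind <- norm_kind(kind)
  f <- as_shape_fun(f)
  if (kind == "D") {
    m <- affine_zero_intercept_slope(f)
    if (is.null(m)) {
      rlang::abort(paste0(
        "the leaf depth functional is recursive only for affine shape ",
        "functions with zero intercept"))
    }
    rec <- function(x) {
      if (is_leaf(x)) return(0)
      sum(vapply(x, rec, numeric(1))) + attr(x, "n") * m
    }
    return(rec(s))
  }
  if (kind == "B") {
    rec <- function(x) {
      if (is_leaf(x)) return(0)
      if (length(x) != 2L) {
        rlang::abort("balance value functionals require binary trees")
      }
      rec(x[[1]]) + rec(x[[2]]) +
        f$fn(abs(attr(x[[1]], "n") - attr(x[[2]], "n")))
    }
    return(rec(s))
  }
  rec <- function(x) {
    if (is_leaf(x)) return(0)
    sum(vapply(x, rec, numeric(1))) + f$fn(attr(x, "n"))
  }
  rec(s)
}

# Returns the slope if f is affine with (numerically) zero intercept on the
# integer grid 0..8, otherwise NULL.
affine_zero_intercept_slope <- function(f) {
  if (identical(f$family, "affine")) {
    if (isTRUE(all.equal(f$params$a, 0))) return(f$params$m) else return(NULL)
  }
  xs <- 0:8
  ys <- f$fn(xs)
  d <- diff(ys)
  if (abs(ys[1]) < 1e-12 && max(abs(d - d[1])) < 1e-12) d[1] else NULL
}

#' Do two indices rank all shapes identically?
#'
#' Two tree shape statistics are equivalent on a domain if they induce the
#' same strict-order comparisons over every pair of shapes:
#' `t1(T) < t1(T')` exactly when `t2(T) < t2(T')`. This checks the
#' condition exhaustively over all enumerated shapes with `n` leaves, and
#' additionally reports whether the tie sets coincide.
#'
#' @param idx1,idx2 Functions mapping a tree to a number.
#' @param n Leaf count (within enumeration bounds).
#' @param domain `"binary"` or `"arbitrary"`.
#' @param tol Values closer than `tol` are considered tied.
#' @return `TRUE`/`FALSE`, with attribute `ties_agree`.
#' @export
equivalent_on <- function(idx1, idx2, n, domain = c("binary", "arbitrary"),
                          tol = 1e-9) {
  domain <- match.arg(domain)
  shapes <- enumerate_shapes(n, domain)
  v1 <- vapply(shapes, idx1, numeric(1))
  v2 <- vapply(shapes, idx2, numeric(1))
  grp <- function(v) {
    o <- order(v)
    g <- cumsum(c(TRUE, diff(v[o]) > tol))
    g[order(o)] # tie-group id per shape, ordered by value
  }
  g1 <- grp(v1)
  g2 <- grp(v2)
  # strict-order agreement: for every pair, sign(v1_i - v1_j) == sign(v2_i - v2_j)
  ok <- TRUE
  ties <- TRUE
  for (i in seq_along(g1)) {
    si <- sign(g1 - g1[i])
    ti <- sign(g2 - g2[i])
    strict <- si != 0 & ti != 0
    if (any(si[strict] != ti[strict])) ok <- FALSE
    if (any((si == 0) != (ti == 0))) ties <- FALSE
    if (any(si != 0 & ti == 0) || any(si == 0 & ti != 0)) ok <- FALSE
    if (!ok) break
  }
  structure(ok, ties_agree = ties)
}
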