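# Closed-form extremal values of the sequence functionals, subtree-count
# formulas for the gfb- and mb-trees, brute-force extremal sets over
# enumerated shapes, and the minimal sequence-coincidence search.
#
# Throughout, h_n = ceiling(log2(n)) is the height of the Sackin-minimal
# trees with n leaves.

h_ceil <- function(n) as.integer(ceiling(log2(n)))

#' Minimum Colless index
#'
#' Closed form `c_n = sum_{i=1}^{h_n - 1} 2^i * s(n / 2^i)` where `s(x)` is
#' the distance from `x` to its nearest integer and `h_n = ceiling(log2 n)`.
#' This is the Colless index of the maximally balanced tree (and the
#' gfb-tree).
#'
#' @param n Number of leaves (`>= 1`).
#' @return An integer.
#' @export
#' @examples
#' colless_min(5) # 2
#' colless_min(8) # 0
colless_min <- function(n) {
  n <- check_size(n)
  h <- h_ceil(n)
  if (h <= 1L) return(0L)
  i <- seq_len(h - 1L)
  x <- n / 2^i
  s <- abs(x - round(x))
  as.integer(round(sum(2^i * s)))
}

#' Extremes of the Sackin index on binary trees
#'
#' The minimum is `-2^h_n + n * (h_n + 1)` with `h_n = ceiling(log2 n)`
#' (equal to `h * 2^h` when `n = 2^h`), attained by all trees using only
#' leaf depths `h_n - 1` and `h_n`; the maximum is `n(n+1)/2 - 1`, attained
#' uniquely by the caterpillar.
#'
#' @param n Number of leaves (`>= 1`).
#' @return A named list with elements `min` and `max`.
#' @export
sackin_extremes <- function(n) {
  n <- check_size(n)
  h <- h_ceil(n)
  list(min = -2^h + n * (h + 1), max = n * (n + 1) / 2 - 1)
}

#' Subtree counts of the gfb-tree
#'
#' `gfb_subtree_count(n, i)` is the number of pending subtrees of the
#' greedy-from-the-bottom tree with `n` leaves that have exactly `i`
#' leaves, by the four-case closed form (with `h_i = ceiling(log2 i)`):
#' `floor(n/i)` or `floor(n/i) - 1` when `i` is a power of two (depending
#' on `n mod i` versus `2^(h_i - 1)`), and 1 or 0 otherwise (depending on
#' whether `2^(h_i - 1)` divides `n - i`).
#'
#' @param n Number of leaves of the gfb-tree.
#' @param i Subtree size(s), `1 <= i <= n` (vectorized).
#' @return Integer count(s).
#' @export
#' @examples
#' gfb_subtree_count(6, 2) # 3 cherries
gfb_subtree_count <- function(n, i) {
  n <- check_size(n)
  if (any(i < 1 | i > n)) rlang::abort("subtree size i must satisfy 1 <= i <= n")
  vapply(as.integer(i), function(ii) {
    hi <- h_ceil(ii)
    if (ii == 2^hi) {
      r <- n %% ii
      if (r == 0 || r >= 2^(hi - 1)) return(n %/% ii)
      return(n %/% ii - 1L)
    }
    if ((n - ii) %% 2^(hi - 1) == 0) 1L else 0L
  }, integer(1))
}

#' Subtree counts of the maximally balanced tree
#'
#' `mb_subtree_count(n, i)` counts the pending subtrees with `i` leaves of
#' the maximally balanced tree with `n` leaves, by counting clade sizes on
#' the constructed tree. `mb_r_param(n, l)` exposes the decomposition
#' parameter `r_l^n = n - 2^l * floor(n / 2^l)` of that tree.
#'
#' @param n Number of leaves of the mb-tree.
#' @param i Subtree size(s), `1 <= i <= n` (vectorized).
#' @param l Level, `0 <= l <= ceiling(log2 n)`.
#' @return Integer count(s).
#' @export
#' @examples
#' mb_subtree_count(5, 2) # 2
mb_subtree_count <- function(n, i) {
  n <- check_size(n)
  if (any(i < 1 | i > n)) rlang::abort("subtree size i must satisfy 1 <= i <= n")
  sizes <- c(unclass(clade_size_sequence(mb_tree(n))), rep(1L, n))
  vapply(as.integer(i), function(ii) sum(sizes == ii), integer(1))
}

#' @rdname mb_subtree_count
#' @export
mb_r_param <- function(n, l) {
  n - 2^l * floor(n / 2^l)
}

new_extremal_report <- function(kind, f_label, n, domain, min_value, max_value,
                                min_keys, max_keys, method) {
  structure(
    list(kind = kind, f = f_label, n = n, domain = domain,
         min_value = min_value, max_value = max_value,
         min_keys = min_keys, max_keys = max_keys, method = method),
    class = "extremal_report"
  )
}

#' @export
print.extremal_report <- function(x, ...) {
  cat(sprintf("<extremal_report %s-functional, f = %s, n = %d, %s domain (%s)>\n",
              x$kind, x$f, x$n, x$domain, x$method))
  cat(sprintf("  min %s attained by %d shape(s)\n", format(x$min_value),
              length(x$min_keys)))
  cat(sprintf("  max %s attained by %d shape(s)\n", format(x$max_value),
              length(x$max_keys)))
  invisible(x)
}

#' Closed-form extremes of the balance value functional
#'
#' For increasing `f` the caterpillar attains the maximum
#' `sum_{i=0}^{n-2} f(i)`. The minimum is `(n-1) * f(0)` when `n` is a
#' power of two (fully balanced tree); for convex `f` it is
#' `c_n * f(1) + (n - 1 - c_n) * f(0)` (maximally balanced tree); for
#' affine `f(x) = m x + a` it is `m * c_n + (n-1) * a`, attained exactly by
#' the Colless-minimal trees.
#'
#' @param f A `shape_fun` (certified or declared family decides which
#'   minimum formula applies). A warning is raised if `f` is not
#'   increasing, in which case the formulas carry no guarantee.
#' @param n Number of leaves.
#' @return An `extremal_report` with `method = "closed_form"`; `NA` minimum
#'   when no closed form covers `f`'s family.
#' @export
bvm_extremes <- function(f, n) {
  f <- as_shape_fun(f)
  n <- check_size(n)
  cert <- classify_function(f, domain_bound = max(8, n))
  if (!cert$increasing) {
    rlang::warn("f is not increasing on the scanned grid; extremal formulas are not guaranteed")
  }
  max_value <- if (n >= 2L) sum(f$fn(0:(n - 2))) else 0
  cn <- colless_min(n)
  pow2 <- n == 2^h_ceil(n)
  if (pow2) {
    min_value <- (n - 1) * f$fn(0)
    min_keys <- canonical_key(fb_tree(h_ceil(n)))
  } else if (cert$affine) {
    min_value <- cert$slope * cn + (n - 1) * cert$intercept
    min_keys <- vapply(argmin_colless_set(n), canonical_key, character(1))
  } else if (cert$convex) {
    min_value <- cn * f$fn(1) + (n - 1 - cn) * f$fn(0)
    min_keys <- canonical_key(mb_tree(n))
  } else {
    min_value <- NA_real_
    min_keys <- character(0)
  }
  new_extremal_report("B", f$label, n, "binary", min_value, max_value,
                      min_keys, canonical_key(cat_tree(n)), "closed_form")
}

#' Closed-form extremes of the clade size functional
#'
#' The caterpillar maximum is `sum_{i=2}^n f(i)` (valid on the arbitrary
#' domain when `f` is additionally 2-positive). Minima: strictly concave
#' `f` gives `sum_i gfb_n(i) f(i)` at the gfb-tree; strictly convex `f`
#' gives `sum_i mb_n(i) f(i)` at the mb-tree; affine `f` follows the Sackin
#' minimum; on the arbitrary domain the star tree gives `f(n)` for
#' 2-positive `f`.
#'
#' @inheritParams bvm_extremes
#' @param domain `"binary"` or `"arbitrary"`.
#' @return An `extremal_report` with `method = "closed_form"`.
#' @export
csm_extremes <- function(f, n, domain = c("binary", "arbitrary")) {
  f <- as_shape_fun(f)
  n <- check_size(n)
  domain <- match.arg(domain)
  cert <- classify_function(f, domain_bound = max(8, n))
  if (!cert$increasing && domain == "binary") {
    rlang::warn("f is not increasing on the scanned grid; extremal formulas are not guaranteed")
  }
  if (n == 1L) {
    return(new_extremal_report("N", f$label, n, domain, 0, 0,
                               canonical_key(new_leaf()),
                               canonical_key(new_leaf()), "closed_form"))
  }
  i <- 2:n
  max_value <- sum(f$fn(i))
  if (domain == "arbitrary") {
    if (!cert$two_positive) {
      rlang::warn("f is not 2-positive; arbitrary-domain extremes are not guaranteed")
    }
    min_value <- f$fn(n)
    min_keys <- canonical_key(star_tree(n))
  } else if (cert$strictly_concave) {
    min_value <- sum(gfb_subtree_count(n, i) * f$fn(i))
    min_keys <- canonical_key(gfb_tree(n))
  } else if (cert$strictly_convex) {
    min_value <- sum(mb_subtree_count(n, i) * f$fn(i))
    min_keys <- canonical_key(mb_tree(n))
  } else if (cert$affine) {
    h <- h_ceil(n)
    min_value <- cert$slope * (-2^h + n * (h + 1)) + (n - 1) * cert$intercept
    min_keys <- vapply(argmin_sackin_set(n), canonical_key, character(1))
  } else {
    min_value <- NA_real_
    min_keys <- character(0)
  }
  new_extremal_report("N", f$label, n, domain, min_value, max_value,
                      min_keys, canonical_key(cat_tree(n)), "closed_form")
}

#' Closed-form extremes of the leaf depth functional
#'
#' Affine `f(x) = m x + a` with `m > 0`: maximum
#' `m * (n(n+1)/2 - 1) + n * a` (caterpillar) and binary minimum
#' `m * (-2^h_n + n (h_n + 1)) + n * a` (Sackin-minimal trees). Strictly
#' increasing convex `f`: maximum `f(n-1) + sum_{i=1}^{n-1} f(i)` and,
#' writing `n = 2^(h_n - 1) + p`, binary minimum
#' `(2^(h_n - 1) - p) f(h_n - 1) + 2 p f(h_n)`. On the arbitrary domain any
#' increasing `f` has minimum `n * f(1)` at the star tree. For concave
#' non-affine `f` the minimizer depends on `f` and no closed form applies.
#'
#' @inheritParams csm_extremes
#' @return An `extremal_report` with `method = "closed_form"`.
#' @export
ldm_extremes <- function(f, n, domain = c("binary", "arbitrary")) {
  f <- as_shape_fun(f)
  n <- check_size(n)
  domain <- match.arg(domain)
  cert <- classify_function(f, domain_bound = max(8, n))
  if (!cert$increasing) {
    rlang::warn("f is not increasing on the scanned grid; extremal formulas are not guaranteed")
  }
  if (n == 1L) {
    v <- f$fn(0)
    return(new_extremal_report("D", f$label, n, domain, v, v,
                               canonical_key(new_leaf()),
                               canonical_key(new_leaf()), "closed_form"))
  }
  h <- h_ceil(n)
  if (cert$affine) {
    m <- cert$slope; a <- cert$intercept
    max_value <- m * (n * (n + 1) / 2 - 1) + n * a
  } else if (cert$convex) {
    max_value <- f$fn(n - 1) + sum(f$fn(seq_len(n - 1)))
  } else {
    max_value <- NA_real_
  }
  if (domain == "arbitrary") {
    min_value <- n * f$fn(1)
    min_keys <- canonical_key(star_tree(n))
  } else if (cert$affine) {
    min_value <- cert$slope * (-2^h + n * (h + 1)) + n * cert$intercept
    min_keys <- vapply(argmin_sackin_set(n), canonical_key, character(1))
  } else if (cert$convex) {
    p <- n - 2^(h - 1)
    min_value <- (2^(h - 1) - p) * f$fn(h - 1) + 2 * p * f$fn(h)
    min_keys <- vapply(argmin_sackin_set(n), canonical_key, character(1))
  } else {
    min_value <- NA_real_
    min_keys <- character(0)
  }
  new_extremal_report("D", f$label, n, domain, min_value, max_value,
                      min_keys, canonical_key(cat_tree(n)), "closed_form")
}

#' Extremal shapes and values by exhaustive enumeration
#'
#' The brute-force oracle: evaluates the functional on every enumerated
#' shape with `n` leaves and reports the exact minimum and maximum values
#' together with the full sets of minimizing and maximizing shapes.
#'
#' @inheritParams phi
#' @param n Number of leaves (within enumeration bounds; defaults cover
#'   binary `n <= 12`, arbitrary `n <= 8` comfortably).
#' @param domain `"binary"` or `"arbitrary"`.
#' @param tol Values within `tol` of the extreme count as attaining it.
#' @return An `extremal_report` with `method = "enumeration"`.
#' @export
enumerate_extremes <- function(kind, f, n, domain = c("binary", "arbitrary"),
                               tol = 1e-9) {
  kind <- norm_kind(kind)
  domain <- match.arg(domain)
  f <- as_shape_fun(f)
  if (kind == "B" && domain != "binary") {
    rlang::abort("balance value functionals are defined on binary trees only")
  }
  shapes <- enumerate_shapes(n, domain)
  vals <- vapply(shapes, function(s) phi(s, kind, f), numeric(1))
  keys <- vapply(shapes, canonical_key, character(1))
  new_extremal_report(
    kind, f$label, n, domain,
    min(vals), max(vals),
    keys[vals <= min(vals) + tol], keys[vals >= max(vals) - tol],
    "enumeration"
  )
}

# ---- minimal sequence coincidences -----------------------------------------

seq_key <- function(s, kind) {
  paste(unclass(tree_sequence(s, kind)), collapse = ",")
}

coincidence_preds <- c("B_equal", "B_different", "N_equal", "N_different",
                       "D_equal", "D_different")

# does some pair of shapes at this n satisfy both predicates? keys1/keys2
# are the per-shape sequence strings for the two predicates' sequences
pair_exists <- function(k1, eq1, k2, eq2) {
  if (eq1 && eq2) {
    return(anyDuplicated(paste(k1, k2, sep = "|")) > 0L)
  }
  if (eq1 && !eq2) {
    groups <- split(k2, k1)
    return(any(vapply(groups, function(g) length(unique(g)) > 1L, logical(1))))
  }
  if (!eq1 && eq2) {
    groups <- split(k1, k2)
    return(any(vapply(groups, function(g) length(unique(g)) > 1L, logical(1))))
  }
  # both different: need a pair differing in both sequences
  for (i in seq_along(k1)) {
    if (any(k1 != k1[i] & k2 != k2[i])) return(TRUE)
  }
  FALSE
}

#' Smallest n with a sequence coincidence between distinct binary shapes
#'
#' Finds the smallest leaf count at which two non-isomorphic rooted binary
#' tree shapes jointly satisfy two predicates on their shape sequences,
#' e.g. "equal balance value sequences" and "different clade size
#' sequences". The search compares ascending sequences over all enumerated
#' binary shapes for increasing `n`.
#'
#' @param first,second Predicates among `"B_equal"`, `"B_different"`,
#'   `"N_equal"`, `"N_different"`, `"D_equal"`, `"D_different"`.
#' @param n_max Upper search bound (default 14).
#' @return The smallest such `n` as an integer, or `NA` if none is found up
#'   to `n_max`.
#' @export
#' @examples
#' \donttest{
#' minimal_sequence_coincidence("B_different", "D_equal") # 6
#' }
minimal_sequence_coincidence <- function(first, second, n_max = 14) {
  first <- match.arg(first, coincidence_preds)
  second <- match.arg(second, coincidence_preds)
  s1 <- substr(first, 1, 1)
  s2 <- substr(second, 1, 1)
  eq1 <- endsWith(first, "equal")
  eq2 <- endsWith(second, "equal")
  for (n in 4:n_max) {
    shapes <- enumerate_binary_shapes(n)
    k1 <- vapply(shapes, seq_key, character(1), kind = s1)
    k2 <- vapply(shapes, seq_key, character(1), kind = s2)
    if (pair_exists(k1, eq1, k2, eq2)) return(as.integer(n))
  }
  NA_integer_
}
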