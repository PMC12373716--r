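# Certification of shape-function properties on the integer grid, empirical
# verification of the imbalance-index definition and of locality, entrywise
# sequence dominance, and the recommendation logic that maps a requested
# domain/sequence/minimizer combination to the function families that
# deliver it.

#' Certify properties of a shape function on an integer grid
#'
#' Scans `f` on the integers from its domain start up to `domain_bound` and
#' certifies monotonicity, convexity/concavity (via finite differences:
#' concavity means the increments decrease), affinity (constant first
#' difference, with slope and intercept recovered), 2-positivity
#' (`f(x) > 0` for all scanned `x >= 2`), and non-negativity. Functionals
#' only ever evaluate `f` at integers up to the leaf count, so a grid
#' certificate at a sufficient bound is exact for all uses below that
#' bound. Strictness uses tolerance 0 for integer-valued differences and
#' `1e-12` relative otherwise. If `f` is a declared parametric family the
#' certificate is derived from the parameters where possible.
#'
#' @param f A `shape_fun`, function, or expression string.
#' @param domain_bound Largest integer scanned (default 256; must be
#'   `>= 3`).
#' @return A `fun_certificate` (see [tidy.fun_certificate()]).
#' @export
#' @examples
#' classify_function(sf_power(2))
#' classify_function(sf_log(shift = -1)) # s-hat: concave, not 2-positive
classify_function <- function(f, domain_bound = 256) {
  f <- as_shape_fun(f)
  if (domain_bound < 3) {
    rlang::abort("domain_bound must be at least 3 to certify convexity")
  }
  xs <- seq(max(0, ceiling(f$domain_min)), domain_bound)
  if (length(xs) < 3L) rlang::abort("domain too small to certify convexity")
  ys <- f$fn(xs)
  if (any(!is.finite(ys))) {
    rlang::abort(sprintf("f is not finite on its stated domain (first bad x = %g)",
                         xs[which(!is.finite(ys))[1]]))
  }
  d1 <- diff(ys)
  d2 <- diff(d1)
  integer_valued <- max(abs(ys - round(ys))) < 1e-12
  tol <- if (integer_valued) 0 else 1e-12 * max(1, max(abs(ys)))
  affine <- all(abs(d2) <= tol)
  slope <- if (affine) mean(d1) else NA_real_
  intercept <- if (affine) ys[1] - slope * xs[1] else NA_real_
  if (identical(f$family, "affine")) {
    affine <- TRUE
    slope <- f$params$m
    intercept <- f$params$a
  }
  x2 <- xs >= 2
  structure(
    list(
      label = f$label,
      increasing = all(d1 >= -tol),
      strictly_increasing = all(d1 > tol),
      convex = all(d2 >= -tol),
      strictly_convex = all(d2 > tol),
      concave = all(d2 <= tol),
      strictly_concave = all(d2 < -tol),
      affine = affine, slope = slope, intercept = intercept,
      two_positive = any(x2) && all(ys[x2] > 0),
      non_negative = all(ys >= 0),
      domain_min = xs[1], domain_bound = domain_bound,
      method = if (identical(f$family, "custom")) "finite_difference_scan"
               else "declared_family"
    ),
    class = "fun_certificate"
  )
}

#' @export
print.fun_certificate <- function(x, ...) {
  flag <- function(v) if (isTRUE(v)) "yes" else "no"
  cat(sprintf("<fun_certificate for %s on [%g, %g] (%s)>\n",
              x$label, x$domain_min, x$domain_bound, x$method))
  cat(sprintf("  increasing: %s (strict: %s)\n", flag(x$increasing),
              flag(x$strictly_increasing)))
  cat(sprintf("  convex: %s (strict: %s); concave: %s (strict: %s)\n",
              flag(x$convex), flag(x$strictly_convex), flag(x$concave),
              flag(x$strictly_concave)))
  if (x$affine) {
    cat(sprintf("  affine with slope %g, intercept %g\n", x$slope, x$intercept))
  }
  cat(sprintf("  2-positive: %s; non-negative: %s\n", flag(x$two_positive),
              flag(x$non_negative)))
  invisible(x)
}

#' Verify the imbalance-index definition empirically
#'
#' An imbalance index must (i) be uniquely maximized by the caterpillar on
#' its domain for every `n`, and (ii) be uniquely minimized by the fully
#' balanced tree on binary trees whenever `n` is a power of two. This
#' checks both conditions by exhaustive enumeration for each `n` up to
#' `n_max` and reports the first counterexample, if any.
#'
#' @inheritParams phi
#' @param n_max Largest leaf count checked.
#' @param domain `"binary"` or `"arbitrary"`.
#' @return A list with `pass` (logical) and, on failure, `failure` holding
#'   `n`, the violated condition, and the witness shape keys.
#' @export
verify_imbalance_index <- function(kind, f, n_max, domain = c("binary", "arbitrary")) {
  kind <- norm_kind(kind)
  domain <- match.arg(domain)
  f <- as_shape_fun(f)
  for (n in 2:n_max) {
    rep <- enumerate_extremes(kind, f, n, domain)
    cat_key <- canonical_key(cat_tree(n))
    if (!identical(rep$max_keys, cat_key)) {
      return(list(pass = FALSE, failure = list(
        n = n, condition = "caterpillar_unique_max",
        witnesses = setdiff(rep$max_keys, cat_key))))
    }
    if (n == 2^h_ceil(n)) {
      rep_b <- if (domain == "binary") rep else enumerate_extremes(kind, f, n, "binary")
      fb_key <- canonical_key(fb_tree(h_ceil(n)))
      if (!identical(rep_b$min_keys, fb_key)) {
        return(list(pass = FALSE, failure = list(
          n = n, condition = "fb_unique_min",
          witnesses = setdiff(rep_b$min_keys, fb_key))))
      }
    }
  }
  list(pass = TRUE, failure = NULL)
}

#' Check locality by random subtree replacement
#'
#' A tree shape statistic `t` is local if replacing a pending subtree
#' changes the statistic by exactly the difference of the subtree values:
#' `t(T) - t(T') = t(T_v) - t(T'_v)`. This performs random replacements
#' (random tree, random inner vertex, random replacement shape with the
#' same leaf count) and tests the identity to `1e-9` relative tolerance.
#' The balance value and clade size functionals are local for every `f`;
#' the leaf depth functional is local exactly for affine `f`.
#'
#' @inheritParams phi
#' @param trials Number of random replacements.
#' @param seed Optional seed for reproducibility (restores the RNG state on
#'   exit).
#' @param n_range Leaf-count range for the random host trees.
#' @return A list with `local` (logical) and, on failure, a `witness` list
#'   with the host, vertex, replacement, and the two sides of the identity.
#' @export
check_locality <- function(kind, f, trials = 100, seed = NULL,
                           n_range = c(4L, 12L)) {
  kind <- norm_kind(kind)
  f <- as_shape_fun(f)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  rand_shape <- function(n) {
    if (kind == "B") random_binary_shape(n) else random_tree_shape(n)
  }
  for (trial in seq_len(trials)) {
    n <- sample(seq(n_range[1], n_range[2]), 1L)
    host <- rand_shape(n)
    vt <- vertex_table(host)
    inner <- vt$vertex[!vt$is_leaf & vt$clade_size < n]
    if (length(inner) == 0L) next
    v <- if (length(inner) == 1L) inner else sample(inner, 1L)
    old_sub <- subtree_at(host, v)
    new_sub <- rand_shape(attr(old_sub, "n"))
    host2 <- replace_subtree(host, v, new_sub)
    lhs <- phi(host, kind, f) - phi(host2, kind, f)
    rhs <- phi(old_sub, kind, f) - phi(new_sub, kind, f)
    if (abs(lhs - rhs) > 1e-9 * max(1, abs(lhs), abs(rhs))) {
      return(list(local = FALSE, witness = list(
        host = write_newick(host), vertex = v,
        replacement = write_newick(new_sub),
        tree_difference = lhs, subtree_difference = rhs)))
    }
  }
  list(local = TRUE, witness = NULL)
}

#' Entrywise dominance of two shape sequences
#'
#' Compares two equal-length sequences of the same kind entrywise. If one
#' sequence is entrywise no larger than the other, every increasing `f`
#' orders the corresponding functional values the same way (strictly if
#' some entry is strictly smaller and `f` strictly increasing).
#'
#' @param a,b `shape_seq` objects of equal length and kind.
#' @return One of `"a_dominates"`, `"b_dominates"`, `"equal"`,
#'   `"incomparable"`, with attribute `strict` for the dominating cases.
#' @export
dominance <- function(a, b) {
  if (!inherits(a, "shape_seq") || !inherits(b, "shape_seq")) {
    rlang::abort("dominance expects two shape_seq objects")
  }
  if (attr(a, "kind") != attr(b, "kind")) {
    rlang::abort("sequences have different kinds")
  }
  if (length(a) != length(b)) {
    rlang::abort("sequences have different lengths")
  }
  av <- unclass(a); bv <- unclass(b)
  if (all(av == bv)) return(structure("equal", strict = FALSE))
  if (all(av <= bv)) return(structure("a_dominates", strict = any(av < bv)))
  if (all(bv <= av)) return(structure("b_dominates", strict = any(bv < av)))
  structure("incomparable", strict = FALSE)
}

# ---- recommendation logic ---------------------------------------------------

# One row per leaf of the decision logic: which (sequence, f-condition)
# pairs yield a valid imbalance index on each domain, which binary
# minimizer they deliver, and equivalence notes.
recommendation_rules <- function() {
  tibble::tribble(
    ~sequence, ~domain, ~condition, ~valid, ~minimizer, ~equivalence, ~note,
    "B", "binary", "f strictly increasing", TRUE, "depends",
      NA_character_, "valid index for every strictly increasing f; minimizer depends on f - use enumeration",
    "B", "binary", "f strictly increasing and convex", TRUE, "mb",
      NA_character_, "mb minimizes; uniquely if f(2)-f(1) > f(1)-f(0) (locally strictly convex)",
    "B", "binary", "f strictly increasing and strictly concave", TRUE, "depends",
      NA_character_, "valid index; minimizer depends on f - use enumeration",
    "B", "binary", "f strictly increasing and affine (m > 0)", TRUE, "argmin_C",
      "Colless", "equivalent to the Colless index",
    "N", "binary", "f strictly increasing", FALSE, NA_character_,
      NA_character_, "not an imbalance index for all such f (piecewise counterexample beats the fb-tree)",
    "N", "binary", "f strictly increasing and strictly concave", TRUE, "gfb",
      NA_character_, "gfb-tree is the unique minimizer",
    "N", "binary", "f strictly increasing and strictly convex", TRUE, "mb",
      NA_character_, "mb-tree is the unique minimizer",
    "N", "binary", "f strictly increasing and affine (m > 0)", TRUE, "argmin_S",
      "Sackin", "equivalent to the Sackin index on binary trees",
    "N", "arbitrary", "f strictly increasing", FALSE, NA_character_,
      NA_character_, "not an imbalance index for all such f",
    "N", "arbitrary", "f strictly increasing, strictly concave and 2-positive", TRUE, "gfb",
      NA_character_, "star tree minimizes on the arbitrary domain; gfb on binary trees",
    "N", "arbitrary", "f strictly increasing, strictly convex and 2-positive", TRUE, "mb",
      NA_character_, "star tree minimizes on the arbitrary domain; mb on binary trees",
    "N", "arbitrary", "f strictly increasing and affine with a >= 0", TRUE, "argmin_S",
      "Sackin if a = 0", "a = 0 makes it equivalent to the Sackin index on arbitrary trees",
    "D", "binary", "f strictly increasing", FALSE, NA_character_,
      NA_character_, "not an imbalance index for all such f (concave counterexample beats the fb-tree)",
    "D", "binary", "f strictly increasing and convex", TRUE, "argmin_S",
      NA_character_, "minimizers coincide with the Sackin-minimal trees",
    "D", "binary", "f strictly increasing and strictly concave", FALSE, NA_character_,
      NA_character_, "minimizer depends on f; not an imbalance index in general",
    "D", "binary", "f strictly increasing and affine (m > 0)", TRUE, "argmin_S",
      "Sackin", "equivalent to the Sackin index",
    "D", "arbitrary", "f strictly increasing and convex", TRUE, "argmin_S",
      NA_character_, "star tree minimizes on the arbitrary domain",
    "D", "arbitrary", "f strictly increasing and affine (m > 0)", TRUE, "argmin_S",
      "Sackin", "equivalent to the Sackin index on arbitrary trees"
  )
}

#' Recommend shape-function families for a requested index
#'
#' Given a domain (binary or arbitrary trees), and optionally a desired
#' binary minimizer target (`"mb"`, `"gfb"`, `"argmin_S"`, `"argmin_C"`)
#' and/or a sequence kind, returns all (sequence, f-condition) pairs that
#' yield a valid imbalance index matching the request, with equivalence
#' annotations. An empty result (with a message) means the combination is
#' impossible; e.g. no balance value functional has the gfb-tree as its
#' guaranteed unique minimizer.
#'
#' @param domain `"binary"` or `"arbitrary"`.
#' @param minimizer Optional target among `"mb"`, `"gfb"`, `"argmin_S"`,
#'   `"argmin_C"`.
#' @param sequence Optional sequence kind (`"B"`, `"N"`, `"D"`).
#' @return A tibble with columns `sequence`, `domain`, `condition`,
#'   `minimizer`, `equivalence`, `note`.
#' @export
#' @examples
#' recommend("binary", minimizer = "gfb")
recommend <- function(domain = c("binary", "arbitrary"), minimizer = NULL,
                      sequence = NULL) {
  domain <- match.arg(domain)
  rules <- recommendation_rules()
  out <- dplyr::filter(rules, .data$domain == !!domain, .data$valid)
  if (!is.null(sequence)) {
    sequence <- norm_kind(sequence)
    out <- dplyr::filter(out, .data$sequence == !!sequence)
  }
  if (!is.null(minimizer)) {
    minimizer <- match.arg(minimizer, c("mb", "gfb", "argmin_S", "argmin_C"))
    out <- dplyr::filter(out, .data$minimizer == !!minimizer)
  }
  out <- dplyr::select(out, -"valid")
  if (nrow(out) == 0L) {
    rlang::inform("no function family delivers this combination; see recommendation_rules() for the full table")
  }
  out
}
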