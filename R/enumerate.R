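# Exhaustive enumeration of rooted tree shapes up to isomorphism, used as
# the brute-force oracle behind all extremal-tree and coincidence searches.
# Shapes are built bottom-up from unordered pairs/multisets of smaller
# shapes, so each isomorphism class is constructed exactly once; results are
# memoized for the session.

.shape_cache <- new.env(parent = emptyenv())

#' Enumerate rooted binary tree shapes
#'
#' Returns one representative per isomorphism class of rooted binary trees
#' with `n` leaves. The counts follow the Wedderburn-Etherington numbers
#' (1, 1, 1, 2, 3, 6, 11, 23, 46, 98, 207, 451, 983, ...).
#'
#' @param n Number of leaves (`>= 1`); enumeration is practical up to about
#'   `n = 15`.
#' @return A list of `tree_shape` objects.
#' @export
#' @examples
#' length(enumerate_binary_shapes(5)) # 3
enumerate_binary_shapes <- function(n) {
  n <- check_size(n)
  key <- paste0("bin", n)
  if (!is.null(.shape_cache[[key]])) return(.shape_cache[[key]])
  if (n == 1L) {
    out <- list(new_leaf())
  } else {
    out <- list()
    for (i in seq_len(n %/% 2)) {
      left <- enumerate_binary_shapes(i)
      right <- enumerate_binary_shapes(n - i)
      if (i < n - i) {
        for (a in left) for (b in right) out[[length(out) + 1L]] <- new_node(list(a, b))
      } else {
        for (j in seq_along(left)) {
          for (k in j:length(left)) {
            out[[length(out) + 1L]] <- new_node(list(left[[j]], left[[k]]))
          }
        }
      }
    }
  }
  .shape_cache[[key]] <- out
  out
}

#' Enumerate arbitrary rooted tree shapes
#'
#' Returns one representative per isomorphism class of rooted trees with `n`
#' leaves and no out-degree-one vertices (counts 1, 1, 2, 5, 12, 33, 90,
#' 261, ...).
#'
#' @param n Number of leaves (`>= 1`); practical up to about `n = 10`.
#' @return A list of `tree_shape` objects.
#' @export
#' @examples
#' length(enumerate_arbitrary_shapes(4)) # 5
enumerate_arbitrary_shapes <- function(n) {
  n <- check_size(n)
  key <- paste0("arb", n)
  if (!is.null(.shape_cache[[key]])) return(.shape_cache[[key]])
  if (n == 1L) {
    out <- list(new_leaf())
  } else {
    # candidate children: all smaller shapes, ordered by (size, key); a
    # root's children form a multiset, realised as a non-decreasing index
    # sequence over the candidates
    cand <- list()
    for (m in seq_len(n - 1L)) cand <- c(cand, enumerate_arbitrary_shapes(m))
    sizes <- vapply(cand, function(s) attr(s, "n"), integer(1))
    keys <- vapply(cand, function(s) attr(s, "key"), character(1))
    ord <- order(sizes, keys, method = "radix")
    cand <- cand[ord]
    sizes <- sizes[ord]
    out <- list()
    pick <- function(min_idx, remaining, chosen) {
      if (remaining == 0L) {
        if (length(chosen) >= 2L) out[[length(out) + 1L]] <<- new_node(cand[chosen])
        return(invisible(NULL))
      }
      for (idx in seq(min_idx, length(cand))) {
        if (sizes[idx] > remaining) break
        pick(idx, remaining - sizes[idx], c(chosen, idx))
      }
    }
    pick(1L, n, integer(0))
  }
  .shape_cache[[key]] <- out
  out
}

#' Random tree shapes
#'
#' `random_binary_shape()` draws a rooted binary shape by recursive uniform
#' leaf-count splits; `random_tree_shape()` draws an arbitrary shape by
#' first choosing a root out-degree and then a random composition of the
#' leaves. These generators reach every shape with positive probability and
#' are used for the randomized locality and recursion checks.
#'
#' @param n Number of leaves (`>= 1`).
#' @return A `tree_shape`.
#' @export
random_binary_shape <- function(n) {
  n <- check_size(n)
  if (n == 1L) return(new_leaf())
  k <- sample.int(n - 1L, 1L)
  new_node(list(random_binary_shape(k), random_binary_shape(n - k)))
}

#' @rdname random_binary_shape
#' @export
random_tree_shape <- function(n) {
  n <- check_size(n)
  if (n == 1L) return(new_leaf())
  k <- sample.int(n - 1L, 1L) + 1L # out-degree between 2 and n
  # random composition of n into k positive parts
  cuts <- sort(sample.int(n - 1L, k - 1L))
  parts <- diff(c(0L, cuts, n))
  new_node(lapply(parts, random_tree_shape))
}

#' Enumerate shapes on a domain
#'
#' @param n Number of leaves.
#' @param domain `"binary"` or `"arbitrary"`.
#' @return A list of `tree_shape` objects.
#' @export
enumerate_shapes <- function(n, domain = c("binary", "arbitrary")) {
  domain <- match.arg(domain)
  if (domain == "binary") enumerate_binary_shapes(n) else enumerate_arbitrary_shapes(n)
}
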