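# Shared fixtures: the shape-function battery and the worked-example trees.

# battery of qualitatively different shape functions; each entry records
# the sequence kinds whose entries lie in its domain (B entries start at 0,
# D at 1 for n >= 2, N at 2)
fun_battery <- function() {
  list(
    identity = list(f = sf_identity(), kinds = c("B", "N", "D")),
    square = list(f = sf_power(2), kinds = c("B", "N", "D")),
    sqrt = list(f = sf_power(0.5), kinds = c("B", "N", "D")),
    affine31 = list(f = sf_affine(3, 1), kinds = c("B", "N", "D")),
    log_xm1 = list(f = sf_log(shift = -1), kinds = "N"),
    convex_ratio = list(f = sf_expr("x + 1/(x + 1)"), kinds = c("B", "N", "D"))
  )
}

# the Remark-3.3 example functions
ex_f1 <- function() sf_log(base = 2, scale = 0.5, shift = 1)
ex_f2 <- function() sf_log(base = 2, scale = 1.5, shift = 1)
ex_f3 <- function() sf_expr("ifelse(x <= 3, x, x + 2)")
ex_f4 <- function() sf_expr("x / (x + 0.5)")
ex_f5 <- function() sf_log(base = 2)

# join two shapes under a fresh root
join_shapes <- function(...) metabalance:::new_node(list(...))

# the 5-leaf tree (fb_2, fb_0) and the 8-leaf tree (gfb_5, gfb_3)
tree_T1 <- function() join_shapes(fb_tree(2), fb_tree(0))
tree_T2 <- function() join_shapes(gfb_tree(5), gfb_tree(3))

# remove each element of y once from x (multiset difference)
setdiff_multiset <- function(x, y) {
  for (v in y) {
    i <- match(v, x)
    if (!is.na(i)) x <- x[-i]
  }
  x
}

# independent total cophenetic oracle: sum over inner vertices v of
# depth(v) times the number of leaf pairs whose LCA is v
tci_by_lca <- function(tree) {
  s <- as_tree_shape(tree)
  total <- 0
  rec <- function(x, depth) {
    if (metabalance:::is_leaf(x)) return(invisible(NULL))
    kids_n <- vapply(x, function(ch) attr(ch, "n"), integer(1))
    pairs_here <- choose(attr(x, "n"), 2) - sum(choose(kids_n, 2))
    total <<- total + depth * pairs_here
    for (ch in x) rec(ch, depth + 1L)
  }
  rec(s, 0L)
  total
}
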