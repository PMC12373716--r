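test_that("worked example values of the three functionals reproduce", {
  f1 <- ex_f1(); f2 <- ex_f2(); f3 <- ex_f3(); f4 <- ex_f4(); f5 <- ex_f5()
  # balance value functional on the three 5-leaf binary shapes
  expect_equal(round(phi(gfb_tree(5), "B", f1), 2), 1.17)
  expect_equal(round(phi(tree_T1(), "B", f1), 2), 1.32)
  expect_equal(round(phi(cat_tree(5), "B", f1), 2), 2.91)
  expect_equal(round(phi(gfb_tree(5), "B", f2), 2), 2.64)
  expect_equal(round(phi(tree_T1(), "B", f2), 2), 2.46)
  expect_equal(round(phi(cat_tree(5), "B", f2), 2), 5.78)
  # clade size functional with the piecewise function
  expect_equal(phi(tree_T2(), "N", f3), 29)
  expect_equal(phi(fb_tree(3), "N", f3), 30)
  # leaf depth functional
  expect_equal(phi(fb_tree(2), "D", f4), 3.2)
  expect_equal(round(phi(cat_tree(4), "D", f4), 2), 3.18)
  expect_equal(phi(fb_tree(2), "D", f5), 4)
  expect_equal(round(phi(cat_tree(4), "D", f5), 2), 4.17)
})

test_that("empty sequences sum to zero and the leaf tree follows conventions", {
  leaf <- subtree_at(cat_tree(2), 2)
  f <- sf_affine(2, 0)
  expect_equal(phi(leaf, "B", f), 0)
  expect_equal(phi(leaf, "N", f), 0)
  expect_equal(phi(leaf, "D", f), f$fn(0))
  expect_error(phi(star_tree(3), "B", f), "binary")
  expect_error(phi(cat_tree(3), "D", sf_log(shift = -1)), "undefined")
})

test_that("classical indices equal the functional with the inducing f", {
  shapes <- c(enumerate_binary_shapes(7), enumerate_binary_shapes(8))
  for (s in shapes) {
    n <- n_leaves(s)
    expect_equal(sackin(s), phi(s, "N", sf_identity()))
    expect_equal(sackin(s), phi(s, "D", sf_identity()))
    expect_equal(avg_leaf_depth(s), phi(s, "D", sf_expr("x / n")))
    expect_equal(s_hat(s), phi(s, "N", sf_log(shift = -1)))
    expect_equal(colless(s), phi(s, "B", sf_identity()))
    expect_equal(quadratic_colless(s), phi(s, "B", sf_power(2)))
    expect_equal(corrected_colless(s),
                 phi(s, "B", sf_expr("2 * x / ((n - 1) * (n - 2))")))
    expect_equal(total_cophenetic(s), phi(s, "N", sf_total_cophenetic()))
  }
  # total cophenetic on arbitrary trees: clade-size form vs LCA oracle,
  # and the third-order functional
  for (s in enumerate_arbitrary_shapes(6)) {
    expect_equal(total_cophenetic(s), tci_by_lca(s))
    expect_equal(total_cophenetic(s), phi(s, "N", sf_total_cophenetic()))
  }
})

test_that("closed-form index values at special trees are right", {
  expect_equal(sackin(cat_tree(8)), 35)
  expect_equal(colless(cat_tree(5)), 6)
  expect_equal(colless(fb_tree(4)), 0)
  expect_equal(corrected_colless(cat_tree(4)), 1)
  expect_equal(corrected_colless(cat_tree(2)), 0) # n <= 2 convention
  expect_equal(total_cophenetic(cat_tree(4)), 4)
  for (n in c(3, 5, 9)) expect_equal(s_hat(star_tree(n)), log(n - 1))
  # s-hat base change only rescales: rankings are identical
  expect_true(equivalent_on(function(t) s_hat(t, base = exp(1)),
                            function(t) s_hat(t, base = 10), 7, "binary"))
})

test_that("a tree whose clade sizes are (2,3,4,6,8) has Sackin index 23", {
  leaf <- subtree_at(cat_tree(2), 2)
  s3 <- join_shapes(cat_tree(2), leaf)                 # clades 3, 2
  s4 <- join_shapes(s3, leaf)                          # clade 4
  s6 <- metabalance:::new_node(list(s4, leaf, leaf))   # clade 6
  s8 <- metabalance:::new_node(list(s6, leaf, leaf))   # clade 8
  expect_equal(as.integer(clade_size_sequence(s8)), c(2, 3, 4, 6, 8))
  expect_equal(sackin(s8), 23)
})

test_that("recursive evaluation agrees with direct evaluation", {
  set.seed(42)
  f_bat <- fun_battery()
  for (kind in c("B", "N", "D")) {
    fs <- if (kind == "D") list(sf_affine(2, 0), sf_identity())
          else Filter(function(e) kind %in% e$kinds, f_bat) |>
            lapply(function(e) e$f)
    for (i in 1:200) {
      n <- sample(2:12, 1)
      s <- if (kind == "B") random_binary_shape(n) else random_tree_shape(n)
      for (f in fs) {
        expect_equal(recursive_phi(s, kind, f), phi(s, kind, f),
                     tolerance = 1e-9)
      }
    }
  }
  expect_error(recursive_phi(cat_tree(4), "D", sf_power(2)), "affine")
  expect_error(recursive_phi(cat_tree(4), "D", sf_affine(2, 1)), "affine")
  # explicit small cases
  expect_equal(recursive_phi(fb_tree(3), "B", sf_affine(1, 5)), 7 * 5)
  expect_equal(recursive_phi(cat_tree(5), "N", sf_identity()), 14)
  expect_equal(recursive_phi(star_tree(4), "D", sf_affine(2, 0)), 8)
})

test_that("ranking equivalence matches the affine-transform theory", {
  expect_true(equivalent_on(colless, corrected_colless, 6, "binary"))
  expect_true(equivalent_on(sackin, avg_leaf_depth, 7, "binary"))
  expect_true(equivalent_on(sackin, sackin, 6, "binary"))
  # affine f with positive intercept: equivalent to Sackin on binary trees
  expect_true(equivalent_on(sackin, function(t) phi(t, "N", sf_affine(1, 2)),
                            7, "binary"))
  # ... but not on arbitrary trees, where the sequence length varies
  expect_false(equivalent_on(sackin, function(t) phi(t, "N", sf_affine(1, 2)),
                             8, "arbitrary"))
  # total cophenetic is equivalent to the first-order choose(x,2) functional
  expect_true(equivalent_on(total_cophenetic,
                            function(t) phi(t, "N", sf_expr("choose(x, 2)")),
                            7, "binary"))
})

test_that("entrywise sequence dominance forces the functional ordering", {
  f_bat <- fun_battery()
  for (n in 5:8) {
    shapes <- enumerate_binary_shapes(n)
    for (kind in c("B", "N", "D")) {
      seqs <- lapply(shapes, tree_sequence, kind = kind)
      vals <- lapply(f_bat, function(e) {
        if (!kind %in% e$kinds) return(NULL)
        vapply(shapes, phi, numeric(1), kind = kind, f = e$f)
      })
      vals <- Filter(Negate(is.null), vals)
      for (i in seq_along(shapes)) {
        for (j in seq_along(shapes)) {
          if (i == j) next
          if (dominance(seqs[[i]], seqs[[j]]) == "a_dominates") {
            for (v in vals) expect_lte(v[i], v[j] + 1e-12)
          }
        }
      }
    }
  }
})

test_that("phi_table evaluates many trees tidily", {
  out <- phi_table(enumerate_binary_shapes(5), "B", sf_identity())
  expect_s3_class(out, "tbl_df")
  expect_equal(nrow(out), 3L)
  expect_setequal(out$value, c(2, 3, 6))
  idx <- tree_indices(list(cat_tree(5), star_tree(5)))
  expect_equal(idx$sackin, c(14, 5))
  expect_true(is.na(idx$colless[2]))
})
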