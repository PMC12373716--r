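test_that("the closed-form Colless minimum matches brute force", {
  for (n in 1:12) {
    enumerated <- min(vapply(enumerate_binary_shapes(n), colless, numeric(1)))
    expect_equal(colless_min(n), enumerated)
  }
  # the mb- and gfb-trees attain it
  for (n in 2:20) {
    expect_equal(colless(mb_tree(n)), colless_min(n))
    expect_equal(colless(gfb_tree(n)), colless_min(n))
  }
  expect_equal(colless_min(8), 0)
  # c_n >= 2 whenever n >= 4 is not a power of two
  for (n in setdiff(4:40, 2^(2:5))) expect_gte(colless_min(n), 2)
})

test_that("Sackin extremes match their closed forms and attaining trees", {
  expect_equal(sackin_extremes(6)$min, 16)
  expect_equal(sackin_extremes(8)$min, 24)
  expect_equal(sackin_extremes(5)$max, 14)
  for (n in 1:12) {
    vals <- vapply(enumerate_binary_shapes(n), sackin, numeric(1))
    ext <- sackin_extremes(n)
    expect_equal(ext$min, min(vals))
    expect_equal(ext$max, max(vals))
  }
  for (n in 2:32) expect_equal(sackin(gfb_tree(n)), sackin_extremes(n)$min)
  for (n in 2:16) expect_equal(sackin(cat_tree(n)), sackin_extremes(n)$max)
})

test_that("gfb subtree counts: closed form equals the constructed tree", {
  for (n in 2:64) {
    sizes <- c(as.integer(clade_size_sequence(gfb_tree(n))), rep(1L, n))
    counted <- vapply(1:n, function(i) sum(sizes == i), integer(1))
    expect_equal(gfb_subtree_count(n, 1:n), counted)
  }
  expect_equal(gfb_subtree_count(6, 2), 3)
  expect_equal(gfb_subtree_count(5, 4), 0)
  expect_error(gfb_subtree_count(5, 6), "1 <= i <= n")
})

test_that("mb subtree counts come from the constructed tree", {
  expect_equal(mb_subtree_count(5, 2), 2)
  expect_equal(mb_subtree_count(8, 4), 2)
  for (n in 2:20) {
    expect_equal(mb_subtree_count(n, n), 1)
    expect_equal(mb_subtree_count(n, 1), n)
    # counts sum to the number of pending subtrees
    expect_equal(sum(mb_subtree_count(n, 1:n)),
                 n + length(clade_size_sequence(mb_tree(n))))
  }
  expect_equal(mb_r_param(12, 3), 12 - 8 * floor(12 / 8))
})

test_that("balance value functional extremes: closed form and attaining sets", {
  rep5 <- bvm_extremes(sf_identity(), 5)
  expect_equal(rep5$min_value, 2)
  expect_equal(rep5$max_value, 6)
  rep4 <- bvm_extremes(sf_power(2), 4)
  expect_equal(rep4$min_value, 0)
  expect_equal(rep4$max_value, 5)
  expect_identical(rep4$min_keys, canonical_key(fb_tree(2)))
  # min is (n-1) f(0) at powers of two for any increasing f
  f <- sf_expr("sqrt(x) + 2")
  rep8 <- bvm_extremes(f, 8)
  expect_equal(rep8$min_value, 7 * 2)
  expect_warning(bvm_extremes(sf_affine(-1, 0), 5), "not increasing")
})

test_that("clade size functional extremes per function family", {
  # piecewise f3 at n = 8: the fb-tree is not the minimizer
  rep <- enumerate_extremes("N", ex_f3(), 8, "binary")
  expect_equal(rep$min_value, 29)
  expect_false(canonical_key(fb_tree(3)) %in% rep$min_keys)
  expect_true(canonical_key(tree_T2()) %in% rep$min_keys)
  # strictly concave 2-positive: gfb unique minimizer, value by subtree counts
  repc <- csm_extremes(sf_power(0.5), 6, "binary")
  expect_equal(repc$min_value, sum(gfb_subtree_count(6, 2:6) * sqrt(2:6)))
  orac <- enumerate_extremes("N", sf_power(0.5), 6, "binary")
  expect_equal(orac$min_value, repc$min_value)
  expect_identical(orac$min_keys, canonical_key(gfb_tree(6)))
  # arbitrary domain: star minimum f(n)
  repa <- csm_extremes(sf_identity(), 6, "arbitrary")
  expect_equal(repa$min_value, 6)
  expect_identical(repa$min_keys, canonical_key(star_tree(6)))
  oraca <- enumerate_extremes("N", sf_identity(), 6, "arbitrary")
  expect_equal(oraca$min_value, 6)
  expect_identical(oraca$min_keys, canonical_key(star_tree(6)))
})

test_that("leaf depth functional extremes per function family", {
  rep <- ldm_extremes(sf_identity(), 6, "binary")
  expect_equal(rep$min_value, 16) # equals the Sackin minimum
  expect_equal(rep$max_value, 20) # f(5) + sum_{1..5} f(i)
  expect_equal(rep$max_value, sackin(cat_tree(6)))
  # arbitrary domain: n * f(1) at the star
  repa <- ldm_extremes(sf_power(0.5), 7, "arbitrary")
  expect_equal(repa$min_value, 7)
  expect_identical(repa$min_keys, canonical_key(star_tree(7)))
  # convex binary minimum: (2^(h-1) - p) f(h-1) + 2 p f(h)
  repc <- ldm_extremes(sf_power(2), 6, "binary")
  expect_equal(repc$min_value, (4 - 2) * 4 + 2 * 2 * 9)
  expect_equal(repc$min_value,
               enumerate_extremes("D", sf_power(2), 6, "binary")$min_value)
})

test_that("enumerated extremal sets at n = 12 match the Sackin/Colless picture", {
  repS <- enumerate_extremes("N", sf_identity(), 12, "binary")
  repC <- enumerate_extremes("B", sf_identity(), 12, "binary")
  expect_equal(length(repS$min_keys), 5L)
  expect_equal(length(repC$min_keys), 4L)
  expect_true(all(repC$min_keys %in% repS$min_keys))
  expect_true(canonical_key(gfb_tree(12)) %in% repC$min_keys)
  expect_true(canonical_key(mb_tree(12)) %in% repC$min_keys)
  # the constructive argmin sets coincide with the enumerated ones
  expect_setequal(vapply(argmin_sackin_set(12), canonical_key, character(1)),
                  repS$min_keys)
  expect_setequal(vapply(argmin_colless_set(12), canonical_key, character(1)),
                  repC$min_keys)
  # quadratic Colless at a power of two: fb uniquely attains 0
  repQ <- enumerate_extremes("B", sf_power(2), 8, "binary")
  expect_identical(repQ$min_keys, canonical_key(fb_tree(3)))
  expect_equal(repQ$min_value, 0)
})

test_that("subtrees of minimizing trees minimize at their own size", {
  for (n in c(6, 11, 12)) {
    for (idx in c("S", "C")) {
      kind <- if (idx == "S") "N" else "B"
      rep <- enumerate_extremes(kind, sf_identity(), n, "binary")
      mins <- Filter(function(s) canonical_key(s) %in% rep$min_keys,
                     enumerate_binary_shapes(n))
      for (s in mins) {
        vt <- vertex_table(s)
        for (v in vt$vertex[!vt$is_leaf]) {
          sub <- subtree_at(s, v)
          m <- n_leaves(sub)
          target <- if (idx == "S") sackin_extremes(m)$min else colless_min(m)
          val <- if (idx == "S") sackin(sub) else colless(sub)
          expect_equal(val, target)
        }
      }
    }
  }
})

test_that("minimal sequence coincidences are found at the right leaf counts", {
  expect_equal(minimal_sequence_coincidence("B_different", "D_equal", 8), 6)
  expect_equal(minimal_sequence_coincidence("N_different", "D_equal", 8), 6)
  expect_equal(minimal_sequence_coincidence("B_equal", "N_equal", 10), 9)
  expect_equal(minimal_sequence_coincidence("B_equal", "D_different", 10), 9)
})

test_that("extremal reports tidy into tibbles", {
  rep <- enumerate_extremes("B", sf_identity(), 6, "binary")
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("which", "value", "tree") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$min_value, colless_min(6))
  expect_equal(gl$method, "enumeration")
})
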