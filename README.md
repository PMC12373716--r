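# metabalance

Tree balance — how evenly a rooted phylogeny splits its leaves — is
usually measured one index at a time: Sackin, Colless, total cophenetic,
and so on. `metabalance` works at the level of *families* of indices. A
tree shape `T` is summarised by one of three ascending integer sequences:

* `B(T)` — the balance values `|n₁ − n₂|` of its inner vertices (binary
  trees),
* `N(T)` — the clade sizes of its inner vertices,
* `D(T)` — the depths of its leaves,

and a whole family of (im)balance indices arises by summing a shape
function `f` over one of them:

```
Φ_f(T) = Σ_{s ∈ Seq(T)} f(s)
```

Choosing `f(x) = x` on `N` or `D` gives the Sackin index; on `B`, the
Colless index; `f(x) = x²` the quadratic Colless index;
`f(x) = log(x−1)` on `N` the s-hat statistic; higher-order variants with
access to the leaf count give the corrected Colless index, the average
leaf depth, and the total cophenetic index. The payoff of the general
view: theorems about *which* `f` make `Φ_f` a valid imbalance index
(uniquely maximized by the caterpillar, uniquely minimized at `n = 2^h`
by the fully balanced tree), and *which tree* minimizes it — the
maximally balanced tree for strictly convex increasing `f`, the
greedy-from-the-bottom tree for strictly concave increasing `f` on clade
sizes, the Sackin- or Colless-minimal trees for affine `f`, the star
tree on arbitrary (multifurcating) trees.

The package provides, for users of rooted trees in phylogenetics and
beyond:

* shape-only tree handling with Newick I/O (via `ape`), canonical
  isomorphism keys, and constructors for the caterpillar, fully
  balanced, maximally balanced, greedy-from-the-bottom, and star trees;
* exhaustive enumeration of binary and arbitrary rooted shapes up to
  isomorphism (Wedderburn–Etherington counts), used as a brute-force
  oracle;
* `phi()` / `recursive_phi()` evaluation of the functionals, the seven
  classical indices, and ranking-equivalence tests;
* closed-form extremal values (`bvm_extremes()`, `csm_extremes()`,
  `ldm_extremes()`, `colless_min()`, `sackin_extremes()`,
  `gfb_subtree_count()`) with enumeration cross-checks
  (`enumerate_extremes()`);
* certification of shape-function properties (`classify_function()`),
  empirical locality and imbalance-index verification, and a
  recommendation table (`recommend()`) mapping a desired minimizer to
  the function families that deliver it;
* a thin command line (`inst/cli/metabalance.R`) over the same
  functions.

## A worked example

Which binary 6-leaf tree minimizes the clade size functional for the
strictly concave `f(x) = √x`, and does the closed form agree with brute
force?

```r
library(metabalance)

f <- sf_power(0.5)
glance(csm_extremes(f, 6, "binary"))        # closed form
#>   kind  f         n domain method      min_value max_value n_minimizers n_maximizers
#> 1 N     x^0.5     6 binary closed_form      8.69      9.83            1            1
glance(enumerate_extremes("N", f, 6, "binary"))  # brute force over all 6 shapes
#>   kind  f         n domain method      min_value max_value n_minimizers n_maximizers
#> 1 N     x^0.5     6 binary enumeration      8.69      9.83            1            1
```

Both routes give minimum 8.69 (attained by one shape — the
greedy-from-the-bottom tree) and maximum 9.83 (the caterpillar). The
recommendation table states the general rule:

```r
recommend("binary", minimizer = "gfb")
#>   sequence domain condition                                   minimizer
#> 1 N        binary f strictly increasing and strictly concave gfb
```

Classical indices for a few shapes:

```r
tree_indices(list(cat_tree(6), gfb_tree(6), star_tree(6)))[, 1:7]
#>   tree                       n sackin avg_leaf_depth s_hat total_cophenetic colless
#> 1 (((((L,L),L),L),L),L);     6     20           3.33  4.79               20      10
#> 2 (((L,L),(L,L)),(L,L));     6     16           2.67  2.71                9       2
#> 3 (L,L,L,L,L,L);             6      6           1     1.61                0      NA
```

The caterpillar's Sackin index 20 is the maximum `n(n+1)/2 − 1` at
`n = 6`; the gfb-tree's 16 is the minimum `−2^h + n(h+1)` with `h = 3`;
the star tree has no Colless index (it is not binary).

## Vignette

`vignettes/metaconcepts.Rmd` describes the model and its assumptions,
the tree families and tie-breaking conventions, the enumeration bounds,
the finite-difference function certification, and known limitations.
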