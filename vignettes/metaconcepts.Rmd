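---
title: "Sequence functionals for rooted tree balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence functionals for rooted tree balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabalance)
```

## The model

A rooted tree here is a shape: a directed tree with one root, no vertex of
out-degree one, and unlabelled leaves — two trees are the same object when
they are isomorphic as unordered rooted trees. Three ascending integer
sequences summarise such a shape:

* the **balance value sequence** `B(T)`: for each inner vertex of a binary
  tree, the absolute difference of its two child clade sizes (length
  `n - 1`);
* the **clade size sequence** `N(T)`: the number of leaves below each
  inner vertex (length between 1, the star tree, and `n - 1`, binary
  trees);
* the **leaf depth sequence** `D(T)`: the root-to-leaf edge counts
  (always length `n`).

A *shape function* `f` maps non-negative integers to reals, and a
*sequence functional* sums it over one of the sequences:

```
Phi_f(T) = sum over s in Seq(T) of f(s).
```

Higher-order functionals additionally pass the leaf count `n` and the
number of inner vertices to `f`, which is how normalized indices such as
the corrected Colless index, the average leaf depth, and the total
cophenetic index arise. Setting `f` to the identity on the clade size or
leaf depth sequence gives the Sackin index; on the balance value sequence,
the Colless index; `f(x) = x^2` gives the quadratic Colless index;
`f(x) = log(x - 1)` on clade sizes gives the s-hat statistic. One family
of functions therefore analyses many indices at once: an imbalance index
must be uniquely maximized by the caterpillar and, at leaf counts `2^h`,
uniquely minimized on binary trees by the fully balanced tree.

```{r}
phi(cat_tree(6), "N", sf_identity())   # Sackin index of the caterpillar
phi(fb_tree(3), "B", sf_power(2))      # quadratic Colless of fb_3: 0
```

## Special trees and their roles

Five constructors cover the extremal landscape (`make_tree()` or the
individual `cat_tree()`, `fb_tree()`, `mb_tree()`, `gfb_tree()`,
`star_tree()`):

* the **caterpillar** (one cherry) maximizes every functional considered
  here whenever `f` is strictly increasing (plus 2-positivity for clade
  sizes on arbitrary trees, and convexity for leaf depths);
* the **fully balanced tree** of height `h` is the unique binary minimum
  at `n = 2^h`;
* the **maximally balanced tree** (every vertex balanced; built by the
  ceiling/floor split, with the larger part placed first — the choice is
  irrelevant up to isomorphism and fixed for determinism) is the unique
  minimizer for strictly convex increasing `f` on both the balance value
  and clade size functionals;
* the **greedy-from-the-bottom tree** is the unique clade size minimizer
  for strictly concave increasing `f`. It is built by repeatedly joining
  the two trees of minimal leaf count; when several trees tie, the two
  with lexicographically smallest canonical keys are joined. The result
  is unique up to isomorphism, and the package cross-checks it against the
  independent construction that attaches `n - 2^(h-1)` cherries to the
  leftmost leaves of the fully balanced tree of height `h - 1`;
* the **star tree** minimizes on the arbitrary-tree domain (for
  2-positive `f` on clade sizes, any increasing `f` on leaf depths).

For affine `f` the functionals collapse onto the classics: the balance
value functional is then equivalent to the Colless index and its
minimizers are the Colless-minimal trees (`argmin_colless_set()`); the
clade size and leaf depth functionals are equivalent to the Sackin index
and share its minimizers (`argmin_sackin_set()`, constructed as all
inequivalent cherry attachments to the fully balanced tree, deduplicated
by canonical key). Throughout, `h_n = ceiling(log2 n)` is the height of
those minimal trees; this reading makes the closed forms for the Colless
minimum `c_n`, the Sackin minimum, and the gfb subtree counts internally
consistent, and every one of them is validated against brute-force
enumeration in the test suite.

```{r}
colless_min(11)
glance(csm_extremes(sf_power(0.5), 6, "binary"))
```

## Enumeration as the oracle

`enumerate_binary_shapes()` and `enumerate_arbitrary_shapes()` build one
representative per isomorphism class bottom-up from unordered pairs or
multisets of smaller shapes, so duplicates are impossible by construction;
binary counts follow the Wedderburn–Etherington numbers. Canonical keys
(recursively sorted child encodings) make membership and set comparisons
plain string operations. Every closed-form extreme, every uniqueness
claim, and the minimal sequence-coincidence table are re-derived against
this oracle. The test suite enumerates binary shapes to `n = 13`
(983 shapes) for the coincidence searches and to `n = 12` (451 shapes)
for the extremal-set checks, and arbitrary shapes to `n = 8` (261
shapes); these sizes keep the whole suite under a minute while the
searched properties are already decided well below the bounds.

Worth knowing: no single sequence determines the shape. The smallest
binary examples — two distinct shapes with equal balance value and clade
size sequences at `n = 9`, differing balance but equal depth sequences at
`n = 6`, equal balance but differing clade size sequences only at
`n = 13` — are re-found by `minimal_sequence_coincidence()`, which groups
enumerated shapes on their sequence strings rather than comparing all
pairs.

## Certifying shape functions

`classify_function()` certifies monotonicity, convexity/concavity,
affinity (recovering slope and intercept), 2-positivity, and
non-negativity by exact finite differences on the integer grid from the
function's domain start up to a bound (default 256). Functionals only
ever evaluate `f` at integers bounded by the leaf count, so a grid
certificate is exact for every use below its bound; no symbolic analysis
is attempted. Strictness uses tolerance 0 when the scanned values are
integers and `1e-12` relative otherwise. Custom functions can be supplied
as expression strings (`sf_expr("x + 1/(x + 1)")`) parsed against a fixed
operator whitelist, so a command line can accept `f` without arbitrary
code execution.

```{r}
tidy(classify_function(sf_log(shift = -1)))[, 1:7]
```

`recommend()` inverts the theory: given the domain, the desired binary
minimizer (`mb`, `gfb`, `argmin_S`, `argmin_C`), and/or the sequence
kind, it lists the function conditions that deliver a valid imbalance
index, with equivalence notes. Combinations the theory cannot deliver
(e.g. the gfb-tree as guaranteed unique minimizer of a balance value
functional) return an empty table with a message; for families whose
minimizer genuinely depends on `f` (e.g. strictly concave `f` on balance
values) the table says so rather than guessing, and `enumerate_extremes()`
is the way to settle a concrete case.

## Locality and recursiveness, checked empirically

The balance value and clade size functionals are local for every `f`:
replacing a pending subtree changes the value by exactly the difference
of the subtree values. The leaf depth functional is local exactly for
affine `f`. `check_locality()` verifies the identity on randomly drawn
host trees, vertices, and replacement shapes (fixed seeds make runs
reproducible; a failing trial returns the concrete witness).
`recursive_phi()` evaluates the functionals through their
standard-decomposition recursions and must agree with the direct sums to
`1e-9` relative tolerance — an appropriate bar for sums of at most `n`
well-scaled terms.

The random generators draw shapes by uniform recursive splits
(`random_binary_shape()`) or random root degree plus a random composition
(`random_tree_shape()`). They reach every shape with positive probability
but are not uniform over isomorphism classes and emulate no evolutionary
model (no Yule or uniform prior); they are a test substrate for
identities that must hold on *every* tree, not a simulator of realistic
phylogenies. Passing locality and recursion checks therefore says nothing
about the distribution of index values on real data — those guarantees
come from the exhaustive enumerations instead.

## Degenerate inputs and conventions

The single-vertex tree has empty balance value and clade size sequences
(functionals evaluate to 0, the empty sum) and leaf depth sequence `(0)`,
which makes the leaf depth recursion start at `f(0) = 0` for zero-
intercept affine `f`. The corrected Colless index is 0 for `n <= 2` by
convention rather than leaving `0/0` to the normalizer. Newick input may
contain out-degree-one vertices; they are collapsed with a warning since
the tree model forbids them. The s-hat logarithm base defaults to the
natural log and is configurable — any base yields an equivalent index,
which the tests confirm by a ranking comparison.

## Limitations

Unrooted trees, networks, and branch-length-aware statistics are out of
scope; only shapes are compared. Closed-form minima are reported `NA`
when no proved formula covers the certified family of `f` (enumeration
still works). The subtree counts of the maximally balanced tree are
obtained by counting on the constructed tree — authoritative for every
`n` used here — rather than from a closed form. Enumeration is
exponential: beyond roughly `n = 15` (binary) or `n = 10` (arbitrary)
the oracle is out of reach, and only the closed forms and constructions
remain.
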