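Package: metabalance
Title: Metaconcepts of Rooted Tree Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying rooted tree balance through sequence
    functionals. A tree's balance value, clade size, or leaf depth sequence
    is summarised by summing a user-chosen shape function f over its
    entries, which yields whole families of (im)balance indices at once,
    including the Sackin, Colless, quadratic and corrected Colless, total
    cophenetic, average leaf depth, and s-hat statistics. The package
    constructs the extremal tree families (caterpillar, fully balanced,
    maximally balanced, greedy-from-the-bottom, star), enumerates rooted
    binary and arbitrary tree shapes up to isomorphism, evaluates
    closed-form extremal values and compares them against brute-force
    enumeration, certifies properties of shape functions (monotonicity,
    convexity, 2-positivity), checks locality and recursiveness
    empirically, and recommends which function families yield valid
    imbalance indices for a requested minimizer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
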