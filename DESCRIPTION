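Package: rnaunrank
Title: Non-Uniform Random Generation of RNA Secondary Structures by
    Weighted Unranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates pseudoknot-free RNA secondary structures of a fixed
    size at random, distributed according to a stochastic context-free
    grammar trained on a database of real structures. The trained grammar is
    transformed into reweighting normal form, its rational rule weights are
    converted to exact integers, the integer-weighted grammar is translated
    into an admissible specification of weighted combinatorial classes, and
    structures are drawn by exact big-integer weighted unranking (sequential
    or boustrophedon order). Includes dot-bracket parsing and validation,
    brute-force language enumeration oracles, relative-frequency training
    with stability analysis, and motif statistics (hairpins, stacks, bulges,
    interior loops, multiloops, helices).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
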