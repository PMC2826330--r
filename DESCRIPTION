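Package: majplus
Title: Majority-Rule (+) Supertrees by Exact Integer Linear Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Constructs majority-rule (+) supertrees from profiles of
    partially-overlapping phylogenetic trees. Input trees are encoded as an
    MRP-style 0/1/? matrix; the unknown entries are filled in by an exact
    integer linear program whose optimum is a restricted representative
    selection of minimum adjusted Robinson-Foulds score. A feasibility-based
    verification loop then determines the strict consensus of all optimal
    candidate supertrees, Maj+(P). For larger inputs a reducible-set data
    reduction heuristic decomposes the profile into a reduced problem and
    satellite problems that are solved independently and recombined.
    Includes a polynomial-time majority-rule (+) consensus for equal leaf
    sets, split support/conflict reporting, a synthetic-profile generator,
    and a brute-force oracle for small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
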