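Package: unicovex
Title: Discovery of Cancer Driver Gene Modules with Balanced Exclusive Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate cancer driver gene modules that are highly
    covered, mutually exclusive and balanced in their exclusive coverage.
    Candidate modules are grown greedily inside local neighborhoods of a
    degree-reduced gene influence network, scored with a composite of minimum
    coverage, exclusive score and exclusive entropy (a Shannon-entropy measure
    of how evenly the exclusively mutated samples are spread across module
    genes), and selected per module size until every coverable sample is
    covered. Sample-specific driver modules are then called by greedy minimum
    set cover within each module-size group, with consensus calling across
    several interaction networks. Includes an influence-network builder
    (insulated heat diffusion on a protein-protein interaction graph), a
    planted-module cohort simulator for validation, and precision/recall,
    PR-curve and ROC-curve evaluation against a reference cancer-gene list.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
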