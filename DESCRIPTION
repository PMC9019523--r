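Package: pdaccum
Title: Accumulation of Known Phylogenetic Diversity over the History of
    Species Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking how known phylogenetic diversity (PD, the
    sum of branch lengths on a phylogenetic tree) has accumulated over the
    historical sequence of species descriptions.  Includes supertree
    assembly by clade extraction, branch-length rescaling and grafting
    (with repair of non-monophyletic groups and taxonomy reconciliation),
    computation of each species's marginal PD contribution at the time of
    its description under randomized within-year removal orders,
    counterfactual discovery orders (full randomization and reversal),
    log-linear trend estimation of the decline in per-species PD
    contributions, per-order accumulation summaries, and a synthetic-data
    generator so the whole pipeline can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
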