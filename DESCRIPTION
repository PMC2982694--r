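Package: cocktailnet
Title: Network-Based Identification of Effective Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the transcriptional response to a combination drug
    from the expression profiles of its member drugs, extracts the
    subnetwork of a background molecular interaction network affected by
    each treatment with a dummy-rooted network-flow program solved by
    linear-programming relaxation (GLPK), and scores every treatment for
    efficacy against side-effect liability to flag combinations that
    outperform each of their members.  Ships a synthetic-data generator
    that emulates probe-level perturbation microarrays, interaction edge
    lists and curated gene sets at desk scale, so the whole pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
SystemRequirements: GLPK stand-alone solver (glpsol) on the PATH
Config/testthat/edition: 3
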