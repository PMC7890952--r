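Package: cernanet
Title: Construction and Analysis of Competing Endogenous RNA Networks
Version: 0.1.0
Authors@R: person("CeNet", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds competing endogenous RNA (ceRNA) networks from expression
    profiles and miRNA-target interaction tables, and analyses them. Provides
    delimited-text readers with symbol harmonization, quality filtering of
    samples and genes, expression transforms, five ceRNA pair measures
    (shared-miRNA hypergeometric enrichment, Pearson correlation, mutual
    information, conditional mutual information, and liquid association with
    Van der Waerden scores), thresholded network assembly with topology and
    Louvain module reports, local hypergeometric over-representation analysis,
    Kaplan-Meier and Cox survival analysis for module biomarkers, and a
    deterministic synthetic-data generator with planted ceRNA triads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    parallel,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
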