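Package: comparex
Title: Comparative Analysis of Gene Co-Expression Networks Across Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gene co-expression and transcription-factor regulation
    networks from expression compendia using a B-spline mutual-information
    estimator with context-likelihood-of-relatedness (CLR) background
    correction, and compares the resulting networks across species through
    ortholog maps. Provides degree-distribution fitting (power law versus
    Poisson), gene centralities, Gene Ontology subnetwork statistics, typed
    network-motif enumeration and enrichment against degree-preserving
    randomized networks, link- and network-neighbourhood conservation tests
    (hypergeometric, FDR-controlled), multi-ortholog and
    sequence-versus-regulation divergence summaries, and a synthetic
    multi-species data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    splines,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
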