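Package: connevo
Title: Merging-Trajectory Connectomics Linked to Transcriptome and
    Molecular Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline that coarsens functional connectivity
    graphs to minimal graphs by an agglomerative merging rule, classifies
    nodes as segregators (early, logarithmic-like mergers) or integrators
    (late, exponential-like mergers), screens a genes-by-regions expression
    matrix against the resulting segregation-minus-integration phenotype
    map using spatial-autocorrelation-preserving surrogate nulls
    (variogram matching), performs surrogate-calibrated gene-set
    overrepresentation with kappa-similarity term clustering, and relates
    the resulting annotations to molecular evolution by regressing mean
    dN/dS ratios on primate divergence times under four curve families
    with a gene-list permutation null. A synthetic-data module generates
    inputs with planted ground truth so that every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
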