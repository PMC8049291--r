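Package: padex
Title: Expression-Pattern Characterization of Parkinson's Disease Associated Genes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes the expression patterns of a Parkinson's disease
    associated gene set (PAGs): tissue-preference enrichment by one-sided
    Fisher exact tests against a background universe, inhibitory versus
    excitatory neuron-type profiling by Wilcoxon rank-sum tests,
    spatiotemporal co-expression module detection with a soft-thresholded
    weighted network and topological overlap clustering, and association of
    module membership with patient age at onset. Seeded synthetic-data
    generators emulate the statistical structure of tissue-level,
    neuron-type-level and developmental expression resources so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
biocViews: GeneExpression, Network, Clustering, Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
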