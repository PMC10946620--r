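Package: EcoParallel
Title: Repeatability of Parallel Ecotype Divergence from Expression and
    Allele-Frequency Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how repeatable parallel ecotype divergence is
    across replicated population pairs, combining a transcriptomic and a
    population-genetic track. The package implements composite-likelihood
    demographic model selection on folded joint site-frequency spectra under
    four-deme divergence models (single versus independent ecotype origins,
    with or without migration) driven by a built-in structured-coalescent
    simulator; diversity and differentiation summaries (pi, Watterson's
    theta, Tajima's D, Hudson/Bhatia FST by gene) with top-fraction outlier
    calling and permutation tests; a self-contained negative-binomial
    differential-expression stage (CPM filtering, TMM normalization,
    likelihood-ratio tests per ecotype pair); gene-reuse repeatability
    statistics (Jaccard indices, exact multi-set hypergeometric overlap
    tests, C-hypergeometric scores, sharing partitions, category
    enrichment); conditioned redundancy analysis of expression with
    permutation ANOVA; and seeded generators of synthetic expression and
    genetic data with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
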