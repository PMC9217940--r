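Package: wocna
Title: Weighted OTU Correlation Network Analysis for Snow Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community analysis toolkit for snow algae bloom microbiomes and
    similar amplicon surveys. Provides iterative-rarefaction alpha diversity
    (observed richness, Simpson evenness, Gini-Simpson diversity) and mean
    Bray-Curtis dissimilarity, paired and unpaired Wilcoxon tests with
    median-difference effect sizes across bloom zones and regions,
    single-covariate permutational multivariate ANOVA on distance matrices,
    and a weighted OTU correlation network analysis (WOCNA): Hellinger
    transformation, soft-thresholded correlation adjacency, topological
    overlap, gap-based module detection, eigen-OTU summaries, bootstrap
    clusterwise Jaccard module stability, Kendall tau module-trait
    correlation, and thresholded first-order co-association networks.
    Includes a synthetic community generator with planted modules,
    environmental drivers and zonal density gradients that provides ground
    truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
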