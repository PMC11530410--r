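Package: loadscape
Title: Mutation Load, Inbreeding and Climate Genomic Offset in Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic-vulnerability analysis for structured plant populations
    from multi-sample variant data: site-level filtering and LD pruning,
    pixy-style windowed nucleotide diversity, Hudson's FST, DXY and Tajima's D
    with missing-data-aware denominators, runs of homozygosity with FROH and
    FIS inbreeding coefficients, polarization of sites to ancestral/derived
    state, Grantham-score classification of missense variants and
    total/masked/realized mutation load, and a gradient-forest style
    genotype-environment turnover model with redundancy-analysis outlier
    detection and per-grid-cell genomic offset under future climate
    scenarios. Includes a synthetic cohort generator emulating a two-lineage,
    thirteen-population study design so the full pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    geosphere,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
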