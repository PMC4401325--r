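Package: radmarker
Title: Molecular Marker Development from Parental RAD-Seq Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mines microsatellites (SSRs) from two de-novo parental contig
    sets, anchors markers across genotypes by seeded local alignment of
    flanking sequences, calls in-silico polymorphisms (SSR repeat-count
    differences and homozygous-polymorphic SNP/InDel sites from caller-style
    variant tables), applies hard filters and known-marker redundancy rules,
    clusters nearby markers into primer regions and designs primer pairs,
    and reports marker summary statistics including segregation chi-square
    screening. Ships a synthetic dual-parent data generator with a planted
    truth table so every pipeline stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
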