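Package: pirnascreen
Title: Biallelic piRNA-Pathway Variant Screening and Pachytene piRNA Length Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a panel-based screen for biallelic
    high-impact variants in piRNA-pathway genes in infertile men, together with
    the downstream analyses that such a screen feeds: compound-heterozygote
    phase resolution from trio genotypes or long-read fragment observations,
    Gene Ontology over-representation of a discovery gene set (one-sided
    hypergeometric test with Bonferroni control), and a small-RNA processing
    cascade that quantifies pachytene piRNA length spectra (26-31 nt) and
    compares case against control samples with Shapiro-Wilk and exact
    Mann-Whitney U statistics. Seedable simulators provide cohorts with planted
    truth, Mendelian trios, phase-informative fragments and toy small-RNA read
    sets so every stage is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
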