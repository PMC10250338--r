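Package: minicircler
Title: Analysis of Minicircular Mitochondrial Genomes from Long Reads
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying multipartite (minicircular) organelle
    genomes in which each small circular chromosome carries one gene
    cassette plus a species-shared constant region containing tandem
    repeats. Provides a synthetic-data generator with ground truth for
    nanopore-style long reads, a local aligner with identity and coverage
    filters, concatemer (homo/hetero) read classification with gene-pair
    network summaries, minicircle annotation (canonical rotation, ORF
    finding under translation table 4, constant-region/cassette
    segmentation, tandem-repeat detection, constant-region grouping), and
    quantitative statistics (qPCR standard curves and absolute copy
    number, Wilcoxon rank-sum GC comparisons, DNA contour-length
    conversions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
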