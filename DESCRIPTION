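Package: magpop
Title: Pool-Seq Population Genomics for Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for metapopulation genomics of eukaryotic
    metagenome-assembled genomes (MAGs) from pooled allele counts: read-recruitment
    quality control (identity filters, vertical coverage, breadth, coverage-profile
    unimodality), single-nucleotide-variant landscapes (density, Ts/Tv, genomic
    context and coding effect), per-locus and median pairwise fixation indices with
    region-level aggregation, selection scans (Lewontin-Krakauer statistic against
    chi-squared and a PCA/Mahalanobis outlier scan on B-allele frequencies with FDR
    control), and environmental variance partitioning of genomic differentiation by
    restricted maximum likelihood over distance-derived kernels, verified by Mantel
    tests. Includes a synthetic-data generator (island-model allele counts with
    planted selected loci, environment-linked differentiation, toy genomes and
    annotations) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    quadprog,
    optparse
Config/testthat/edition: 3
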