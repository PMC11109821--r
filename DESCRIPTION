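Package: ovipop
Title: Population-Genomic Viability Metrics for Wild and Domestic Sheep Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the genetic viability of small, bottlenecked
    ungulate populations from whole-genome SNP data. Implements outgroup-f3
    and f4 statistics with weighted block-jackknife standard errors,
    1-outgroup-f3 distance matrices with chunked-bootstrap replicates,
    classical MDS and neighbor-joining summaries with bipartition support,
    sliding-window runs-of-homozygosity calling with F_ROH and inbreeding-time
    dating, coverage-based genetic sexing (Rx), pseudo-haploid pairwise-mismatch
    kinship classification, mitochondrial nucleotide diversity, and
    GERP-weighted relative mutation load. A synthetic-data generator with known
    truth (drift on a population tree, planted relatives, planted homozygous
    tracts, sex-dependent X coverage, conserved-region allele burdens)
    supports parameter-recovery testing of every stage.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
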