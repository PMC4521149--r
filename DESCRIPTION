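Package: hgtscreen
Title: Screening Insect Genomes for Horizontally Transferred Bacterial Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate horizontal gene transfer (HGT) events from
    bacteria into an insect genome by differential homology screening: each
    predicted protein is compared against taxon-partitioned reference sets and
    called a candidate when its best bacterial hit is more significant than its
    best arthropod hit. Candidates are filtered for bacterial contamination of
    the assembly using an RNA-seq exon-coverage criterion, annotated with
    genomic-integration evidence (introns, scaffold context), and confirmed
    phylogenetically by neighbor-joining trees with bootstrap support, outgroup
    rooting, and a bacterial-clade placement test. A synthetic-data generator
    produces truth-labelled annotation, hit tables, coverage tracks, and
    alignments so every stage is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
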