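Package: labSweeps
Title: Domestication Genomics of Laboratory Fly Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and characterises genetic differentiation between inbred
    laboratory strains and wild populations of Drosophila melanogaster.
    Implements outgroup polarisation of diallelic sites under coverage
    filters, classification of lab-specific and highly differentiated SNPs
    (Hudson's FST with Z-transformation), codon-level annotation of coding
    changes (Grantham distance, codon position, preferred-codon shifts), a
    neutral codon-mutation simulator providing null envelopes for
    selective-constraint statistics across site-frequency classes,
    Watterson's theta and Dxy in genomic windows, extended-haplotype outlier
    detection around focal SNPs (Z-hap scores), category and gene-set
    enrichment with gene-length normalisation, neighbor-joining trees on
    p-distances with bootstrap, and a forward-in-time population simulator
    that generates complete synthetic studies (inbred strains, a wild panel,
    an outgroup, gene models) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
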