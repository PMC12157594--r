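Package: pangecall
Title: Pangenome-Aware Small-Variant Calling from Haplotype-Augmented Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pangenome-aware small-variant caller. Candidate
    SNVs and indels are discovered from read alignments against a linear
    reference, encoded as fixed-width multi-channel pileup tensors augmented
    with a block of reference-aligned pangenome haplotypes, and genotyped
    with a small convolutional neural network into reference, heterozygous
    and homozygous-alternate classes. The package also builds personalized
    haplotype panels by k-mer similarity scoring, writes VCF, generates
    seeded synthetic diploid data sets (including a segmental-duplication
    read-mismapping scenario), and evaluates call sets against a truth set
    with fixed/induced error-transition classification stratified by region
    and panel allele frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    graphics,
    utils,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
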