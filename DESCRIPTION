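Package: ccmosaic
Title: Founder Haplotype Mosaics, Residual Heterozygosity and Private
    Deletions in Collaborative Cross Strains
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing the genomes of Collaborative Cross
    (CC) recombinant inbred mouse strains. Implements trio-based estimation
    of residual heterozygosity from genotyping-array calls, 36-state founder
    diplotype reconstruction by a forward-backward hidden Markov model with
    obligate-ancestor (MRCA) merging, discovery of strain-private homozygous
    deletions from short reads via a 45-mer tiling of the reference against
    an exact k-mer read index, and founder haplotype frequency and
    wild-derived enrichment accounting. A synthetic CC funnel breeding
    simulator with known ground truth supports end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, HiddenMarkovModel, SNP, Sequencing, StructuralVariation
RoxygenNote: 7.3.3
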