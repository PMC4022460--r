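Package: satkit
Title: Alignment-Free Characterization of Complex Satellite DNA from Shotgun Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing complex satellite DNA families (such as human
    satellites 2 and 3, built from diverged arrangements of the pentamer CATTC) directly
    from whole-genome shotgun reads, without alignment or a consensus reference. Provides
    a pentamer-enrichment Poisson screen and RepeatMasker-based selection of
    satellite-containing reads with quality masking and orientation; k-mer frequency
    featurization; mate-pair-constrained recursive spectral clustering (normalized cut)
    into satellite subfamilies gated by self-mate-pair frequency; subfamily-diagnostic
    24-mer libraries; Bayesian binomial-mixing localization of subfamilies to chromosomes
    from flow-sorted chromosome read sets, and Poisson-model localization of unmapped
    scaffolds; and per-individual satellite array size estimation from short-read k-mer
    hit rates with AT-matched single-copy controls. A synthetic-data module simulates
    satellite genomes, Sanger-like paired reads, flow-sorted chromosome mixtures and
    short reads with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    cluster,
    optparse
Config/testthat/edition: 3
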