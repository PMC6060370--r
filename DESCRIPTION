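Package: sweepscan
Title: Selection-Signature Scans in Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genomic signatures of selection among hierarchically
    structured subpopulations from diploid SNP genotypes. Implements windowed
    Weir-Cockerham F_ST and the locus-specific d_i divergence statistic with
    empirical thresholding, the FLK and hapFLK tests of allele- and
    haplotype-frequency differentiation against a Reynolds-distance kinship
    matrix, a fastPHASE-style haplotype-cluster hidden Markov model fitted by
    EM to unphased genotypes, a local-haplotype-sharing scan with
    orphan-signal removal, merging of significant windows into regions of
    interest, cross-method consensus, and gene annotation. Includes a
    Balding-Nichols simulator of structured populations with founder-mosaic
    linkage disequilibrium and injected selective sweeps with recorded ground
    truth, plus PLINK PED/MAP and VCF input/output and marker quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    MASS,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
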