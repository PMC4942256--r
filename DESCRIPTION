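Package: haploscreen
Title: Haploid Gene-Trap Insertional Mutagenesis Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for loss-of-function genetic screens in
    near-haploid human cells mutagenized with a gene-trap retrovirus.
    Includes a fully synthetic screen simulator with known ground truth
    (genome, gene models, insertion library, drug selection and inverse-PCR
    style sequencing reads), restriction-site read trimming, exact-match
    unique read mapping, insertion-site calling with proximity and
    read-support filters, exon/intron sense-orientation classification of
    inactivating insertions, and per-gene enrichment testing against a
    control library with Fisher's exact test. Also provides small defined
    calculators used alongside such screens: monoisotopic mass and
    Paal-Knorr adduct arithmetic with ppm extracted-ion-chromatogram
    windows, phosphatidylethanolamine fraction from phosphorus analysis,
    radiolabel flux normalization, calcein liposome-leakage percentages,
    viability normalization and delta-delta-CT relative expression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    methods,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
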