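Package: coculture
Title: Multi-Omics Analysis of Pairwise Microbial Co-Culture Experiments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing pairwise co-culture interaction experiments
    in small bacterial communities. Provides multiplexed RNA-seq
    deconvolution by competitive k-mer assignment against concatenated
    strain genomes (with rRNA decontamination, median-of-ratios
    normalization, TPM, and a simplified negative-binomial differential
    expression test), LC-MS peak-table preprocessing (blank and replicate
    filtering, related-peak collapsing, QC-based signal drift correction,
    probabilistic quotient normalization, k-nearest-neighbour imputation,
    generalised-logarithm variance stabilization) with dual-contrast
    attribution of metabolite features to producer strains, colony-area
    quantification from plate images, hypergeometric pathway enrichment,
    and synthetic-data generators that emulate the full experimental
    design with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    MASS,
    jsonlite,
    yaml,
    png,
    optparse,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
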