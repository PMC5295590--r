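Package: evilmap
Title: Mapping EMS-Induced Mutations by Sequencing Without Outcrossing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward genetics by sequencing for EMS-mutagenized inbred
    pedigrees. Filters raw variant calls down to high-confidence
    EMS-induced G:C-to-A:T SNPs through a sequential quality cascade,
    removes reproducible false-positive positions by subtracting calls
    shared between independently mutagenized lineages, maps a recessive
    mutant by allele-frequency cosegregation among siblings without an
    outcross, and reduces the candidate list to a single causal coding
    change. Includes a pedigree simulator (selfing with recombination,
    pooled sequencing at unequal depths, planted error-prone positions)
    that provides ground truth for end-to-end validation, a simplified
    binomial genotype caller, and a codon-level variant effect
    annotator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
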