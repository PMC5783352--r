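Package: trfbin
Title: Structure-Anchored Binning and Quantification of tRNA-Derived Fragments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide discovery and quantification of tRNA-derived
    fragments (tRFs) from small RNA sequencing data. Parses tRNAscan-SE
    annotations, filters pseudogene, selenocysteine and intron-containing
    tRNAs, anchors fixed-width bins on clover-leaf landmarks (precursor
    leader/trailer, mature ends and the D-, anticodon- and T-loops), exports
    them as GTF, assigns aligned reads to bins, and tests differential tRF
    abundance with TMM-scaled Fisher exact contrasts. Includes sex-bias
    classification across strains, mutual-information sample comparison with
    a Spearman estimator, PCA and Ward clustering with Newick dendrogram
    export, a negative-binomial read simulator with truth tables for
    end-to-end validation, and a command-line pipeline front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
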