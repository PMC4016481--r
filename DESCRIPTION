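Package: TElandscape
Title: Transposable Element Landscape Annotation, Dating and Decay Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for characterising the transposable
    element (TE) landscape of a genome from a consensus library:
    a seed-and-extend repeat annotator, iterative majority-rule consensus
    building with single-copy boundary detection, discovery of SINE
    subfamilies from co-segregating diagnostic sites, Kimura 2-parameter
    divergence dating with conversion to activity windows in millions of
    years, fragment decay profiling as evidence of genomic deletion,
    nested-insertion detection, an intact open reading frame census, and
    a horizontal-transfer screen.  A companion simulator plants TE copies
    with known ages, truncations, deletions, subfamily structure and
    nesting into synthetic genomes so that every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
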