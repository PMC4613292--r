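Package: barcodegap
Title: Barcoding-Gap Analysis and Species Identification for DNA Barcode Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation of short DNA barcode markers (such as the nuclear
    ribosomal ITS2 region) for species discrimination within a genus.
    Implements Kimura 2-parameter pairwise distances with pairwise deletion,
    the six standard metrics of inter-specific divergence and intra-specific
    variation, barcoding-gap distribution profiles with Wilcoxon rank-sum
    comparison, species identification by best local-alignment hit and by
    nearest genetic distance with leave-one-out success rates, per-species
    heterogeneity/separability tables in the style of TaxonGap, and
    neighbor-joining trees with nonparametric bootstrap supports and
    outgroup rooting. A sequence-family simulator generates labeled
    alignments with controlled intra- and inter-specific divergence for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
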