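Package: barcodive
Title: DNA Barcode Evaluation for Recently Diversified Plant Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate candidate DNA barcoding loci in species groups
    with shallow divergence and incomplete lineage sorting. Computes Kimura
    2-parameter distances with pairwise deletion and saturation masking,
    intra- versus inter-specific barcoding-gap statistics (median and Wilcoxon
    two-sample tests, distance histograms), neighbor-joining and UPGMA trees
    with nonparametric bootstrap, species-monophyly resolution rates with
    bootstrap qualification, and leave-one-out specimen identification under
    the best match, best close match and all species barcodes criteria, over
    arbitrary marker combinations. Includes a multispecies-coalescent
    simulator (Yule species tree with compressible internal branches,
    per-marker gene trees, introgression events, K80 sequence evolution)
    that produces truth-labeled multi-marker datasets for validating every
    stage of the analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    Biostrings,
    optparse
Config/testthat/edition: 3
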