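Package: ncatlas
Title: Multi-Tissue Noncoding RNA Aging Trajectories and Parabiosis Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for body-wide small noncoding RNA aging
    studies: reads-per-million normalization and abundance filtering
    (including prepachytene piRNA cluster filtering), Spearman-based
    classification of local versus global aging miRNAs, fold-change
    deregulation testing with Benjamini-Hochberg correction per tissue and
    timepoint, fuzzy c-means clustering of z-scored cross-organ expression
    trajectories with minimum-centroid-distance model selection,
    miRNA-mRNA target inference by inverse expression correlation with
    conserved binding-site enrichment controls, coverage statistics for
    fragment-sequenced long ncRNAs, IUPAC motif scanning of mature miRNA
    sequences, and rejuvenation/accelerated-aging classification for
    heterochronic parabiosis cohorts. Includes a negative-binomial
    synthetic cohort generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    mclust,
    Biostrings
Config/testthat/edition: 3
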