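Package: eshrd
Title: Enrichment-Score Deconvolution of Homogenate RNA Differential Expression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies genes by brain cell-type specificity from a
    cell-sorted reference expression panel (fpkm, genes x cell types) using
    per-cell-type enrichment scores, and uses the resulting labels to
    deconvolute bulk (homogenate) differential-expression results into
    cell-type-specific findings. Includes permutation-based enrichment
    testing of cell classes among differentially expressed genes,
    sign-concordance and rank-correlation validation against cell-resolved
    differential-expression tables, mouse-to-human ortholog mapping, and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
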