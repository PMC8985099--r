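Package: sspAMS
Title: Small Secreted Proteins and Arbuscular Mycorrhizal Symbiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of plant small secreted proteins (SSPs) in
    relation to arbuscular mycorrhizal symbiosis (AMS). Implements a
    majority-decision consensus caller over per-tool secretion predictions
    (signal peptide, transmembrane, extracellular localization),
    classification of ortholog groups as AMS-specific or AMS-preferential,
    detection of cross-species convergent AMF-responsive expression of SSPs,
    and extraction of thresholded Pearson co-expression subnetworks. Ships a
    synthetic-data generator with known ground truth so the whole pipeline is
    exercisable end-to-end without external predictors or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
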