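Package: dockfp
Title: Inverse Molecular Docking Fingerprints and Retrospective
    Enrichment Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Target fishing by inverse molecular docking: aggregates
    per-structure docking scores to unique protein targets (best score
    per UniProt accession), converts each ligand's score profile into a
    Z-score fingerprint, compares fingerprints by all-against-all
    root-mean-square deviation with Ward agglomerative clustering, and
    builds curated top-target heatmaps and hit tables. Includes a
    retrospective validation suite (ROC AUC, enrichment factor, robust
    initial enhancement, BEDROC, predictiveness-curve total gain)
    against known actives, a synthetic docking-score generator with
    planted ground truth, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    pheatmap,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    ape
Config/testthat/edition: 3
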