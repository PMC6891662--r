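Package: hemoquant
Title: Quantification of Insect Hemocyte Immune Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement pipeline for the cellular immune assays used to
    study parasitoid venom immunosuppression in insect hosts. Scores
    bead encapsulation micrographs (capsule angular coverage, annulus
    thickness, grade schemes and the weighted encapsulation index),
    quantifies hemocyte spreading and phagocytosis percentages from
    multi-channel fields, computes relative F-actin fluorescence,
    post-processes molecular-docking pose tables (best-conformer
    selection, binding energy to inhibition constant conversion, ligand
    ranking), and provides the accompanying statistics (one-way ANOVA
    with Tukey HSD, Pearson chi-square). Includes seeded synthetic-data
    generators that render beads, hemocyte fields and reading tables
    with exact ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
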