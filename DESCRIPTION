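Package: cmaquant
Title: Quantification Toolkit for Pharmacological Chaperone-Mediated Autophagy Activation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the chaperone-mediated autophagy (CMA) activation index
    from gene-expression matrices using a weighted, direction-signed gene
    network, together with the supporting quantitative assays of a
    pharmacological CMA-activation study: expression preprocessing
    (interquartile-range filtering, z-score normalization, delta-delta-Ct
    fold changes), co-repressor/receptor expression ratios, fluorescent
    KFERQ-reporter puncta quantification from multichannel image fields
    (nuclei segmentation, expressing-cell gating, blob detection, CMA-positive
    classification, field-level quality control, tandem mCherry-GFP flux
    classification), fluorescence-polarization binding EC50 fits,
    non-compartmental pharmacokinetics, and radiolabel proteolysis fractions.
    Seeded synthetic-data generators with exhaustive ground truth make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
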