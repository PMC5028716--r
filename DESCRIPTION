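Package: deltarad
Title: Delta-Radiomics Response Phenotyping for Paired CT Lesion Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delta-radiomics analysis of paired (baseline/follow-up)
    CT lesion scans. Reads NIfTI/NRRD volumes with binary lesion masks,
    resamples to isotropic resolution, extracts a catalogue of 183 radiomic
    features (Laws texture energies, Gabor energies, grey-level co-occurrence
    statistics including IMC1 and the maximum correlation coefficient,
    surface shape-index fractions, sigmoid lesion-margin profiles, and
    volumetric descriptors), forms per-feature pre-minus-post delta values,
    applies coefficient-of-variation plus correlation-pruning feature
    selection, and screens features by ROC AUC against a binary mutation
    label with test-retest intraclass-correlation stability analysis. A
    synthetic lesion-phantom cohort generator with a mutation-dependent
    treatment-response model supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    minpack.lm,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
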