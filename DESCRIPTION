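Package: sodiumAT
Title: Quantitative Sodium MRI Analysis of the Achilles Tendon
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for quantitative sodium (23Na) MRI of the
    Achilles tendon. Implements saturation-recovery T1 and biexponential
    T2* relaxometry of the spin-3/2 23Na nucleus, voxel-wise
    monoexponential 1H T2* mapping, signal-to-noise estimation against a
    dedicated noise region, apparent tissue sodium concentration (aTSC)
    via reference-vial calibration with relaxation-weighting and
    partial-volume corrections, coil-sensitivity and translation motion
    correction, regional tendon statistics (Friedman and paired Wilcoxon
    tests with Bonferroni correction), and a synthetic digital-phantom
    study generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
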