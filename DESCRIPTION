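Package: fcgrflow
Title: Flow-Cytometric FcgammaRIIIa-V158F Genotype Prediction and ADCC Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts the FcgammaRIIIa (CD16) V158F polymorphism (FF, VF, VV)
    from a single-tube flow cytometry staining that exploits the differential
    binding of two anti-CD16 antibody clones (MEM154, genotype-sensitive;
    LNK16, genotype-tolerant) on NK cell subsets. Implements deterministic
    density-based gating, construction of 30 per-sample binding features,
    conditional-permutation-importance feature ranking, variance-inflation-factor
    filtering, and a linear-discriminant-analysis plus multinomial logistic
    regression classifier, together with leakage-safe grouped cross-validation,
    learning-curve analysis and a naive MFI-boundary baseline. A second
    component quantifies antibody-dependent cellular cytotoxicity (ADCC):
    LDH-release specific lysis, flow-based tumour-kill deltas, a 154-measure
    delta/fold-change immune parameter table, rank-based group statistics and
    tSNE embedding. A seeded synthetic flow-data generator provides the
    statistical structure the method assumes for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    ranger,
    Rtsne,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    cluster,
    withr
Config/testthat/edition: 3
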