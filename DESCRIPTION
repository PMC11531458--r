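Package: edemaquant
Title: Quantitative CT Densitometry of Pulmonary Edema in ARDS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-density analysis of chest CT scans for quantifying
    pulmonary edema in acute respiratory distress syndrome. Computes lung
    volume, mean Hounsfield density, calculated lung weight and the
    aerated/tissue decomposition from a CT volume and a binary lung mask,
    with an optional Hounsfield-unit window that excludes contrast-agent
    voxels. Derives CT-based pulmonary edema against the height-predicted
    expected lung weight, and thermodilution-based edema from the
    extravascular lung water index and ideal body weight. Provides
    Bland-Altman agreement statistics with limits of agreement and an
    agreement-study power simulation, rank correlation, mask-overlap
    indices (Jaccard/Dice), and a synthetic CT phantom and cohort
    generator with exact per-voxel tissue-fraction ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
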