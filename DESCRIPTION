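Package: femur3d
Title: Bone-Centered 3D Femoral Angle Measurement and Method-Comparison
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes canine femoral torsion, neck inclination and varus
    angles from three-dimensional anatomical landmark coordinates using a
    bone-centered coordinate system: a least-squares sphere fit locates the
    femoral head center, landmark-defined longitudinal and retrocondylar
    axes define transverse and dorsal projection planes, and signed
    projected angles yield the six standard angle variants (FTA-NC/NBC,
    FIA-NC/NBC, FVA-pd/td). Includes a parametric torsional-deformity
    phantom and clinical-cohort simulator for validation, plus the
    method-comparison statistics used in morphometric agreement studies:
    Bland-Altman limits of agreement, Passing-Bablok regression, and
    Bland's coefficient of variation for repeated measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
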