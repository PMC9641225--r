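Package: tumorburden
Title: Single-Slice Tumor Burden Quantification and Survival Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies metastatic tumor burden from single-slice CT lesion
    annotations and relates it to immunotherapy outcomes. Per-lesion 3D
    volumes are approximated from 2D freehand ROI polygons via exact polygon
    moments (area, principal axes), aggregated into five patient-level
    parameters (total volume, RECIST diameter sum, neutrophil-to-lymphocyte
    ratio, lesion count, organ count) at baseline and first evaluation, with
    percent variations, cutoff binarization and two-parameter concordance
    scores. Survival analysis (Kaplan-Meier with Greenwood bands, Mantel-Cox
    log-rank, Cox proportional hazards with Efron ties, Spearman independence
    screening) is implemented in-package, and a reproducible synthetic-cohort
    generator with planted proportional-hazards effects supports end-to-end
    testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    MASS
Suggests:
    survival,
    yaml,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
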