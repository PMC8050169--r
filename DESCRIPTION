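Package: stepconn
Title: Physical Activity, Sedentary Time and Structural Brain Network Degree
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline linking thigh-worn accelerometer
    (activPAL-style) measures of physical activity and sedentary time to
    node degree of structural white-matter brain networks. Provides posture
    bout classification under a step-cadence rule, construction of
    individual tract-volume-weighted connectomes from streamline sets,
    occurrence-based group reference networks at a target sparsity,
    whole-brain and regional degree metrics, and confounder-adjusted
    standardized-beta regression models. A synthetic cohort generator with
    known ground truth (event logs, label atlases, streamlines, connectomes
    and covariates) makes every stage testable without access to cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
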