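Package: zmatch
Title: Single-Subject Gray-Matter Atrophy Detection with Age-Matched
    Normative References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise Z-statistic mapping of gray-matter volume against
    normative reference groups for single-subject atrophy detection.
    Implements standard whole-sample references, age-bracket references
    built from the k cognitively normal subjects nearest in age to the
    index subject, regression-based W-score models, subthreshold-voxel
    extent scoring over labeled regions of interest, and ROC evaluation
    with paired DeLong tests for comparing reference strategies.  Includes
    a synthetic cohort generator with nonlinear age-related gray-matter
    decline, amyloid-status effects, and focal medial-temporal atrophy,
    so the full pipeline can be exercised and validated without access
    to clinical MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
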