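Package: electrovar
Title: Between-Subject Variability of EEG Electrode Positions and Their
    Underlying Brain Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for quantifying between-subject variability of EEG
    electrode positions localized on structural MRI. Per-subject electrode
    coordinates exported from neuro-navigation software are mapped to MNI
    space with subject-specific affine transformations, projected from the
    scalp onto a peeled cortical surface, and summarized per electrode
    (cross-subject mean, standard deviation, skewness, and overall
    deviation), with grand standard deviations, extreme-electrode rankings,
    and cap-size-grouped summaries. Electrode locations are labeled against
    a probabilistic cortical atlas using a highest-probability rule with
    tie and no-label exclusions, tallied as percentages over usable
    subjects, and supplemented by a nearest-label lookup (e.g. Brodmann
    areas) at cohort mean coordinates. Results can be rendered into
    NIfTI-1 volumes for overlay on an MNI template. A synthetic-cohort
    generator (10-10 montage on an ellipsoidal head, cap-level and
    electrode-level placement noise, synthetic atlases) provides
    ground-truth data for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
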