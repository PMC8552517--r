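Package: normvol
Title: Normative Modeling of Regional Brain Volumes and Segmentation-Method Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits age-dependent normative distributions of regional brain
    volumes with the LMS method under the Yeo-Johnson transformation,
    correcting for sex and height, and scores individual patients as
    z-scores relative to the reference population. Quantifies the
    interchangeability of volume measurement methods via Pearson
    correlation and absolute-agreement intraclass correlation ICC(A,1) on
    volumes and on patient z-scores, and evaluates the diagnostic value of
    the z-score with a Mann-Whitney AUC and bootstrap confidence
    intervals. Includes a synthetic cohort generator with per-method
    systematic distortions for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
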