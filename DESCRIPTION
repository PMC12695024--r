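Package: trackdev
Title: Sequential Cell Tracking for Longitudinal Calcium Imaging in the
    Growing Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks neurons across daily two-photon calcium imaging
    sessions in the developing brain, where tissue growth between
    recordings breaks the rigid-alignment assumption of adult-brain
    tracking tools. Consecutive sessions are aligned by affine
    registration of mean field-of-view images, regions of interest are
    matched by maximising total intersection-over-union through a linear
    sum assignment, putative false matches are rejected by automatic
    (Otsu) thresholding of the match-quality distribution, and tracks
    are propagated sequentially across sessions. Includes the
    complete-tracks evaluation metric against manually annotated ground
    truth, a synthetic multi-session benchmark generator with known
    correspondences, and longitudinal population analyses for tracked
    neurons: calcium event rates, pairwise-correlation structure and its
    across-day similarity, sigmoid transition fitting, dimensionality,
    and ridge decoding of motion from population activity within and
    across days.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    data.table,
    jsonlite,
    Matrix,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
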