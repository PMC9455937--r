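Package: motionmend
Title: Skeletal Motion Enhancement with a Tobit Kalman Filter and a
    Convolutional Motion Manifold
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cleaning and enhancing skeletal joint-trajectory data of
    the kind produced by low-cost depth sensors. Provides a per-joint Tobit
    Kalman filter with adaptive velocity-based censoring limits, a temporal
    convolutional autoencoder that learns a human-motion manifold, and
    latent-space optimization that fuses the two in either a parallel
    (filter-assisted) or serial (filter-refined) paradigm. Includes a
    forward-kinematic gait generator and corruption operators (additive
    Gaussian noise, random drop-out, occlusion bursts and outliers) so the
    whole pipeline is exercisable on synthetic data, plus preprocessing
    (Hampel outlier removal, rigid registration by singular value
    decomposition, per-joint bias removal) and evaluation metrics (joint
    position error, bone-length error, gait joint angles, body-quadrant
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
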