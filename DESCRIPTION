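Package: spectroclust
Title: Geographically Weighted Spectral Classification and Local
    Calibration for Soil Vis-NIR Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts soil organic carbon (SOC) from visible/near-infrared
    reflectance spectra in large spectral libraries by first classifying the
    spectra with geographically weighted principal component analysis (GWPCA)
    followed by fuzzy c-means (FCM) clustering, then calibrating a separate
    model per spectral cluster. Provides spectral preprocessing (resampling,
    absorbance transform, Savitzky-Golay smoothing), GWPCA with bisquare
    kernel and bandwidth selection, FCM with FPI/NCE cluster-validity
    indices, Kennard-Stone calibration/validation splitting, NIPALS partial
    least squares regression and an M5-style model tree, RPIQ-based model
    evaluation with grouped reports, random-forest band importance, a
    synthetic spatially structured spectral-scene generator, and an
    end-to-end pipeline comparing cluster-wise, stratum-wise and global
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    ranger,
    signal,
    stats,
    utils
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
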