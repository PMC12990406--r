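Package: decoctr
Title: Real-Time Mass-Spectrometry Monitoring and Endpoint Prediction for
    Herbal Decoctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing online real-time mass-spectrometry (ORT-MS)
    monitoring of herbal decoctions. Provides a calibrated kinetic simulator
    for the dissolution and sequential first-order hydrolysis of aconitum
    alkaloids and companion compound classes (biphasic tannin intermediates,
    thermal conversion products, stable terpenoids and declining glycosides),
    a dual-polarity full-scan stream renderer with a JSON-lines and mzML
    interface, extracted-ion-chromatogram reconstruction with boxcar
    denoising, Gaussian-sum and Fourier-series kinetic curve fitting, and a
    five-dimensional safety/bioactivity/time/energy/financial-cost (SBTEF)
    schema that selects an optimal decoction endpoint by safety-first
    lexicographic decision. Ships a worked Zhenwu Decoction scenario
    calibrated to published signal-intensity anchors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
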