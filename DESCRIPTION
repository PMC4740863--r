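Package: hemoscan
Title: Wideband Microwave Head Imaging for Intracranial Hemorrhage Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Radar-based microwave head imaging toolkit built around a
    delay-and-sum back-projection reconstruction driven by a point-of-entry,
    distance-dependent effective head permittivity model. Provides the full
    monostatic signal-processing chain (inverse discrete Fourier conversion of
    reflection-coefficient sweeps, Woody-aligned adjacent average subtraction
    for skin-clutter removal, gain normalization), Fermat shortest-electrical-
    path travel-time tables restricted to line-of-sight boundary points,
    image-quality metrics (signal-to-maximum-clutter, average signal-to-clutter,
    localization error), a synthetic 2D layered head phantom with a ray-based
    monostatic forward model, noise studies, and analytic radiation-safety
    calculators (incident power density and erfc-based skin temperature rise).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    minpack.lm,
    pracma,
    png
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
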