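Package: trenchsim
Title: Synthetic Mother-Machine Micrographs with Pixel-Perfect Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates bacterial growth in mother-machine microfluidic
    trenches with an agent-based model (adder, sizer and timer size
    regulation, lysis, rigid 1-D confinement), renders super-sampled
    optical-path-length scenes of the resulting linear colonies, corrupts
    them through a parametric microscope model (Airy and obscured-Airy
    point spread functions, apodisation, defocus) and a camera model
    (shot noise, read noise, quantisation), and exports training datasets
    of realistic phase-contrast or fluorescence images paired with exact
    ground-truth masks. Includes reference-matching utilities (histogram
    and rotational Fourier spectrum matching, per-region error reports)
    and label-free evaluation statistics: sawtooth identification-error
    rate, Jaccard-optimal probability thresholding, seeded watershed
    post-processing, and precision from quadratic residuals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
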