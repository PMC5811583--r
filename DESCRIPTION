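Package: scoutdose
Title: Quantitative Dosimetry for Holmium-166 Scout-Dose Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative safety dosimetry for holmium-166 microsphere
    scout-dose imaging during radioembolisation work-up. Computes the lung
    shunt fraction from anterior/posterior planar scintigraphy via the
    geometric mean, delineates extrahepatic depositions on quantitative
    SPECT by a phantom-calibrated percentage-of-maximum threshold,
    estimates deposited activity by margin-ROI summation, and converts
    activity and volume to beta absorbed dose. Includes a synthetic
    generator for NEMA IQ phantom and patient-like scenes with known
    ground truth (partial-volume-aware rasterization, Gaussian system
    blurring, Poisson noise), a threshold-calibration sweep, cohort
    summaries, and a command-line pipeline.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
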