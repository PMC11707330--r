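Package: plasmidcge
Title: Quantification of Plasmid DNA Isoforms from Gel Electrophoresis Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the topological isoforms of plasmid DNA (supercoiled,
    open-circular, linear) from one-dimensional capillary gel electrophoresis
    densiograms and agarose gel lane profiles. Provides background correction
    (linear or buffer-lane), windowed trapezoidal peak integration with
    sum-normalized fractions and optional dye attachment-efficiency
    correction, signal-to-noise and saturation quality control, Gaussian
    multipeak deconvolution of overlapping bands, and DNA-ladder apparent-size
    calibration. Includes downstream analyses for replicate aggregation,
    mixture-linearity regression, concentration-series checks and enzyme
    digestion time courses, plus a synthetic densiogram generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
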