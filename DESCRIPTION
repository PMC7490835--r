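Package: msdeconv
Title: Deconvolution and Compensation of Overlap Interferences in Gas
    Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Corrects isobaric (overlap) interferences in quadrupole
    mass-spectrometric gas analysis. Measured ion-current peak heights are
    deconvolved into contributions of known, max-normalised basis spectra by
    error-weighted least squares; the chi-square goodness of fit is used to
    rescale coefficient errors when stated measurement errors underestimate
    the misfit. The fraction of the ion current contributed by a target
    species at its analysis m/z is then used to compensate the peak height
    before calibration of concentrations or partial pressures by peak-height
    comparison against a reference gas. Includes readers and writers for a
    plain-text raw-readings dialect and the DECONVOLUTION configuration
    block, a synthetic-readings generator for validation, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
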