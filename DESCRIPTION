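Package: acwpeaks
Title: Spectral Peaks and Intrinsic Neural Timescales in Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the alpha/theta spectral peak of resting-state EEG
    power spectra (power, frequency, prominence, width, power ratio,
    spectral extrema) and the intrinsic neural timescale via
    autocorrelation-window statistics (ACW-50, ACW-e^-1, ACW-0), together
    with the downstream inference chain used to relate both families of
    markers to the state of consciousness: normality-gated group contrasts,
    gated correlations with Benjamini-Hochberg adjustment, chi-square tests
    on peak-occurrence tables, quantile splits, bootstrap mediation, and
    one-vs-one multiclass maximum-margin classification. Ships a synthetic
    EEG cohort generator with known spectral and temporal ground truth so
    the whole pipeline is testable without confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
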