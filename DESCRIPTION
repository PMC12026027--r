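Package: miadapt
Title: Motor-Imagery BCI Adaptability and EEG Functional Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies individual adaptability to motor-imagery
    brain-computer interfaces (MI-BCI) as the mean cross-validated pairwise
    classification accuracy over four imagery tasks, and relates it to EEG
    functional network structure. Provides a synthetic EEG generator with
    ground-truth phase-lagged coupling and event-related desynchronization,
    an EEG preprocessing chain (average re-reference, windowed-FIR band-pass,
    downsampling, channel interpolation, epoching), four feature extraction
    pipelines (multitaper power spectral density, discrete wavelet and
    wavelet-packet statistics, Riemannian covariance distances, filter-bank
    common spatial patterns), weighted phase lag index (WPLI) connectivity
    with proportional thresholding, binary graph metrics with hemispheric
    summaries, and Pearson correlation screening of network properties
    against adaptability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
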