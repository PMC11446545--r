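Package: mudecomp
Title: Real-Time Motor Unit Decomposition of Multichannel EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes the firing activity of individual motor units from
    multichannel electromyographic (EMG) recordings. Motor unit filters
    (separation vectors) are estimated offline from a baseline isometric
    contraction by convolutive blind-source separation (signal extension,
    whitening, fixed-point independent component analysis with deflation,
    k-means spike/noise classification and silhouette gating), then re-applied
    epoch by epoch to streamed EMG to identify discharge times and smoothed
    firing rates in real time. Includes a motor-unit-pool EMG simulator with
    ground-truth discharge times (recruitment, rate coding, twitch force,
    closed-loop force tracking, surrogate action-potential templates for
    surface grids and intramuscular arrays), programmatic spike-train editing,
    and spike-train agreement metrics (rate of agreement, sensitivity,
    precision, false negative rate, smoothed-rate RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    arrow,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
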