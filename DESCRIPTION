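Package: ymcoupling
Title: Single-Cell Coupling Analysis of the Yeast Metabolic Cycle and the Cell Division Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies phase coupling between flavin-reported metabolic
    oscillations and the cell division cycle in single budding-yeast cells.
    Provides a coupled-oscillator simulator of unsynchronized single-cell
    fluorescence traces (flavin plus a Whi5 nuclear-localization reporter,
    with nuclear-separation events gated to metabolic-cycle troughs or
    decoupled as under rapamycin), the trace-preprocessing chain used for
    time-lapse microscopy data (polynomial detrending, max normalization,
    Savitzky-Golay smoothing, prominence-based peak and trough detection,
    autocorrelation period estimation, short-track exclusion and sick-cell
    censoring), Whi5 nuclear-localization scoring from mask images, and the
    coupling statistics: peak-to-peak and trough-to-trough metabolic periods,
    division-cycle periods, trough-to-division lags, Whi5-to-flavin peak
    lags, metabolic cycles per division, period return maps and cohort
    summaries with Kolmogorov-Smirnov comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
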