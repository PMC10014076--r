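Package: lectincap
Title: Channel Capacity and Noise Decomposition of Glycan-Lectin Signaling Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Information-theoretic analysis of receptor-to-NF-kB reporter
    signaling from dose-indexed single-cell fluorescence data. Estimates the
    channel capacity of a receptor channel by binning single-cell outputs on a
    rectangular grid, maximizing mutual information over input distributions
    with the Blahut-Arimoto algorithm, correcting finite-sample bias by
    extrapolation to infinite sample size, and bootstrapping confidence
    intervals. Decomposes dose-response channels into signal power, noise
    power and their ratio, fits four-parameter logistic dose-response curves
    with EC50 comparison by the extra-sum-of-squares F test, and compares
    channels across receptors with rank-based tests. Includes readers for FCS
    3.0/3.1 and CSV event data and a synthetic single-cell reporter simulator
    with an analytically solvable known-channel mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
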