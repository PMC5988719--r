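Package: ornpulse
Title: Quantification of Prior and Optogenetically Evoked Activity in
    Larval Olfactory Receptor Neurons
Version: 0.1.0
Authors@R:
    person("ornpulse", "developers", email = "ornpulse@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying calcium-imaging recordings and
    optogenetic choice-assay behavior of Drosophila larval olfactory
    receptor neurons (ORNs). Implements delta-F/F0 normalization with
    lowest-quartile or stimulus-onset baselines, sigma-threshold event
    detection and event-frequency estimation for pre-stimulus ("prior")
    activity, periodogram power spectra with cross-trace averaging,
    pulse- and continuous-stimulation response metrics (maximum
    delta-F/F0, post-stimulus undershoot, return time), mean filtering
    and rolling-ball background subtraction for image stacks, ROI trace
    extraction, quadrant choice-assay performance indices and boundary
    entry/turn-back probabilities from larval trajectories, exact
    Wilcoxon rank-sum and Fisher tests with Bonferroni and
    Benjamini-Hochberg adjustment, and seeded synthetic-data generators
    (calcium traces, stimulus responses, image stacks, arena
    trajectories) with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
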