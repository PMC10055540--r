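Package: kirsub
Title: Sub-Conductance Gating Analysis for Forced-Open Kir2 Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pH-dependent sub-conductance gating in
    forced-open inwardly rectifying potassium (Kir2) channels. Implements a
    two-parameter independent-subunit protonation model of sub-state gating
    (stationary distributions, titration curves, kinetic rates), synthetic
    single-channel trace generation with exact ground truth (continuous-time
    Markov and empirical semi-Markov modes, Bessel-filtered acquisition),
    trace idealization by constrained Gaussian-mixture fitting and Viterbi
    decoding, sub-state statistics (occupancies, transition tallies,
    intra-burst closure analysis, per-level current-voltage fits), a
    Henderson-Hasselbalch-type titration fitter for the model parameters, and
    pore-trajectory analytics for molecular-dynamics output (cylinder
    selections, conduction-event counting, potassium occupancy histograms,
    solvation/dewetting profiles, opposing-chain minimum-distance
    distributions) together with a synthetic trajectory generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
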