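Package: hybridbnm
Title: Hybrid Brain Network Models Driven by Injected Source Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of hybrid brain network models: coupled
    excitatory-inhibitory neural-mass nodes on a structural connectome driven
    by injected per-region currents (e.g. EEG source activity), with
    feedback-inhibition-control tuning of local inhibitory weights, a
    Balloon-Windkessel hemodynamic forward model, generators for artificial
    alpha-band drive and synthetic connectomes, and an analysis suite
    covering alpha-phase firing histograms, cycle-locked grand averages,
    static and sliding-window functional connectivity, Welch power-law
    spectral fits and detrended fluctuation analysis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
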