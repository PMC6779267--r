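Package: brainsl
Title: Adaptive Frequency-Modulated Stuart-Landau Whole-Brain Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting of a whole-brain network model in which each
    cortical region is a Stuart-Landau oscillator near a supercritical Hopf
    bifurcation, coupled through a weighted structural connectome, with an
    adaptive free-running frequency driven by the phases of structurally
    connected neighbours. Provides stochastic (Euler-Maruyama) integration of
    the coupled system, BOLD-like signal extraction, static and instantaneous
    phase-based functional connectivity summaries (modularity, order parameter,
    synchrony, metastability, dynamic-FC similarity distributions), grid-search
    identification of the model working point with a composite unity-normalized
    score and AIC model comparison, group-representative connectome
    construction with rank-based Gaussian weight resampling, graph-theoretic
    utilities (efficiencies, degree-preserving null models, threshold
    selection), an in silico single-node lesion suite (robustness under random
    failures versus targeted attacks, nodal and inter-system link vulnerability
    maps, feature-space hazardousness mapping), and a synthetic study generator
    so the full pipeline runs without any empirical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
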