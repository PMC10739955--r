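Package: crhmem
Title: Contextual Memory in Hypothalamic CRH Neurons: Simulation and
    Calcium-Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how hypothalamic corticotropin-releasing
    hormone (CRH) neurons store contextual memories of aversive and
    appetitive experience. Implements a spiking network of adaptive
    leaky integrate-and-fire neurons with a two-factor (aversive) and a
    one-factor (appetitive) delayed synaptic learning rule; a fiber
    photometry preprocessing chain (polynomial bleaching correction,
    isosbestic fitting, dF/F and cross-day z-scoring); cross-day
    miniscope field-of-view registration by stochastic descent on a
    weighted Frobenius image metric; data-driven subpopulation
    clustering (affinity propagation with exemplar-based agglomeration,
    and a +/-1 SD classifier); and population state-space analyses
    (SVD-based PCA, paired Pre/Post comparisons, recruitment
    regression, freezing-time summaries). Synthetic-data generators
    with known ground truth exercise the full pipeline end to end.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
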