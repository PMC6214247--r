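Package: painmark
Title: Topological Markers of Pain in Time-Varying Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ensembles of time-varying functional brain
    connectomes against a behavioural pain signal. Computes nine deterministic
    and five stochastic topological network measures (including the
    local-community-paradigm correlation, small-worldness indices against
    degree-preserving random and lattice null models, a bootstrap goodness-of-fit
    p-value for power-law degree distributions, modularity and structural
    consistency), summarises them per time step over connectome ensembles,
    interpolates the resulting curves on an hourly grid with monotone
    shape-preserving cubic Hermite interpolation, assesses correlation with a
    behavioural signal through a permutation significance test with Gaussian and
    distribution-preserving null models, embeds the signal set with PCA and
    Minimum Curvilinear Embedding, and tracks region-resolved retained
    connectivity (engrams) across time steps. Includes a seeded synthetic study
    generator with planted positive and negative controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    limma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
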