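Package: menet
Title: Molecular Ecological Network Analysis for Longitudinal Microbiome Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and analyses molecular ecological networks (MENs) from
    amplicon sequence variant (ASV) count tables: low-abundance and prevalence
    filtering, rarefaction, alpha and beta diversity with permutation tests
    (ANOSIM, Adonis, MRPP), Pearson correlation networks thresholded by the
    random-matrix-theory (RMT) transition from Gaussian-orthogonal-ensemble to
    Poisson eigenvalue spacing statistics, a full per-network topological index
    panel with degree-preserving null ensembles, modularity and Zi-Pi keystone
    classification, robustness and vulnerability simulation, time-series
    regression and complexity-stability correlation, pathway correlation
    networks with MCODE-style core subnetwork extraction, and a synthetic
    longitudinal community generator with planted correlation modules for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
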