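Package: nanodock
Title: Graph-Based Prediction of Nanocluster-Protein Interaction Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts interaction sites between ligand-protected metal
    nanoclusters and proteins. Proteins are represented as alpha-carbon
    contact graphs with 39 per-residue attributes expanded by a continuous
    Weisfeiler-Lehman scheme; nanoclusters by global shape descriptors and
    per-ligand geometric descriptors. A five-fold ensemble of feed-forward
    regressors, supervised only by configuration-level Coulomb plus van der
    Waals energies, learns pairwise ligand-residue interaction contributions.
    Rigid-body placement uses Metropolis simulated annealing with an adaptive
    step controller, agglomerative clustering of sampled centers of mass to
    rank candidate sites, and restricted all-atom refinement. A synthetic
    complex generator with a closed-form pairwise energy oracle makes the
    whole pipeline trainable and testable without molecular dynamics data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    boot,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
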