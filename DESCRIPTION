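Package: gacontact
Title: Protein Long-Range Contact Prediction with Genetic-Algorithm
    Classifier Ensembles
Version: 0.1.0
Authors@R:
    person("gacontact", "developers", email = "gacontact@example.org",
           role = c("aut", "cre"))
Description: Predicts long-range inter-residue contacts in protein chains
    from per-residue sequence profiles. Residue pairs separated by at least
    24 positions are encoded as 460-dimensional window vectors over three
    sliding profile windows, a genetic algorithm evolves a remove/merge
    feature transformation scored by nearest-centroid training accuracy,
    and an ensemble of such classifiers trained on disjoint balanced
    negative subsamples ranks candidate pairs for top-L/k evaluation.
    Includes PDB C-alpha and profile-table readers, a CASP RR writer, a
    geometry-driven synthetic chain generator, evaluation utilities, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
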