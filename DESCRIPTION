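Package: bilexnet
Title: Multi-Layer Self-Organizing Map Model of Bilingual Object Naming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and analyses a multi-layer self-organizing-map (SOM) model of the
    bilingual lexicon: coupled semantic, phonological and orthographic 30x40 maps joined
    by name-agreement-scaled Hebbian pathways and cross-language lateral connections
    within the phonological map. Provides encoders for feature norms, phoneme strings and
    spellings; a three-phase training protocol with a self-adjusting neighbourhood radius;
    simulated object naming with a three-route activation decomposition; a semantic
    convergence analysis battery (name-distribution similarity profiles, Fisher r-to-z
    group comparisons, typicality, weighted category centers and distance ratios,
    stepwise discriminant boundary complexity, outlier proportions); and a synthetic
    bilingual naming-data generator for fully reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
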