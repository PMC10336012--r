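Package: polyfp
Title: Polymer SMILES Canonicalization, Fragment-Based Polymer Generation,
    Chemical Language-Model Fingerprints, and Multitask Property Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for polymer informatics built around the PSMILES
    representation (SMILES strings with two [*] endpoint markers for the
    polymer repeat unit). Provides graph-based canonicalization that maps
    all translational, multiplicative, and permutational rewritings of a
    repeat unit to one unique string; retrosynthetic (BRICS-rule) fragment
    decomposition of polymer corpora and seeded recombination into novel
    hypothetical polymers; a small transformer encoder trained as a masked
    language model on canonical PSMILES whose sentence-averaged token
    latents serve as dense polymer fingerprints (with attention-map and
    feed-forward-activation introspection); composition-weighted copolymer
    fingerprints; and selector-conditioned multitask property predictors
    trained with five-fold cross-validation and a stacking meta learner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    nnet,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
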