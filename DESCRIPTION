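Package: rxnvae
Title: Generative Variational Autoencoder for Balanced Chemical Reaction Equations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for generating novel, stoichiometrically balanced gas-phase
    chemical reactions with a character-level sequence variational autoencoder
    (VAE). Provides a reaction-SMILES dialect parser with elemental composition
    and balance checking, corpus cleaning and integer encoding, a bidirectional
    LSTM encoder / repeat-vector LSTM decoder VAE implemented in C++, latent
    space sampling with a validation cascade (deduplication, balance, species
    validity), a reaction thermochemistry layer (Gibbs energy, entropy and
    dipole differences over per-species property tables) with a stability
    filter, a seeded synthetic corpus generator for testing, and a pipeline
    driver wiring the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
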