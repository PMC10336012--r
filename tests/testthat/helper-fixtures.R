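# Shared fixtures, built once per test run.  Heavy artifacts (the trained
# mini language model and its corpus) are created lazily and cached so
# that only the tests that need them pay for them.

.fx <- new.env(parent = emptyenv())

fixture_monomers <- function(n = 20, seed = 3) {
  key <- paste0("mons_", n, "_", seed)
  if (is.null(.fx[[key]])) .fx[[key]] <- seed_monomers(n, seed = seed)
  .fx[[key]]
}

fixture_library <- function() {
  if (is.null(.fx$lib)) .fx$lib <- build_library(fixture_monomers())
  .fx$lib
}

# A small trained language model for unit tests (not the acceptance-scale
# one): a few hundred strings, a few epochs.
fixture_lm <- function() {
  if (is.null(.fx$lm)) {
    corpus <- combine_fragments(fixture_library(), 300, seed = 21,
                                max_fragments = 3)
    cfg <- lm_config(epochs = 8, batch_size = 32, lr = 2.5e-3,
                     target_f1 = NULL)
    .fx$lm <- train_mlm(corpus, cfg, seed = 22, canonicalize = FALSE,
                        quiet = TRUE)
  }
  .fx$lm
}

# Small synthetic property table with descriptor fingerprints.
fixture_prop_data <- function(n_polymers = 40, n_records = 600, seed = 5,
                              sigma_rel = 0.15) {
  key <- paste0("prop_", n_polymers, "_", n_records, "_", seed, "_", sigma_rel)
  if (is.null(.fx[[key]])) {
    mons <- fixture_monomers(n_polymers, seed = 4)
    cfg <- generator_config(seed = seed, sigma_rel = sigma_rel)
    .fx[[key]] <- synth_properties(mons, cfg, n_records = n_records)
  }
  .fx[[key]]
}
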