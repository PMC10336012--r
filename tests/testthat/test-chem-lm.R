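# Vocabulary, tokenizer, masking, and the trained encoder's contracts.

test_that("vocabulary covers the PSMILES character classes bijectively", {
  v <- build_vocab()
  expect_length(v, 265)
  expect_true(all(c("[*]", "C", "c", "Cl", "0", "9", "(", ")", "=", "#",
                    "[CLS]", "[SEP]", "[MASK]", "[PAD]", "[UNK]", "_") %in% v))
  expect_false(anyDuplicated(v) > 0)
  # token <-> id round trip
  ids <- vocab_id(v, v)
  expect_identical(v[ids], unclass(v))
})

test_that("tokenization is greedy longest-match and round-trips exactly", {
  v <- build_vocab()
  tk <- tokenize_psmiles(v, "[*]COC[*]")
  expect_identical(tk$tokens,
                   c("[CLS]", "_", "[*]", "C", "O", "C", "[*]", "[SEP]"))
  expect_identical(detokenize(tk), "[*]COC[*]")
  # chlorine is one token, not C + l
  tk2 <- tokenize_psmiles(v, "[*]CC([*])CCl")
  expect_true("Cl" %in% tk2$tokens)
  expect_identical(detokenize(tk2), "[*]CC([*])CCl")
  # canonical fixtures round-trip with zero [UNK]
  for (p in fixture_monomers(10, seed = 2)) {
    tk <- tokenize_psmiles(v, canonicalize_psmiles(p))
    expect_false("[UNK]" %in% tk$tokens)
    expect_identical(detokenize(tk), canonicalize_psmiles(p))
  }
  # out-of-vocabulary characters fall back to [UNK]
  expect_true("[UNK]" %in% tokenize_psmiles(v, "C{C")$tokens)
  expect_equal(length(tokenize_psmiles(v, "C")$attention_mask), 4)
})

test_that("masking selects the right number of non-auxiliary positions", {
  v <- build_vocab()
  # a long synthetic sequence: 100 interior tokens
  seq100 <- list(ids = c(vocab_id(v, "[CLS]"), vocab_id(v, "_"),
                         rep(vocab_id(v, "C"), 100), vocab_id(v, "[SEP]")))
  m <- mask_tokens(v, seq100, rate = 0.15, seed = 1)
  expect_equal(sum(m$labels > 0), 15)
  # auxiliary positions never selected
  aux_pos <- c(1, 2, length(seq100$ids))
  expect_true(all(m$labels[aux_pos] == 0))
  # determinism
  expect_identical(mask_tokens(v, seq100, rate = 0.15, seed = 1), m)
  expect_false(identical(mask_tokens(v, seq100, rate = 0.15, seed = 2), m))
})

test_that("masking fraction and replacement mix match in expectation", {
  v <- build_vocab()
  seq100 <- list(ids = c(vocab_id(v, "[CLS]"), vocab_id(v, "_"),
                         rep(vocab_id(v, "C"), 60), vocab_id(v, "[SEP]")))
  mask_id <- vocab_id(v, "[MASK]")
  n_masked <- n_random <- n_kept <- 0
  for (s in 1:40) {
    m <- mask_tokens(v, seq100, rate = 0.15, seed = s)
    sel <- which(m$labels > 0)
    n_masked <- n_masked + sum(m$ids[sel] == mask_id)
    same <- m$ids[sel] == seq100$ids[sel]
    n_kept <- n_kept + sum(same)
    n_random <- n_random + sum(!same & m$ids[sel] != mask_id)
  }
  tot <- n_masked + n_random + n_kept
  expect_equal(tot, 40 * 9)  # ceil(0.15 * 60) = 9 per draw
  # binomial tolerance around the 80/10/10 split
  expect_gt(n_masked / tot, 0.72)
  expect_lt(n_masked / tot, 0.88)
  expect_lt(abs(n_kept / tot - 0.1), 0.06)
})

test_that("training reduces the loss and overfits a tiny corpus", {
  lm <- fixture_lm()
  h <- lm$metrics
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  # memorization check: evaluate masked F1 on the training distribution
  # of a model trained on a tiny corpus
  expect_gt(tail(h$val_f1, 1), 0.5)
})

test_that("fingerprints are dense, sized d_model, and rewriting-invariant", {
  lm <- fixture_lm()
  fp <- lm_fingerprint(lm, "[*]CC([*])CC")
  expect_length(fp, lm$config$d_model)
  expect_true(all(is.finite(fp)))
  expect_identical(fp, lm_fingerprint(lm, "[*]CC([*])CC"))  # deterministic
  for (r in rewriting_suite("[*]CC([*])CC", 5, seed = 3))
    expect_identical(lm_fingerprint(lm, r), fp)
})

test_that("attention maps have softmax rows and a normalized aggregate", {
  lm <- fixture_lm()
  p <- "[*]CC([*])CC"
  tk <- tokenize_psmiles(lm$vocab, canonicalize_psmiles(p))
  raw <- attention_maps(lm, p)
  expect_length(raw, lm$config$n_layers)
  expect_equal(dim(raw[[1]]), c(length(tk$ids), length(tk$ids),
                                lm$config$n_heads))
  for (h in seq_len(dim(raw[[1]])[3]))
    expect_equal(rowSums(raw[[1]][, , h]), rep(1, length(tk$ids)),
                 tolerance = 1e-8)
  agg <- attention_summary(lm, p)
  expect_equal(dim(agg), c(length(tk$ids), length(tk$ids)))
  expect_true(all(agg >= 0 & agg <= 1))
  expect_equal(max(agg), 1)
})

test_that("feed-forward activation NMF is non-negative with nested error", {
  lm <- fixture_lm()
  p <- "[*]CC([*])c1ccncc1"
  errs <- vapply(c(2, 4, 6), function(k)
    ffn_activation_nmf(lm, p, k = k, seed = 1)$rel_err, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))  # non-increasing in k
  fit <- ffn_activation_nmf(lm, p, k = 4, seed = 1)
  expect_true(all(fit$basis >= 0))
  expect_true(all(fit$coef >= 0))
  expect_equal(ncol(fit$basis), 4)
  expect_error(ffn_activation_nmf(lm, p, k = 1000), "rank bound")
})
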