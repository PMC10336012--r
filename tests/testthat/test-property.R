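# Property registry, transforms, copolymer fingerprints, splits, the
# multitask ensemble + meta learner, and evaluation arithmetic.

test_that("registry covers the property families with unique symbols", {
  reg <- property_registry()
  expect_false(anyDuplicated(reg$symbol) > 0)
  expect_setequal(unique(reg$category),
                  c("thermal", "thermodynamic & physical", "electronic",
                    "optical & dielectric", "mechanical", "permeability"))
  expect_true(all(reg$transform[grepl("^mu_", reg$symbol)] == "log10p1"))
  expect_equal(reg$transform[reg$symbol == "eps_b"], "log10p1")
  expect_equal(reg$transform[reg$symbol == "T_g"], "identity")
  expect_true(all(paste0("k_", c("1.78", "3", "15")) %in% reg$symbol))
})

test_that("target transforms are exact and guarded", {
  expect_equal(transform_target("mu_O2", 0), 0)
  expect_equal(transform_target("mu_CO2", 999), 3)
  expect_equal(transform_target("T_g", 450), 450)
  x <- c(0, 0.5, 10, 1e4)
  expect_equal(inverse_transform_target("mu_N2", transform_target("mu_N2", x)),
               x, tolerance = 1e-12)
  expect_error(transform_target("mu_He", -1), "negative")
  expect_error(transform_target("no_such_prop", 1), "unregistered")
})

test_that("copolymer fingerprints combine by composition weights", {
  f1 <- c(1, 0, 2); f2 <- c(0, 1, 4)
  expect_equal(combine_fingerprints(list(f1), 1), f1)
  expect_equal(combine_fingerprints(list(f1, f2), c(0.25, 0.75)),
               combine_fingerprints(list(f2, f1), c(0.75, 0.25)))
  expect_equal(combine_fingerprints(list(f1, f1), c(0.5, 0.5)), f1)
  expect_error(combine_fingerprints(list(f1, f2), c(0.5, 0.4)), "sum to 1")
  expect_error(combine_fingerprints(list(f1, c(1, 2)), c(0.5, 0.5)),
               "lengths differ")
})

test_that("split plans partition the data with stratified 20/80 shares", {
  tab <- fixture_prop_data()
  plan <- make_splits(tab, seed = 4)
  cv <- sort(unlist(plan$folds))
  expect_length(intersect(plan$meta_train, cv), 0)
  expect_setequal(c(plan$meta_train, cv), seq_len(nrow(tab)))
  expect_equal(anyDuplicated(cv), 0)
  # ~20% per property in the meta set
  for (p in unique(tab$property)) {
    idx <- which(tab$property == p)
    share <- length(intersect(plan$meta_train, idx)) / length(idx)
    expect_gt(share, 0.10)
    expect_lt(share, 0.30)
  }
  expect_identical(make_splits(tab, seed = 4), plan)
  expect_false(identical(make_splits(tab, seed = 5)$meta_train,
                         plan$meta_train))
  w <- capture_warnings(make_splits(tab[1:3, ], seed = 1))
  expect_true(any(grepl("fewer records", w)))
})

test_that("evaluation arithmetic matches hand-computed values", {
  rep1 <- evaluate_predictions(c(1, 2, 4), c(1, 2, 3), rep("T_g", 3))
  expect_equal(rep1$per_property$r2, 0.5)
  expect_equal(rep1$per_property$rmse, 1 / sqrt(3))
  # perfect predictions
  rep2 <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3), rep("T_g", 3))
  expect_equal(rep2$per_property$r2, 1)
  expect_equal(rep2$per_property$rmse, 0)
  # predicting the mean gives R^2 = 0
  rep3 <- evaluate_predictions(rep(2, 3), c(1, 2, 3), rep("T_g", 3))
  expect_equal(rep3$per_property$r2, 0)
  # category means equal means of member properties
  rep4 <- evaluate_predictions(c(1, 2, 4, 10, 30), c(1, 2, 3, 20, 30),
                               c("T_g", "T_g", "T_g", "T_m", "T_m"))
  expect_equal(rep4$per_category$r2, mean(rep4$per_property$r2))
  expect_error(evaluate_predictions(numeric(), numeric(), character()),
               "no aligned")
})

test_that("the ensemble + meta stack trains and predicts on all pairs", {
  tab <- fixture_prop_data()
  fps <- record_fingerprints(tab, descriptor_fingerprint)
  plan <- make_splits(tab, seed = 6)
  cfg <- multitask_config(hidden = 8L, maxit = 300L)
  ens <- train_ensemble(plan, fps, tab, cfg, seed = 6)
  expect_s3_class(ens, "multitask_ensemble")
  expect_length(ens$models, 5)
  # every model predicts every (polymer, property) pair
  P <- ensemble_predictions(ens, fps[1:4, , drop = FALSE],
                            rep("T_g", 4))
  expect_equal(dim(P), c(4, 5))
  expect_true(all(is.finite(P)))
  meta <- train_meta(ens, plan, fps, tab, cfg, seed = 6)
  expect_s3_class(meta, "meta_learner")
  mons <- unique(tab$psmiles_1)[1:3]
  pred <- predict_properties(meta, ens, mons)
  expect_equal(nrow(pred), 3 * length(ens$symbols))
  expect_true(all(is.finite(pred$prediction)))
  # transformed properties come back on the native (positive) scale
  expect_true(all(pred$prediction[pred$property == "mu_CO2"] > -1))
  summ <- summarize_predictions(pred)
  expect_true(all(summ$min <= summ$mean & summ$mean <= summ$max))
  expect_error(predict_properties(meta, ens, mons, symbols = "bogus"),
               "untrained")
  # deterministic inference
  expect_identical(predict_properties(meta, ens, mons), pred)
})

test_that("meta learner stacking approaches consistent ensemble output", {
  tab <- fixture_prop_data(n_records = 500, sigma_rel = 0)
  fps <- record_fingerprints(tab, descriptor_fingerprint)
  plan <- make_splits(tab, seed = 8)
  cfg <- multitask_config(hidden = 10L, maxit = 500L)
  ens <- train_ensemble(plan, fps, tab, cfg, seed = 8)
  meta <- train_meta(ens, plan, fps, tab, cfg, seed = 8)
  # on noiseless linear data the stack should fit well out of fold
  expect_gt(mean(meta$val_r2, na.rm = TRUE), 0.9)
})
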