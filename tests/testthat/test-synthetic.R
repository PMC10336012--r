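# Synthetic fixtures: seed monomers, rewriting suites, descriptors, and
# the property generator's recoverable structure.

test_that("seed monomers are valid, deduplicated, and include the probes", {
  mons <- seed_monomers(20, seed = 1)
  expect_length(mons, 20)
  for (p in mons) expect_true(validate_psmiles(p)$valid)
  expect_true(all(c("[*]CC([*])CC", "[*]CC([*])CCC",
                    "[*]CC([*])c1ccncc1") %in% mons))
  keys <- vapply(mons, canonicalize_psmiles, character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(seed_monomers(20, seed = 1), mons)
  expect_false(identical(seed_monomers(20, seed = 2), mons))
})

test_that("rewriting suites cover all variance classes and the class", {
  p <- "[*]CCO[*]"
  suite <- rewriting_suite(p, 6, seed = 11)
  expect_length(suite, 6)
  for (v in suite) expect_true(same_polymer_oracle(v, p))
  nh <- vapply(suite, function(s) n_heavy(parse_psmiles(s)), numeric(1))
  expect_true(any(nh == 6) || any(nh == 9))       # a k-fold multiple
  expect_true(any(nh == 3 & suite != p) ||
              any(vapply(suite[nh == 3], function(s) s != p, logical(1))))
})

test_that("descriptors capture cheap graph structure", {
  d <- descriptor_fingerprint("[*]CC([*])c1ccccc1")
  expect_named(d, DESCRIPTOR_NAMES)
  expect_equal(unname(d["n_heavy"]), 8)
  expect_equal(unname(d["backbone_len"]), 2)
  expect_equal(unname(d["arom_frac"]), 0.75)
  expect_equal(unname(d["n_rings"]), 1)
  expect_equal(unname(d["longest_side"]), 4)
  d2 <- descriptor_fingerprint("[*]CCOCC(=O)O[*]")
  expect_equal(unname(d2["n_O"]), 3)
  expect_equal(unname(d2["n_double"]), 1)
  # descriptors are representation-independent up to canonical class
  expect_equal(descriptor_fingerprint("[*]COC[*]"),
               descriptor_fingerprint("[*]OCC[*]"))
})

test_that("noiseless generation is exactly recomputable from the weights", {
  mons <- fixture_monomers(10, seed = 4)
  cfg <- generator_config(seed = 2, sigma_rel = 0, copoly_frac = 0)
  tab <- synth_properties(mons, cfg, n_records = 80)
  D <- t(vapply(mons, descriptor_fingerprint,
                numeric(length(DESCRIPTOR_NAMES))))
  Z <- D %*% t(cfg$weights)
  for (j in seq_along(cfg$properties)) {
    if (cfg$transform[j] == "log10p1") {
      rng <- range(Z[, j]); span <- if (diff(rng) > 0) diff(rng) else 1
      Z[, j] <- 3 * (Z[, j] - rng[1]) / span
    }
  }
  for (r in seq_len(nrow(tab))) {
    i <- match(tab$psmiles_1[r], mons)
    j <- match(tab$property[r], cfg$properties)
    expected <- if (cfg$transform[j] == "log10p1") 10^Z[i, j] - 1 else Z[i, j]
    expect_equal(tab$value[r], expected, tolerance = 1e-12)
  }
})

test_that("shared latent weights induce inter-task correlation", {
  mons <- fixture_monomers(40, seed = 4)
  cfg <- generator_config(seed = 3, sigma_rel = 0.15, copoly_frac = 0)
  tab <- synth_properties(mons, cfg, n_records = 2000)
  per_poly <- function(sym) {
    d <- tab[tab$property == sym, ]
    tapply(d$value, d$psmiles_1, mean)
  }
  tg <- per_poly("T_g"); tm <- per_poly("T_m")
  common <- intersect(names(tg), names(tm))
  expect_gt(length(common), 10)
  expect_gt(cor(tg[common], tm[common]), 0.5)
})

test_that("copolymer values follow the composition-weighted mixing rule", {
  mons <- fixture_monomers(10, seed = 4)
  cfg <- generator_config(seed = 7, sigma_rel = 0, copoly_frac = 1,
                          properties = c("T_g", "T_m"))
  tab <- synth_properties(mons, cfg, n_records = 40)
  cfg0 <- generator_config(seed = 7, sigma_rel = 0, copoly_frac = 0,
                           properties = c("T_g", "T_m"))
  homo <- synth_properties(mons, cfg0,
                           n_records = length(mons) * 2)
  hval <- function(p, sym) {
    d <- homo[homo$psmiles_1 == p & homo$property == sym, ]
    if (nrow(d)) d$value[1] else NA_real_
  }
  checked <- 0
  for (r in seq_len(nrow(tab))) {
    y1 <- hval(tab$psmiles_1[r], tab$property[r])
    y2 <- hval(tab$psmiles_2[r], tab$property[r])
    if (is.na(y1) || is.na(y2)) next
    expect_equal(tab$value[r],
                 tab$c_1[r] * y1 + tab$c_2[r] * y2, tolerance = 1e-10)
    checked <- checked + 1
  }
  expect_gt(checked, 3)
})

test_that("generation is reproducible under the seed", {
  mons <- fixture_monomers(10, seed = 4)
  cfg <- generator_config(seed = 5)
  expect_identical(synth_properties(mons, cfg, n_records = 50),
                   synth_properties(mons, cfg, n_records = 50))
})
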