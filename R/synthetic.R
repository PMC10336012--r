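## Synthetic fixtures: seed monomers, equivalent-rewriting suites, and
## property tables with known (recoverable) structure.  Everything is
## seeded and fully reproducible; none of it depends on a learned model.

PROBE_POLYMERS <- c(butene = "[*]CC([*])CC",
                    pentene = "[*]CC([*])CCC",
                    vinylpyridine = "[*]CC([*])c1ccncc1")

#' Generate a deduplicated list of seed monomers
#'
#' Template-built PSMILES strings over vinyl, ether, ester, and amide
#' backbones with a small substituent alphabet.  The three probe polymers
#' poly(but-1-ene) `[*]CC([*])CC`, poly(pent-1-ene) `[*]CC([*])CCC`, and
#' poly(4-vinylpyridine) `[*]CC([*])c1ccncc1` are always included.
#' Deduplication is canonical, so no two entries denote the same polymer.
#'
#' @param n number of monomers to return (>= 1).
#' @param seed integer seed controlling the template shuffle.
#' @return Character vector of `n` valid PSMILES strings (fewer, with a
#'   warning, if the template space is exhausted).
#' @examples
#' seed_monomers(10, seed = 1)
#' @export
seed_monomers <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  subst <- c("C", "CC", "CCC", "C(C)C", "CO", "COC", "OC", "OC(=O)C",
             "C(=O)OC", "C#N", "F", "Cl", "Br", "c1ccccc1", "c1ccncc1",
             "Cc1ccccc1", "C(F)(F)F", "N", "N(C)C", "SC", "CCO", "C(C)(C)C",
             "OCC", "CC#N", "Oc1ccccc1", "CCl", "C=C", "CC(C)C")
  templates <- c(
    "[*]CC[*]", "[*]CCO[*]", "[*]CCCO[*]", "[*]CCC(=O)O[*]",
    "[*]CCCCC(=O)N[*]", "[*]CCOC(=O)c1ccccc1C(=O)O[*]",
    "[*]Oc1ccc(cc1)C(C)(C)c1ccc(O[*])cc1",
    vapply(subst, function(r) paste0("[*]CC([*])", r), character(1)),
    vapply(subst, function(r) paste0("[*]CC(", r, ")CO[*]"), character(1)),
    vapply(subst, function(r) paste0("[*]CC(", r, ")C(=O)O[*]"), character(1)),
    vapply(subst, function(r) paste0("[*]CC(", r, ")CC(=O)N[*]"), character(1)),
    vapply(subst, function(r) paste0("[*]CCC(", r, ")O[*]"), character(1)))
  templates <- unname(templates)
  with_seed(seed, {
    templates <- sample(templates)
  })
  out <- unname(PROBE_POLYMERS)
  keys <- vapply(out, canonicalize_psmiles, character(1))
  for (t in templates) {
    if (length(out) >= n) break
    if (!validate_psmiles(t)$valid) next
    key <- canonicalize_psmiles(t)
    if (key %in% keys) next
    out <- c(out, t)
    keys <- c(keys, key)
  }
  if (length(out) < n)
    warning("template space exhausted: returning ", length(out),
            " monomers instead of ", n)
  out[seq_len(min(n, length(out)))]
}

## Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

## One random syntactic permutation of p: shuffle the atom storage order
## and the writer's traversal ranks.
permute_psmiles <- function(p) {
  mol <- parse_psmiles(p)
  n <- n_atoms(mol)
  perm <- sample(n)
  inv <- order(perm)
  m2 <- atoms_subset(mol, perm)
  m2$bonds$a1 <- inv[mol$bonds$a1]
  m2$bonds$a2 <- inv[mol$bonds$a2]
  st <- star_idx(m2)
  write_smiles(m2, start = st[sample.int(2, 1)], rank = sample(n))
}

#' Equivalent rewritings of a PSMILES string
#'
#' Draws `n` rewritings of `p` from the three variance classes --
#' translations (backbone window shifts), multiplications (k-fold repeats,
#' k <= 3), and permutations (randomized atom order) -- all of which
#' canonicalize to `canonicalize_psmiles(p)`.  With `n >= 3` at least one
#' member of each class is included (translations are skipped when the
#' backbone admits none).
#'
#' @param p valid PSMILES string.
#' @param n number of rewritings.
#' @param seed integer seed.
#' @return Character vector of `n` valid PSMILES strings.
#' @examples
#' rewriting_suite("[*]CCO[*]", 5, seed = 1)
#' @export
rewriting_suite <- function(p, n, seed = 1L) {
  stopifnot(n >= 1)
  mol <- parse_psmiles(p)
  m <- length(unit_backbone(unit_from_mol(mol)))
  with_seed(seed, {
    out <- character(0)
    rots <- if (m > 1L) {
      js <- seq_len(m - 1L)
      ok <- vapply(js, function(j)
        !inherits(tryCatch(rotate_psmiles(p, j), error = identity), "error"),
        logical(1))
      js[ok]
    } else integer(0)
    classes <- c(if (length(rots)) "rotate", "multiply", "permute")
    draws <- c(classes, sample(c(if (length(rots)) "rotate", "multiply", "permute"),
                               max(0, n - length(classes)), replace = TRUE))
    draws <- draws[seq_len(n)]
    for (cl in draws) {
      v <- switch(cl,
        rotate = rotate_psmiles(p, sample(rots, 1)),
        multiply = multiply_psmiles(p, sample(2:3, 1)),
        permute = permute_psmiles(p))
      out <- c(out, v)
    }
    out
  })
}

## ---------------------------------------------------------------------------
## Synthetic property tables

#' Configuration for the synthetic property generator
#'
#' Ground truth is linear in the cheap graph descriptors: property p of
#' polymer i is `y_pi = w_p . d_i + eps`, `eps ~ N(0, sigma_p)`, where the
#' per-property weights `w_p = a_p U` are mixtures of shared latent weight
#' rows `U`, which induces inter-property correlation (the synthetic
#' counterpart of the empirical T_g--T_m correlation multitask learning
#' exploits).  Properties flagged with the log10(x+1) transform in the
#' registry are generated as `10^z - 1` of a linear latent `z`, so they are
#' strictly positive and exercise the transform.  `sigma_rel` scales the
#' noise standard deviation relative to the signal standard deviation.
#'
#' @param seed integer seed used for the weights and all sampling.
#' @param properties property symbols (must be registered); default five
#'   properties spanning three correlated thermal tasks, a physical one,
#'   and a transformed permeability.
#' @param sigma_rel per-property noise-to-signal ratio(s); recycled.
#' @param obs_prob per-property observation probability (missingness mask);
#'   recycled.  A small value makes a low-n task.
#' @param copoly_frac fraction of records that are two-comonomer copolymers.
#' @param interaction_sd standard deviation of optional copolymer
#'   interaction noise (0 disables it).
#' @param n_latent number of shared latent weight rows.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             properties = c("T_g", "T_m", "T_d", "rho", "mu_CO2"),
                             sigma_rel = 0.15,
                             obs_prob = 1,
                             copoly_frac = 0.2,
                             interaction_sd = 0,
                             n_latent = 3L) {
  reg <- property_registry()
  if (!all(properties %in% reg$symbol))
    stop("unregistered property symbol(s): ",
         paste(setdiff(properties, reg$symbol), collapse = ", "))
  np <- length(properties)
  J <- length(DESCRIPTOR_NAMES)
  sigma_rel <- rep_len(sigma_rel, np)
  obs_prob <- rep_len(obs_prob, np)
  stopifnot(all(sigma_rel >= 0), all(obs_prob > 0), all(obs_prob <= 1))
  with_seed(seed + 90001L, {
    U <- matrix(stats::rnorm(n_latent * J), n_latent, J)
    A <- matrix(stats::rnorm(np * n_latent, sd = 0.6), np, n_latent)
    ## the first latent dominates the first min(3, np) tasks, with only a
    ## small task-specific admixture -> strong inter-task correlation
    k3 <- seq_len(min(3, np))
    A[k3, ] <- 0.25 * A[k3, ]
    A[k3, 1] <- 1
    W <- A %*% U
  })
  dimnames(W) <- list(properties, DESCRIPTOR_NAMES)
  structure(list(seed = as.integer(seed), properties = properties,
                 weights = W, sigma_rel = sigma_rel, obs_prob = obs_prob,
                 copoly_frac = copoly_frac, interaction_sd = interaction_sd,
                 transform = reg$transform[match(properties, reg$symbol)]),
            class = "generator_config")
}

#' Generate a synthetic property table
#'
#' Builds a long-format property table (one row per polymer/property
#' observation) over the given polymers according to a
#' [generator_config()].  Homopolymer values follow the configured linear
#' descriptor model; copolymer values are composition-weighted mixtures of
#' their comonomer values.  With `sigma_rel = 0` the table is exactly
#' recomputable from the descriptors and weights (noiseless oracle).
#'
#' @param polymers character vector of valid PSMILES strings.
#' @param cfg a `generator_config`.
#' @param n_records number of records to draw (with replacement over
#'   polymers); default one record per polymer and property.
#' @return A data frame in the dataset schema: `psmiles_1, psmiles_2, c_1,
#'   c_2, property, value` (with `psmiles_2 = NA`, `c_1 = 1` for
#'   homopolymers).
#' @export
synth_properties <- function(polymers, cfg, n_records = NULL) {
  stopifnot(inherits(cfg, "generator_config"), length(polymers) >= 1)
  D <- t(vapply(polymers, descriptor_fingerprint,
                numeric(length(DESCRIPTOR_NAMES))))
  ## latent (pre-transform, pre-noise) signals: polymers x properties
  Z <- D %*% t(cfg$weights)
  np <- length(cfg$properties)
  ## scale transformed targets into a positive decade range
  for (j in seq_len(np)) {
    if (cfg$transform[j] == "log10p1") {
      rng <- range(Z[, j])
      span <- if (diff(rng) > 0) diff(rng) else 1
      Z[, j] <- 3 * (Z[, j] - rng[1]) / span
    }
  }
  sig_sd <- apply(Z, 2, stats::sd)
  sig_sd[sig_sd == 0 | is.na(sig_sd)] <- 1
  with_seed(cfg$seed, {
    if (is.null(n_records)) n_records <- length(polymers) * np
    rows <- vector("list", n_records)
    for (r in seq_len(n_records)) {
      j <- sample(np, 1, prob = cfg$obs_prob)
      copoly <- stats::runif(1) < cfg$copoly_frac && length(polymers) > 1
      if (copoly) {
        ij <- sample(length(polymers), 2)
        c1 <- sample(c(0.25, 0.5, 0.75), 1)
        z <- c1 * Z[ij[1], j] + (1 - c1) * Z[ij[2], j] +
          if (cfg$interaction_sd > 0) stats::rnorm(1, sd = cfg$interaction_sd) else 0
      } else {
        ij <- sample(length(polymers), 1)
        c1 <- 1
        z <- Z[ij[1], j]
      }
      z <- z + stats::rnorm(1, sd = cfg$sigma_rel[j] * sig_sd[j])
      ## log-scale latents are floored at 0 so transformed properties stay
      ## non-negative (physical lower bound of the permeability scale)
      val <- if (cfg$transform[j] == "log10p1") 10^max(z, 0) - 1 else z
      rows[[r]] <- data.frame(
        psmiles_1 = polymers[ij[1]],
        psmiles_2 = if (copoly) polymers[ij[2]] else NA_character_,
        c_1 = c1, c_2 = if (copoly) 1 - c1 else NA_real_,
        property = cfg$properties[j], value = val,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
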