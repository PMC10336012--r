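## Multitask property prediction: registry, target transforms, stratified
## splits, the five-fold cross-validation ensemble of selector-conditioned
## networks, the stacking meta learner, and evaluation.

#' Polymer property registry
#'
#' The registry of predictable properties: symbol, description, unit,
#' category, and target transform.  Gas permeabilities `mu_*` and
#' elongation at break `eps_b` are modeled on the `log10(x+1)` scale; all
#' other properties use the identity transform.
#'
#' @return Data frame with columns `symbol`, `name`, `unit`, `category`,
#'   `transform`.
#' @export
property_registry <- function() {
  tab <- rbind(
    c("T_g", "glass transition temperature", "K", "thermal"),
    c("T_m", "melting temperature", "K", "thermal"),
    c("T_d", "degradation temperature", "K", "thermal"),
    c("c_p", "heat capacity", "J g-1 K-1", "thermodynamic & physical"),
    c("E_at", "atomization energy", "eV atom-1", "thermodynamic & physical"),
    c("O_i", "limiting oxygen index", "%", "thermodynamic & physical"),
    c("X_c", "crystallization tendency (DFT)", "%", "thermodynamic & physical"),
    c("X_e", "crystallization tendency (exp.)", "%", "thermodynamic & physical"),
    c("rho", "density", "g cm-3", "thermodynamic & physical"),
    c("E_gc", "band gap (chain)", "eV", "electronic"),
    c("E_gb", "band gap (bulk)", "eV", "electronic"),
    c("E_ea", "electron affinity", "eV", "electronic"),
    c("E_i", "ionization energy", "eV", "electronic"),
    c("E_ib", "electronic injection barrier", "eV", "electronic"),
    c("delta", "cohesive energy density", "cal cm-3", "electronic"),
    c("n_c", "refractive index (DFT)", "", "optical & dielectric"),
    c("n_e", "refractive index (exp.)", "", "optical & dielectric"),
    c("k_c", "dielectric constant (DFT)", "", "optical & dielectric"),
    cbind(paste0("k_", c("1.78", "2", "3", "4", "5", "6", "7", "9", "15")),
          paste0("dielectric constant at log10(f/Hz) = ",
                 c("1.78", "2", "3", "4", "5", "6", "7", "9", "15")),
          "", "optical & dielectric"),
    c("E", "Young's modulus", "MPa", "mechanical"),
    c("sigma_y", "tensile strength at yield", "MPa", "mechanical"),
    c("sigma_b", "tensile strength at break", "MPa", "mechanical"),
    c("eps_b", "elongation at break", "", "mechanical"),
    c("mu_O2", "O2 gas permeability", "barrer", "permeability"),
    c("mu_CO2", "CO2 gas permeability", "barrer", "permeability"),
    c("mu_N2", "N2 gas permeability", "barrer", "permeability"),
    c("mu_H2", "H2 gas permeability", "barrer", "permeability"),
    c("mu_He", "He gas permeability", "barrer", "permeability"),
    c("mu_CH4", "CH4 gas permeability", "barrer", "permeability"))
  out <- data.frame(symbol = tab[, 1], name = tab[, 2], unit = tab[, 3],
                    category = tab[, 4], stringsAsFactors = FALSE)
  out$transform <- ifelse(grepl("^mu_", out$symbol) | out$symbol == "eps_b",
                          "log10p1", "identity")
  out
}

#' Target transform and its inverse
#'
#' Applies the registered target transform for a property symbol:
#' `x -> log10(x + 1)` for flagged properties (which must be non-negative),
#' identity otherwise.  `inverse_transform_target()` inverts it exactly.
#'
#' @param symbol registered property symbol.
#' @param x numeric vector on the native scale.
#' @return Numeric vector on the model (transformed) scale.
#' @export
transform_target <- function(symbol, x) {
  tr <- registry_transform(symbol)
  if (tr == "log10p1") {
    if (any(x < 0, na.rm = TRUE))
      stop("negative value for log10(x+1)-transformed property ", symbol)
    log10(x + 1)
  } else x
}

#' @rdname transform_target
#' @param y numeric vector on the model scale.
#' @export
inverse_transform_target <- function(symbol, y) {
  tr <- registry_transform(symbol)
  if (tr == "log10p1") 10^y - 1 else y
}

registry_transform <- function(symbol) {
  reg <- property_registry()
  i <- match(symbol, reg$symbol)
  if (is.na(i)) stop("unregistered property symbol: ", symbol)
  reg$transform[i]
}

## ---------------------------------------------------------------------------
## Copolymer fingerprints

#' Composition-weighted copolymer fingerprint
#'
#' Combines comonomer fingerprints into a copolymer fingerprint by the
#' composition-weighted sum `F = sum_i c_i F_i`.  Invariant to comonomer
#' order; reduces to the homopolymer fingerprint at `c = 1`.
#'
#' @param fps list of numeric fingerprint vectors (equal length).
#' @param fractions numeric comonomer fractions, positive, summing to 1.
#' @return Numeric fingerprint vector.
#' @examples
#' combine_fingerprints(list(c(1, 0), c(0, 1)), c(0.25, 0.75))
#' @export
combine_fingerprints <- function(fps, fractions) {
  stopifnot(is.list(fps), length(fps) == length(fractions), length(fps) >= 1)
  if (any(fractions <= 0)) stop("comonomer fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("comonomer fractions must sum to 1 (got ", sum(fractions), ")")
  len <- unique(vapply(fps, length, integer(1)))
  if (length(len) != 1) stop("fingerprint lengths differ")
  out <- numeric(len)
  for (i in seq_along(fps)) out <- out + fractions[i] * fps[[i]]
  out
}

#' Fingerprint every record of a property table
#'
#' Computes one fingerprint per table row, caching unique PSMILES and
#' combining copolymers by their composition weights.
#'
#' @param table property table (schema of [synth_properties()]).
#' @param fp_fun function mapping one PSMILES string to a numeric vector
#'   (e.g. [descriptor_fingerprint()] or a [lm_fingerprint()] closure).
#' @return Numeric matrix, one row per record.
#' @export
record_fingerprints <- function(table, fp_fun) {
  uniq <- unique(stats::na.omit(c(table$psmiles_1, table$psmiles_2)))
  cache <- lapply(uniq, fp_fun)
  names(cache) <- uniq
  t(vapply(seq_len(nrow(table)), function(r) {
    if (is.na(table$psmiles_2[r]) || table$psmiles_2[r] == "") {
      cache[[table$psmiles_1[r]]]
    } else {
      combine_fingerprints(list(cache[[table$psmiles_1[r]]],
                                cache[[table$psmiles_2[r]]]),
                           c(table$c_1[r], table$c_2[r]))
    }
  }, numeric(length(cache[[1]]))))
}

## ---------------------------------------------------------------------------
## Splits

#' Stratified meta-train / cross-validation split plan
#'
#' Shuffles the table with the given seed, then assigns 20% of the records
#' to the meta-learner training set and partitions the remaining 80% into
#' `n_folds` disjoint cross-validation folds.  Assignment is stratified per
#' property by 10-quantile bins of the (transformed) target so every fold
#' sees the full value range of every property.
#'
#' @param table property table (schema of [synth_properties()]).
#' @param seed integer seed.
#' @param n_folds number of folds (default 5).
#' @param meta_frac fraction held out for the meta learner (default 0.2).
#' @return A `split_plan`: list with `meta_train` (row indices), `folds`
#'   (list of row-index vectors), and `strata` (per-row labels).
#' @export
make_splits <- function(table, seed = 1L, n_folds = 5L, meta_frac = 0.2) {
  stopifnot(nrow(table) >= 1)
  tvals <- vapply(seq_len(nrow(table)), function(r)
    transform_target(table$property[r], table$value[r]), numeric(1))
  strata <- character(nrow(table))
  for (p in unique(table$property)) {
    idx <- which(table$property == p)
    if (length(idx) < n_folds)
      warning("property ", p, " has fewer records (", length(idx),
              ") than folds; records assigned anyway")
    qs <- unique(stats::quantile(tvals[idx], probs = seq(0, 1, length.out = 11)))
    bin <- if (length(qs) > 2)
      cut(tvals[idx], breaks = qs, include.lowest = TRUE, labels = FALSE)
    else rep(1L, length(idx))
    strata[idx] <- paste0(p, ".", bin)
  }
  meta_train <- integer(0)
  folds <- rep(list(integer(0)), n_folds)
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      n_meta <- round(meta_frac * length(idx))
      meta_train <- c(meta_train, idx[seq_len(n_meta)])
      rest <- idx[setdiff(seq_along(idx), seq_len(n_meta))]
      if (length(rest))
        for (k in seq_along(rest)) {
          f <- (k - 1L) %% n_folds + 1L
          folds[[f]] <- c(folds[[f]], rest[k])
        }
    }
  })
  structure(list(meta_train = sort(meta_train),
                 folds = lapply(folds, sort),
                 strata = strata),
            class = "split_plan")
}

## ---------------------------------------------------------------------------
## Multitask ensemble

onehot_property <- function(property, symbols) {
  m <- matrix(0, length(property), length(symbols),
              dimnames = list(NULL, symbols))
  m[cbind(seq_along(property), match(property, symbols))] <- 1
  m
}

## Design matrix: fingerprint concatenated with the one-hot selector.
mt_design <- function(fps, property, symbols) {
  cbind(fps, onehot_property(property, symbols))
}

fit_one_net <- function(x, y, config) {
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  fit <- nnet::nnet(xs, y, size = config$hidden, linout = TRUE,
                    decay = config$decay, maxit = config$maxit,
                    skip = TRUE, trace = FALSE, MaxNWts = 100000)
  list(fit = fit, center = ctr, scale = scl)
}

predict_one_net <- function(net, x) {
  as.numeric(stats::predict(net$fit, scale(x, net$center, net$scale)))
}

#' Default configuration for the multitask networks
#'
#' @param hidden hidden units of each fold network.
#' @param maxit BFGS iterations.
#' @param decay weight decay.
#' @param meta_hidden hidden units of the meta learner (`0` = linear
#'   stacking).
#' @param meta_decay weight decay of the meta learner.  The stacking net
#'   sees only a handful of meta-training rows for sparsely observed
#'   properties, so it is regularized much harder than the fold networks
#'   to keep its property-specific corrections shrunk toward the ensemble
#'   consensus.
#' @return Config list.
#' @export
multitask_config <- function(hidden = 16L, maxit = 600L, decay = 1e-4,
                             meta_hidden = 4L, meta_decay = 1e-2) {
  list(hidden = hidden, maxit = maxit, decay = decay,
       meta_hidden = meta_hidden, meta_decay = meta_decay)
}

#' Train the five-fold multitask ensemble
#'
#' Trains one selector-conditioned multitask network per cross-validation
#' fold on the other folds' records, minimizing mean squared error on
#' standardized transformed targets.  Target standardization is fit on each
#' model's own training folds only.
#'
#' @param plan a `split_plan` from [make_splits()].
#' @param fps matrix of per-record fingerprints (rows align with `table`).
#' @param table property table.
#' @param config from [multitask_config()].
#' @param seed integer seed (network initialization).
#' @return A `multitask_ensemble`: fold models, per-property scalers, the
#'   property symbols, and per-fold validation R^2 on the transformed scale.
#' @export
train_ensemble <- function(plan, fps, table, config = multitask_config(),
                           seed = 1L) {
  symbols <- sort(unique(table$property))
  tvals <- vapply(seq_len(nrow(table)), function(r)
    transform_target(table$property[r], table$value[r]), numeric(1))
  X <- mt_design(fps, table$property, symbols)
  models <- vector("list", length(plan$folds))
  fold_r2 <- matrix(NA_real_, length(plan$folds), length(symbols),
                    dimnames = list(NULL, symbols))
  for (f in seq_along(plan$folds)) {
    tr <- sort(unlist(plan$folds[-f]))
    va <- plan$folds[[f]]
    ## pooled within-property sd backs a shrinkage prior: a target scale
    ## estimated from a handful of rows of a sparse property would
    ## otherwise distort the shared loss for every task
    pooled_var <- mean(vapply(symbols, function(p) {
      i <- tr[table$property[tr] == p]
      if (length(i) > 1) stats::var(tvals[i]) else NA_real_
    }, numeric(1)), na.rm = TRUE)
    sc <- lapply(symbols, function(p) {
      i <- tr[table$property[tr] == p]
      n <- length(i)
      mu <- if (n) mean(tvals[i]) else 0
      v <- if (n > 1) stats::var(tvals[i]) else pooled_var
      ## guard only the degenerate cases: with fewer than ~9 rows a raw
      ## variance estimate can be off by an order of magnitude
      if (n - 1 < 8)
        v <- (max(n - 1, 0) * v + 8 * pooled_var) / (max(n - 1, 0) + 8)
      c(mu = mu, sd = if (is.na(v) || v == 0) 1 else sqrt(v))
    })
    names(sc) <- symbols
    y <- (tvals - vapply(table$property, function(p) sc[[p]]["mu"], numeric(1))) /
      vapply(table$property, function(p) sc[[p]]["sd"], numeric(1))
    with_seed(seed + f, {
      net <- fit_one_net(X[tr, , drop = FALSE], y[tr], config)
    })
    models[[f]] <- list(net = net, scalers = sc)
    if (length(va)) {
      pv <- predict_one_net(net, X[va, , drop = FALSE])
      for (p in symbols) {
        i <- which(table$property[va] == p)
        if (length(i) > 1) {
          yt <- tvals[va][i]
          ph <- pv[i] * sc[[p]]["sd"] + sc[[p]]["mu"]
          fold_r2[f, p] <- 1 - sum((yt - ph)^2) / sum((yt - mean(yt))^2)
        }
      }
    }
  }
  structure(list(models = models, symbols = symbols, config = config,
                 fp_dim = ncol(fps), fold_r2 = fold_r2),
            class = "multitask_ensemble")
}

## Per-record predictions of all fold models, on the transformed scale.
## Returns an n x 5 matrix.
ensemble_predictions <- function(ens, fps, property) {
  X <- mt_design(fps, property, ens$symbols)
  sapply(ens$models, function(m) {
    raw <- predict_one_net(m$net, X)
    mu <- vapply(property, function(p) m$scalers[[p]]["mu"], numeric(1))
    sd <- vapply(property, function(p) m$scalers[[p]]["sd"], numeric(1))
    raw * sd + mu
  })
}

#' Train the stacking meta learner
#'
#' Fits the stacking model that maps the five fold-model predictions
#' (concatenated with the property selector) to the final transformed
#' target, using the held-out 20% meta-training records; validation R^2 is
#' recorded on the 80% cross-validation portion.
#'
#' @inheritParams train_ensemble
#' @param ensemble a trained `multitask_ensemble`.
#' @return A `meta_learner` with the stacking model and validation R^2.
#' @export
train_meta <- function(ensemble, plan, fps, table,
                       config = multitask_config(), seed = 1L) {
  stopifnot(inherits(ensemble, "multitask_ensemble"))
  tvals <- vapply(seq_len(nrow(table)), function(r)
    transform_target(table$property[r], table$value[r]), numeric(1))
  mt <- plan$meta_train
  if (!length(mt)) stop("split plan has an empty meta-training set")
  P <- ensemble_predictions(ensemble, fps[mt, , drop = FALSE], table$property[mt])
  Xm <- cbind(P, onehot_property(table$property[mt], ensemble$symbols))
  meta_decay <- if (is.null(config$meta_decay)) config$decay else config$meta_decay
  model <- if (config$meta_hidden > 0) {
    with_seed(seed + 1000L, fit_one_net(Xm, tvals[mt],
      list(hidden = config$meta_hidden, decay = meta_decay,
           maxit = config$maxit)))
  } else {
    fit <- stats::lm.fit(cbind(1, Xm), tvals[mt])
    fit$coefficients[is.na(fit$coefficients)] <- 0  # collinear selector cols
    fit
  }
  obj <- structure(list(model = model, linear = config$meta_hidden == 0,
                        symbols = ensemble$symbols),
                   class = "meta_learner")
  cv <- sort(unlist(plan$folds))
  val_r2 <- NULL
  if (length(cv)) {
    ph <- predict_meta(obj, ensemble, fps[cv, , drop = FALSE], table$property[cv])
    val_r2 <- vapply(ensemble$symbols, function(p) {
      i <- which(table$property[cv] == p)
      if (length(i) < 2) return(NA_real_)
      yt <- tvals[cv][i]
      1 - sum((yt - ph[i])^2) / sum((yt - mean(yt))^2)
    }, numeric(1))
  }
  obj$val_r2 <- val_r2
  obj
}

## Meta predictions on the transformed scale.
predict_meta <- function(meta, ensemble, fps, property) {
  P <- ensemble_predictions(ensemble, fps, property)
  Xm <- cbind(P, onehot_property(property, meta$symbols))
  if (meta$linear) {
    as.numeric(cbind(1, Xm) %*% meta$model$coefficients)
  } else {
    predict_one_net(meta$model, Xm)
  }
}

#' Predict properties on the native scale
#'
#' Runs the full prediction path -- fingerprints, five fold models, meta
#' learner, inverse target transform -- for every polymer x property pair.
#'
#' @param meta trained `meta_learner`.
#' @param ensemble trained `multitask_ensemble`.
#' @param polymers character vector of PSMILES strings (homopolymers) or a
#'   precomputed fingerprint matrix.
#' @param symbols property symbols to predict (default: all the ensemble
#'   was trained on).
#' @param fp_fun fingerprint function used when `polymers` is a character
#'   vector.
#' @return Data frame `polymer`, `property`, `prediction` (native units).
#' @export
predict_properties <- function(meta, ensemble, polymers,
                               symbols = ensemble$symbols,
                               fp_fun = descriptor_fingerprint) {
  bad <- setdiff(symbols, ensemble$symbols)
  if (length(bad)) stop("unregistered/untrained property symbol(s): ",
                        paste(bad, collapse = ", "))
  if (is.character(polymers)) {
    fps <- t(vapply(polymers, fp_fun, numeric(ensemble$fp_dim)))
    ids <- polymers
  } else {
    fps <- polymers
    ids <- rownames(fps)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(fps)))
  }
  out <- do.call(rbind, lapply(symbols, function(p) {
    yh <- predict_meta(meta, ensemble, fps, rep(p, nrow(fps)))
    data.frame(polymer = ids, property = p,
               prediction = inverse_transform_target(p, yh),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Min/mean/max screening summary per property
#'
#' @param predictions output of [predict_properties()].
#' @return Data frame with one row per property.
#' @export
summarize_predictions <- function(predictions) {
  do.call(rbind, lapply(split(predictions, predictions$property), function(d)
    data.frame(property = d$property[1], min = min(d$prediction),
               mean = mean(d$prediction), max = max(d$prediction))))
}

## ---------------------------------------------------------------------------
## Evaluation

#' Evaluate predictions against truth
#'
#' Computes per-property R^2 (coefficient of determination) and RMSE --
#' transformed properties are evaluated on the transformed scale -- plus
#' category and overall averages.
#'
#' @param predictions numeric vector of predictions (native units).
#' @param truth numeric vector of true values (native units).
#' @param property character vector of property symbols, aligned.
#' @return An `evaluation_report`: list with `per_property`,
#'   `per_category`, and `overall` components.
#' @examples
#' evaluate_predictions(c(1, 2, 4), c(1, 2, 3), rep("T_g", 3))
#' @export
evaluate_predictions <- function(predictions, truth, property) {
  stopifnot(length(predictions) == length(truth),
            length(truth) == length(property))
  if (!length(truth)) stop("no aligned prediction/truth pairs")
  reg <- property_registry()
  per <- do.call(rbind, lapply(unique(property), function(p) {
    i <- which(property == p)
    yt <- transform_target(p, truth[i])
    yh <- transform_target(p, pmax(predictions[i],
      if (registry_transform(p) == "log10p1") 0 else -Inf))
    data.frame(property = p,
               category = reg$category[match(p, reg$symbol)],
               n = length(i),
               r2 = 1 - sum((yt - yh)^2) / sum((yt - mean(yt))^2),
               rmse = sqrt(mean((yt - yh)^2)),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  cat_avg <- do.call(rbind, lapply(split(per, per$category), function(d)
    data.frame(category = d$category[1], r2 = mean(d$r2), rmse = mean(d$rmse))))
  rownames(cat_avg) <- NULL
  structure(list(per_property = per, per_category = cat_avg,
                 overall = c(r2 = mean(per$r2), rmse = mean(per$rmse))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("per property:\n")
  print(x$per_property, row.names = FALSE)
  cat(sprintf("overall: R2 = %.3f, RMSE = %.4g\n",
              x$overall["r2"], x$overall["rmse"]))
  invisible(x)
}

## Single-task baseline (no selector), used for multitask-benefit checks.
train_single_task <- function(fps, values, symbol, config = multitask_config(),
                              seed = 1L) {
  tv <- transform_target(symbol, values)
  mu <- mean(tv); sd <- stats::sd(tv); if (is.na(sd) || sd == 0) sd <- 1
  with_seed(seed, {
    net <- fit_one_net(as.matrix(fps), (tv - mu) / sd, config)
  })
  structure(list(net = net, mu = mu, sd = sd, symbol = symbol),
            class = "single_task_model")
}

predict_single_task <- function(model, fps) {
  predict_one_net(model$net, as.matrix(fps)) * model$sd + model$mu
}
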