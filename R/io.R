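## File I/O and model persistence: PSMILES list files, the property-table
## CSV schema, run configuration, and save/load for trained models.

#' Read a PSMILES list file
#'
#' One PSMILES string per line; blank lines and lines starting with `#`
#' are skipped.  Every record is validated; invalid lines abort with their
#' line numbers (or are reported when `on_invalid = "report"`).
#'
#' @param path file path.
#' @param on_invalid `"error"` (default) or `"report"`; with `"report"`
#'   the return value carries an `invalid` attribute (data frame of line
#'   numbers and issue codes) and invalid lines are dropped.
#' @return Character vector of valid PSMILES strings.
#' @export
read_psmiles_file <- function(path, on_invalid = c("error", "report")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop("cannot read '", path, "'")
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  vals <- trimws(lines[keep])
  bad <- NULL
  for (i in seq_along(vals)) {
    v <- validate_psmiles(vals[i])
    if (!v$valid)
      bad <- rbind(bad, data.frame(line = keep[i],
                                   issues = paste(v$issues$code, collapse = ";"),
                                   stringsAsFactors = FALSE))
  }
  if (!is.null(bad)) {
    if (on_invalid == "error")
      stop("invalid PSMILES at line(s) ", paste(bad$line, collapse = ", "),
           " of ", path)
    ok <- !(keep %in% bad$line)
    out <- vals[ok]
    attr(out, "invalid") <- bad
    return(out)
  }
  vals
}

#' @rdname read_psmiles_file
#' @param x character vector of PSMILES strings.
#' @param header optional comment header line(s) (written with `#`).
#' @export
write_psmiles_file <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines(x, con)
  invisible(path)
}

PROPERTY_CSV_COLS <- c("psmiles_1", "psmiles_2", "c_1", "c_2", "property",
                       "value")

#' Read / write a property table CSV
#'
#' Schema: `psmiles_1, psmiles_2, c_1, c_2, property, value`.  Homopolymer
#' rows leave `psmiles_2`/`c_2` blank and must have `c_1 = 1`; copolymer
#' fractions must be positive and sum to 1; property symbols must be
#' registered.  `write_property_csv()` followed by `read_property_csv()`
#' is the identity up to float formatting.
#'
#' @param path file path.
#' @return Data frame in the schema above.
#' @export
read_property_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(psmiles_1 = "character",
                                       psmiles_2 = "character"))
  if (!identical(names(df), PROPERTY_CSV_COLS))
    stop("property CSV header must be: ",
         paste(PROPERTY_CSV_COLS, collapse = ","))
  df$psmiles_2[!nzchar(df$psmiles_2)] <- NA_character_
  reg <- property_registry()
  bad <- setdiff(unique(df$property), reg$symbol)
  if (length(bad))
    stop("unregistered property symbol(s): ", paste(bad, collapse = ", "))
  homo <- is.na(df$psmiles_2)
  if (any(homo & abs(df$c_1 - 1) > 1e-8))
    stop("homopolymer rows must have c_1 = 1 (rows ",
         paste(which(homo & abs(df$c_1 - 1) > 1e-8), collapse = ", "), ")")
  co <- !homo
  if (any(co)) {
    s <- df$c_1[co] + df$c_2[co]
    if (any(is.na(s)) || any(abs(s - 1) > 1e-8) ||
        any(df$c_1[co] <= 0) || any(df$c_2[co] <= 0))
      stop("copolymer fractions must be positive and sum to 1 (rows ",
           paste(which(co)[is.na(s) | abs(s - 1) > 1e-8], collapse = ", "), ")")
  }
  for (p in unique(df$psmiles_1)) {
    if (!validate_psmiles(p)$valid) stop("invalid PSMILES in table: ", p)
  }
  for (p in unique(stats::na.omit(df$psmiles_2))) {
    if (!validate_psmiles(p)$valid) stop("invalid PSMILES in table: ", p)
  }
  df
}

#' @rdname read_property_csv
#' @param records data frame in the property-table schema.
#' @export
write_property_csv <- function(records, path) {
  df <- records[, PROPERTY_CSV_COLS]
  df$psmiles_2[is.na(df$psmiles_2)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Run configuration

#' Read a run configuration file (YAML)
#'
#' @param path YAML file with optional blocks `lm`, `multitask`,
#'   `generator`, and a global `seed`.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

#' Write the resolved run configuration next to an output
#'
#' @param cfg named list.
#' @param path output YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Model persistence

#' Save / load a trained language model
#'
#' The model directory holds the architecture and training configuration
#' (`config.json`), the vocabulary (`vocab.txt`), the weights
#' (`weights.rds`), and the training metrics (`metrics.json`).  A loaded
#' model reproduces fingerprints bitwise.
#'
#' @param model a `polymer_lm`.
#' @param dir directory (created if missing).
#' @export
save_lm <- function(model, dir) {
  stopifnot(inherits(model, "polymer_lm"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$config
  cfg$target_f1 <- if (is.null(cfg$target_f1)) NA else cfg$target_f1
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  writeLines(unclass(model$vocab), file.path(dir, "vocab.txt"))
  saveRDS(tf_get_weights(model$ptr), file.path(dir, "weights.rds"))
  jsonlite::write_json(model$metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_lm
#' @export
load_lm <- function(dir) {
  if (!dir.exists(dir)) stop("model directory not found: ", dir)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  if (!length(cfg$target_f1) || is.na(cfg$target_f1[1])) cfg$target_f1 <- NULL
  vocab <- structure(readLines(file.path(dir, "vocab.txt")),
                     class = "psmiles_vocab")
  model <- lm_init(vocab, cfg, seed = 0L)
  ws <- readRDS(file.path(dir, "weights.rds"))
  tf_set_weights(model$ptr, ws)
  mfile <- file.path(dir, "metrics.json")
  if (file.exists(mfile)) {
    model$metrics <- jsonlite::read_json(mfile, simplifyVector = TRUE)
    model$trained <- TRUE
  }
  model
}

#' Save / load a trained property-prediction run
#'
#' A run directory bundles the multitask ensemble, the meta learner, the
#' split plan, and the fingerprint type used at training time.
#'
#' @param ensemble a `multitask_ensemble`.
#' @param meta a `meta_learner`.
#' @param plan the `split_plan`.
#' @param dir directory.
#' @param fp_type fingerprint used at training (`"descriptor"` or a
#'   language-model directory path).
#' @export
save_run <- function(ensemble, meta, plan, dir, fp_type = "descriptor") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(ensemble = ensemble, meta = meta, plan = plan,
               fp_type = fp_type), file.path(dir, "run.rds"))
  jsonlite::write_json(
    list(symbols = ensemble$symbols, fp_dim = ensemble$fp_dim,
         fp_type = fp_type, fold_r2 = as.data.frame(ensemble$fold_r2),
         meta_val_r2 = as.list(meta$val_r2)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_run
#' @export
load_run <- function(dir) {
  f <- file.path(dir, "run.rds")
  if (!file.exists(f)) stop("run directory not found or incomplete: ", dir)
  readRDS(f)
}
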