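## Chemical language model: vocabulary, tokenizer, masking, masked-LM
## training, fingerprint pooling, and encoder introspection.

AUX_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]", "_")

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

SPECIAL_TOKENS <- c("[*]", "(", ")", "[", "]", "=", "#", "-", "+", ":",
                    "/", "\\", "%")

#' Build the PSMILES token vocabulary
#'
#' A fixed, deterministic vocabulary covering every character class of
#' canonical PSMILES strings: the five auxiliary tokens plus the word-start
#' marker `_`, the uppercased and lowercased symbols of the 118 elements,
#' digits 0-9, and the SMILES special characters including `[*]`.  With the
#' defaults the vocabulary has 265 tokens.
#'
#' @return Character vector of class `psmiles_vocab`; token ids are the
#'   positions in the vector.
#' @examples
#' v <- build_vocab()
#' length(v)
#' @export
build_vocab <- function() {
  toks <- c(AUX_TOKENS, ELEMENT_SYMBOLS, tolower(ELEMENT_SYMBOLS),
            as.character(0:9), SPECIAL_TOKENS)
  stopifnot(!anyDuplicated(toks))
  structure(toks, class = "psmiles_vocab")
}

vocab_id <- function(vocab, token) {
  i <- match(token, vocab)
  ifelse(is.na(i), match("[UNK]", vocab), i)
}

#' Tokenize a canonical PSMILES string
#'
#' Greedy longest-match segmentation against the vocabulary, wrapped in
#' `[CLS] _ ... [SEP]`.  Unknown characters map to `[UNK]`; concatenating
#' the interior tokens reproduces the input exactly (when no `[UNK]`
#' fired).  Fingerprints depend on the writing of the string, so `p` should
#' be canonical (see [canonicalize_psmiles()]).
#'
#' @param vocab a `psmiles_vocab`.
#' @param p canonical PSMILES string.
#' @return A `token_sequence`: list with `ids` (integer), `tokens`
#'   (character), and `attention_mask` (all 1; kept for the sequence
#'   contract).
#' @examples
#' tokenize_psmiles(build_vocab(), "[*]COC[*]")$tokens
#' @export
tokenize_psmiles <- function(vocab, p) {
  stopifnot(inherits(vocab, "psmiles_vocab"), is.character(p), length(p) == 1)
  toks <- character()
  i <- 1L
  n <- nchar(p)
  maxlen <- 3L  # longest surface token is "[*]"
  while (i <= n) {
    hit <- NULL
    for (w in rev(seq_len(min(maxlen, n - i + 1L)))) {
      cand <- substr(p, i, i + w - 1L)
      if (cand %in% AUX_TOKENS) next  # auxiliary tokens never match surface
      if (!is.na(match(cand, vocab))) { hit <- cand; break }
    }
    if (is.null(hit)) {
      toks <- c(toks, "[UNK]")
      i <- i + 1L
    } else {
      toks <- c(toks, hit)
      i <- i + nchar(hit)
    }
  }
  tokens <- c("[CLS]", "_", toks, "[SEP]")
  structure(list(ids = vocab_id(vocab, tokens), tokens = tokens,
                 attention_mask = rep(1L, length(tokens))),
            class = "token_sequence")
}

#' @rdname tokenize_psmiles
#' @param seq a `token_sequence`.
#' @return `detokenize()`: the interior surface string.
#' @export
detokenize <- function(seq) {
  toks <- seq$tokens
  paste(toks[!(toks %in% AUX_TOKENS)], collapse = "")
}

#' Mask tokens for the fill-in-the-blanks task
#'
#' Selects `ceiling(rate * n_interior)` non-auxiliary positions; of the
#' selected positions 80% are replaced by `[MASK]`, 10% by a random
#' vocabulary token, and 10% left unchanged.  Seeded and reproducible.
#'
#' @param vocab a `psmiles_vocab`.
#' @param seq a `token_sequence`.
#' @param rate masking rate (default 0.15).
#' @param seed integer seed.
#' @return List with `ids` (masked id vector) and `labels` (0 everywhere
#'   except the selected positions, which carry the original token id).
#' @export
mask_tokens <- function(vocab, seq, rate = 0.15, seed = 1L) {
  aux_ids <- match(AUX_TOKENS, vocab)
  interior <- which(!(seq$ids %in% aux_ids))
  if (!length(interior)) stop("sequence has no maskable positions")
  n_mask <- min(length(interior), ceiling(rate * length(interior)))
  mask_id <- match("[MASK]", vocab)
  candidates <- seq_along(vocab)[-aux_ids]  # any non-auxiliary token
  with_seed(seed, {
    sel <- sort(sample(interior, n_mask))
    u <- stats::runif(n_mask)
    ids <- seq$ids
    labels <- integer(length(ids))
    labels[sel] <- ids[sel]
    repl <- ids[sel]
    repl[u < 0.8] <- mask_id
    rnd <- which(u >= 0.8 & u < 0.9)
    if (length(rnd)) repl[rnd] <- sample(candidates, length(rnd), replace = TRUE)
    ids[sel] <- repl
    list(ids = ids, labels = labels)
  })
}

## ---------------------------------------------------------------------------
## Model object and training

#' Configuration of the language-model encoder
#'
#' The `mini` preset (2 layers, 4 heads, width 64) is sized so that masked
#' language model training on tens of thousands of short PSMILES strings
#' completes in minutes on one CPU core; the `paper` preset mirrors the
#' published scale (12 layers, 12 heads, width 600) and is provided as a
#' configuration only.
#'
#' @param preset `"mini"` or `"paper"`.
#' @param d_model,n_heads,n_layers,d_ff,max_len architecture overrides.
#' @param lr,batch_size,epochs,rate training parameters (Adam learning
#'   rate, sequences per batch, maximal epochs, masking rate).
#' @param target_f1 stop early once the held-out masked-token F1 reaches
#'   this value (`NULL` to disable).
#' @return Config list.
#' @export
lm_config <- function(preset = c("mini", "paper"), d_model = NULL,
                      n_heads = NULL, n_layers = NULL, d_ff = NULL,
                      max_len = 160L, lr = 2e-3, lr_decay = 1,
                      batch_size = 32L, epochs = 30L, rate = 0.15,
                      target_f1 = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    mini = list(d_model = 64L, n_heads = 4L, n_layers = 2L),
    paper = list(d_model = 600L, n_heads = 12L, n_layers = 12L))
  d_model <- if (is.null(d_model)) def$d_model else d_model
  n_heads <- if (is.null(n_heads)) def$n_heads else n_heads
  n_layers <- if (is.null(n_layers)) def$n_layers else n_layers
  d_ff <- if (is.null(d_ff)) 4L * d_model else d_ff
  list(preset = preset, d_model = as.integer(d_model),
       n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
       d_ff = as.integer(d_ff), max_len = as.integer(max_len),
       lr = lr, lr_decay = lr_decay, batch_size = as.integer(batch_size),
       epochs = as.integer(epochs), rate = rate, target_f1 = target_f1)
}

## Fresh encoder with seeded normal(0, 0.02) initialization.
lm_init <- function(vocab, config, seed = 1L) {
  ptr <- tf_new(length(vocab), config$d_model, config$n_heads,
                config$n_layers, config$d_ff, config$max_len)
  ws <- tf_get_weights(ptr)
  with_seed(seed + 7L, {
    for (i in seq_along(ws)) {
      w <- ws[[i]]
      ## weight matrices get normal(0, 0.02); biases and layer-norm
      ## parameters (single-row slots) keep their 0/1 defaults
      if (nrow(w) > 1L && all(w == 0)) {
        ws[[i]] <- matrix(stats::rnorm(length(w), sd = 0.02),
                          nrow(w), ncol(w))
      }
    }
  })
  attr(ws, "step") <- 0
  tf_set_weights(ptr, ws)
  structure(list(ptr = ptr, vocab = vocab, config = config,
                 init_seed = as.integer(seed), metrics = NULL,
                 trained = FALSE),
            class = "polymer_lm")
}

#' @export
print.polymer_lm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "polymer language model: %d layers x %d heads, width %d (ff %d), vocab %d%s\n",
    cfg$n_layers, cfg$n_heads, cfg$d_model, cfg$d_ff, length(x$vocab),
    if (x$trained) sprintf("; trained, validation F1 = %.4f",
                           utils::tail(x$metrics$val_f1, 1)) else "; untrained"))
  invisible(x)
}

## Tokenize a corpus once; returns list of id vectors.
corpus_ids <- function(vocab, corpus) {
  lapply(corpus, function(p) tokenize_psmiles(vocab, p)$ids)
}

#' Train the masked language model
#'
#' Canonical PSMILES strings are tokenized, split 80/20 into training and
#' validation sets, and the encoder is trained to predict masked tokens
#' from their context (cross-entropy on the masked positions, Adam, fresh
#' masks every epoch).  The held-out micro-averaged masked-token F1 --
#' with exactly one label per masked position this equals the masked-token
#' accuracy -- is evaluated after every epoch on a fixed validation
#' masking.
#'
#' @param corpus character vector of canonical PSMILES strings (they are
#'   canonicalized here if `canonicalize = TRUE`).
#' @param config from [lm_config()].
#' @param seed integer master seed (controls init, shuffling, masking).
#' @param canonicalize canonicalize the corpus first (default `TRUE`).
#' @param quiet suppress per-epoch progress lines.
#' @return A trained `polymer_lm`; `$metrics` holds per-epoch training
#'   loss and validation F1/loss.
#' @export
train_mlm <- function(corpus, config = lm_config(), seed = 1L,
                      canonicalize = TRUE, quiet = FALSE) {
  stopifnot(length(corpus) >= 10)
  if (canonicalize)
    corpus <- vapply(corpus, canonicalize_psmiles, character(1),
                     USE.NAMES = FALSE)
  vocab <- build_vocab()
  model <- lm_init(vocab, config, seed)
  ids <- corpus_ids(vocab, corpus)
  n <- length(ids)
  with_seed(seed + 13L, {
    ord <- sample(n)
  })
  n_train <- floor(0.8 * n)
  train_ids <- ids[ord[seq_len(n_train)]]
  val_ids <- ids[ord[seq(n_train + 1L, n)]]
  ## fixed validation masking so F1 is comparable across epochs
  val_masked <- lapply(seq_along(val_ids), function(i)
    mask_tokens(vocab, list(ids = val_ids[[i]]), rate = config$rate,
                seed = seed * 1000L + i))
  hist <- list(train_loss = numeric(), val_loss = numeric(),
               val_f1 = numeric())
  batch_seed <- seed
  lr <- config$lr
  decay <- if (is.null(config$lr_decay)) 1 else config$lr_decay
  for (ep in seq_len(config$epochs)) {
    with_seed(seed + 100L + ep, {
      ord_ep <- sample(n_train)
    })
    ep_loss <- 0; ep_n <- 0
    bs <- config$batch_size
    starts <- seq(1L, n_train, by = bs)
    for (s in starts) {
      take <- ord_ep[s:min(s + bs - 1L, n_train)]
      batch_seed <- batch_seed + 1L
      masked <- lapply(seq_along(take), function(i)
        mask_tokens(vocab, list(ids = train_ids[[take[i]]]),
                    rate = config$rate, seed = batch_seed * 131L + i))
      res <- tf_train_batch(model$ptr,
                            lapply(masked, `[[`, "ids"),
                            lapply(masked, `[[`, "labels"), lr)
      ep_loss <- ep_loss + res$loss * res$n
      ep_n <- ep_n + res$n
    }
    ev <- tf_eval_batch(model$ptr,
                        lapply(val_masked, `[[`, "ids"),
                        lapply(val_masked, `[[`, "labels"))
    f1 <- ev$correct / ev$n
    hist$train_loss <- c(hist$train_loss, ep_loss / ep_n)
    hist$val_loss <- c(hist$val_loss, ev$loss)
    hist$val_f1 <- c(hist$val_f1, f1)
    if (!quiet)
      message(sprintf("epoch %2d  train loss %.4f  val loss %.4f  val F1 %.4f",
                      ep, ep_loss / ep_n, ev$loss, f1))
    if (!is.null(config$target_f1) && f1 >= config$target_f1) break
    lr <- lr * decay
  }
  model$metrics <- hist
  model$trained <- TRUE
  model
}

## ---------------------------------------------------------------------------
## Fingerprints and introspection

#' Language-model polymer fingerprint
#'
#' Canonicalize, tokenize, encode, and average the final-layer token
#' latents over all (non-padding) positions, auxiliary tokens included --
#' the sentence-average pooling convention.  Deterministic for fixed
#' weights; identical for every rewriting of the same polymer because
#' canonicalization precedes encoding.
#'
#' @param model a `polymer_lm`.
#' @param p valid PSMILES string.
#' @return Numeric vector of length `d_model`.
#' @export
lm_fingerprint <- function(model, p) {
  stopifnot(inherits(model, "polymer_lm"))
  seq <- tokenize_psmiles(model$vocab, canonicalize_psmiles(p))
  h <- tf_encode(model$ptr, seq$ids)
  colMeans(h)
}

#' Cosine distance between two fingerprint vectors
#'
#' @param a,b numeric vectors.
#' @return `1 - cos(a, b)`.
#' @export
cosine_distance <- function(a, b) {
  1 - sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

#' Aggregated attention map of a polymer
#'
#' Element-wise sum of the attention maps over all heads and all encoder
#' layers, normalized by the matrix maximum; rows/columns follow the token
#' sequence including the auxiliary `[CLS]`, `_`, `[SEP]` tokens.
#'
#' @param model a `polymer_lm`.
#' @param p valid PSMILES string.
#' @return Square numeric matrix with token labels as dimnames, entries in
#'   `[0, 1]`.
#' @export
attention_summary <- function(model, p) {
  stopifnot(inherits(model, "polymer_lm"))
  seq <- tokenize_psmiles(model$vocab, canonicalize_psmiles(p))
  at <- tf_attention(model$ptr, seq$ids)
  T <- length(seq$ids)
  agg <- matrix(0, T, T)
  for (l in seq_along(at)) {
    cu <- at[[l]]
    for (h in seq_len(dim(cu)[3])) agg <- agg + cu[, , h]
  }
  agg <- agg / max(agg)
  dimnames(agg) <- list(seq$tokens, seq$tokens)
  agg
}

#' Raw per-layer, per-head attention maps
#'
#' @inheritParams attention_summary
#' @return List (one per layer) of `T x T x H` arrays; every row of every
#'   head slice sums to 1.
#' @export
attention_maps <- function(model, p) {
  stopifnot(inherits(model, "polymer_lm"))
  seq <- tokenize_psmiles(model$vocab, canonicalize_psmiles(p))
  tf_attention(model$ptr, seq$ids)
}

#' Non-negative factorization of feed-forward activations
#'
#' Collects the ReLU activations of the feed-forward layers (token x
#' neuron, layers concatenated) and factorizes them into `k` non-negative
#' components by seeded multiplicative updates.  Component loadings show
#' which sets of neurons fire for which tokens.
#'
#' @param model a `polymer_lm`.
#' @param p valid PSMILES string.
#' @param k number of components (default 4).
#' @param seed integer seed for the factorization init.
#' @return List with `basis` (token x k, rownames = tokens), `coef`
#'   (k x neuron), and the relative reconstruction error `rel_err`.
#' @export
ffn_activation_nmf <- function(model, p, k = 4L, seed = 1L) {
  stopifnot(inherits(model, "polymer_lm"))
  seq <- tokenize_psmiles(model$vocab, canonicalize_psmiles(p))
  acts <- tf_ffn_activations(model$ptr, seq$ids)
  acts[acts < 0] <- 0  # ReLU output is already non-negative; belt and braces
  if (k > min(dim(acts)))
    stop("k exceeds the activation matrix rank bound")
  fit <- nmf_factorize(acts, k, seed = seed)
  rownames(fit$basis) <- seq$tokens
  fit
}

## Multiplicative-update NMF (Lee-Seung, Frobenius loss), seeded init.
nmf_factorize <- function(X, k, seed = 1L, n_iter = 200L, eps = 1e-9) {
  stopifnot(all(X >= 0))
  n <- nrow(X); m <- ncol(X)
  with_seed(seed, {
    W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
    H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  })
  for (it in seq_len(n_iter)) {
    H <- H * (t(W) %*% X) / (t(W) %*% W %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% H %*% t(H) + eps)
  }
  rec <- W %*% H
  list(basis = W, coef = H,
       rel_err = norm(X - rec, "F") / max(norm(X, "F"), eps))
}
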