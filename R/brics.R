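## Retrosynthetic fragmentation and recombination of polymer repeat units,
## following the published BRICS bond-cleavage rule set: 16 link-class
## environments and a pairing matrix that governs which fragment ends may
## be rejoined.  Environments are implemented as predicates on the package
## molecular graph.  Polymer endpoint markers are univalent "*" atoms that
## match no environment, so cleavage rules can never fire on them -- they
## ride along as protected chain-continuation links (class 0) and are
## restored as plain [*] endpoints after recombination.

## ---------------------------------------------------------------------------
## Link-class environments

brics_env_table <- function(mol) {
  n <- n_atoms(mol)
  el <- mol$atoms$element
  ar <- mol$atoms$aromatic
  chg <- mol$atoms$charge
  b <- mol$bonds
  deg <- tabulate(c(b$a1, b$a2), n)
  cyc <- cycle_bond_rows(mol)
  in_ring_bond <- logical(n_bonds(mol)); in_ring_bond[cyc] <- TRUE
  nbrows <- vector("list", n)
  for (r in seq_len(n_bonds(mol))) {
    nbrows[[b$a1[r]]] <- c(nbrows[[b$a1[r]]], r)
    nbrows[[b$a2[r]]] <- c(nbrows[[b$a2[r]]], r)
  }
  other <- function(r, v) if (b$a1[r] == v) b$a2[r] else b$a1[r]
  in_ring_atom <- logical(n)
  in_ring_atom[unique(c(b$a1[cyc], b$a2[cyc]))] <- TRUE

  ## per-atom neighbor summaries
  info <- lapply(seq_len(n), function(v) {
    rows <- nbrows[[v]]
    ws <- vapply(rows, other, integer(1), v = v)
    list(rows = rows, ws = ws, ords = b$order[rows], ring = in_ring_bond[rows])
  })
  has_dbl_O <- vapply(seq_len(n), function(v) {
    i <- info[[v]]
    any(i$ords == 2 & el[i$ws] == "O" & !ar[i$ws])
  }, logical(1))
  has_multiple <- vapply(seq_len(n), function(v)
    any(info[[v]]$ords %in% c(2, 3)), logical(1))

  envs <- matrix(FALSE, n, 16)
  for (v in seq_len(n)) {
    i <- info[[v]]
    if (el[v] == "*") next
    aliph <- !ar[v]
    nb_el <- el[i$ws]
    if (el[v] == "C" && aliph) {
      carbonyl <- deg[v] == 3 && has_dbl_O[v] &&
        any(nb_el %in% c("*", "C", "N", "O"))
      envs[v, 1] <- carbonyl
      envs[v, 6] <- carbonyl && !in_ring_atom[v]
      envs[v, 4] <- deg[v] >= 2 && !any(i$ords == 2) &&
        any(nb_el == "C" & i$ords == 1 & !i$ring)
      envs[v, 7] <- deg[v] %in% c(2, 3) && any(nb_el == "C" & i$ords == 2)
      envs[v, 8] <- !in_ring_atom[v] && deg[v] >= 2 && !has_multiple[v]
      envs[v, 13] <- in_ring_atom[v] &&
        any(nb_el %in% c("C", "N", "O", "S") & i$ords == 1 & i$ring) &&
        any(nb_el %in% c("N", "O", "S") & i$ords == 1 & i$ring)
      envs[v, 15] <- in_ring_atom[v] &&
        sum(nb_el == "C" & !ar[i$ws] & i$ords == 1 & i$ring) >= 2
    }
    if (el[v] == "C" && ar[v]) {
      arom_nb <- i$ords == 1.5
      envs[v, 14] <- any(arom_nb & el[i$ws] %in% c("N", "O", "S") & ar[i$ws]) &&
        sum(arom_nb & el[i$ws] %in% c("C", "N", "O", "S")) >= 2
      envs[v, 16] <- sum(arom_nb & el[i$ws] == "C" & ar[i$ws]) >= 2
    }
    if (el[v] == "O" && !ar[v]) {
      envs[v, 3] <- deg[v] == 2 &&
        any(nb_el %in% c("*", "C") & i$ords == 1 & !i$ring)
    }
    if (el[v] == "N") {
      if (!ar[v]) {
        amide_ring_N <- in_ring_atom[v] &&
          any(el[i$ws] == "C" & i$ring & has_dbl_O[i$ws])
        envs[v, 5] <- deg[v] >= 2 && !any(i$ords == 2) &&
          all(nb_el %in% c("*", "C", "S")) && !amide_ring_N
        envs[v, 10] <- amide_ring_N &&
          sum(i$ring & el[i$ws] %in% c("C", "N", "O", "S")) >= 2
      } else {
        envs[v, 9] <- chg[v] == 0L &&
          sum(i$ords == 1.5 & el[i$ws] %in% c("C", "N", "O", "S")) >= 2
      }
    }
    if (el[v] == "S" && !ar[v]) {
      envs[v, 11] <- deg[v] == 2 && any(nb_el %in% c("*", "C") & i$ords == 1)
      envs[v, 12] <- deg[v] == 4 && sum(i$ords == 2 & el[i$ws] == "O") == 2 &&
        any(nb_el %in% c("*", "C"))
    }
  }
  envs
}

## Pairing matrix: which link classes may be joined, and with which bond
## order (7-7 junctions are double bonds, everything else single).
brics_pairs <- function() {
  p <- rbind(
    c(1, 3), c(1, 5), c(1, 10),
    c(3, 4), c(3, 13), c(3, 14), c(3, 15), c(3, 16),
    c(4, 5), c(4, 11),
    c(5, 12), c(5, 13), c(5, 14), c(5, 15), c(5, 16),
    c(6, 13), c(6, 14), c(6, 15), c(6, 16),
    c(7, 7),
    c(8, 9), c(8, 10), c(8, 13), c(8, 14), c(8, 15), c(8, 16),
    c(9, 13), c(9, 14), c(9, 15), c(9, 16),
    c(10, 13), c(10, 14), c(10, 15), c(10, 16),
    c(11, 13), c(11, 14), c(11, 15), c(11, 16),
    c(13, 14), c(13, 15), c(13, 16),
    c(14, 14), c(14, 15), c(14, 16),
    c(15, 16),
    c(16, 16))
  data.frame(i = p[, 1], j = p[, 2],
             order = ifelse(p[, 1] == 7 & p[, 2] == 7, 2, 1))
}

link_compatible <- function(i, j) {
  if (i == 0L || j == 0L) return(TRUE)
  pr <- brics_pairs()
  any((pr$i == i & pr$j == j) | (pr$i == j & pr$j == i))
}

link_bond_order <- function(i, j) if (i == 7L && j == 7L) 2 else 1

## Cleavable bonds of a molecule: single acyclic bonds whose two atoms
## match a compatible environment pair.  The first matching rule (in
## published rule order) labels the bond.
brics_find_bonds <- function(mol) {
  envs <- brics_env_table(mol)
  cyc <- cycle_bond_rows(mol)
  pr <- brics_pairs()
  out <- NULL
  for (r in seq_len(n_bonds(mol))) {
    if (r %in% cyc) next
    a <- mol$bonds$a1[r]; bb <- mol$bonds$a2[r]
    ord <- mol$bonds$order[r]
    if (mol$atoms$element[a] == "*" || mol$atoms$element[bb] == "*") next
    for (k in seq_len(nrow(pr))) {
      need <- if (pr$order[k] == 2) 2 else 1
      if (ord != need) next
      if (envs[a, pr$i[k]] && envs[bb, pr$j[k]]) {
        out <- rbind(out, c(r, pr$i[k], pr$j[k])); break
      }
      if (envs[bb, pr$i[k]] && envs[a, pr$j[k]]) {
        out <- rbind(out, c(r, pr$j[k], pr$i[k])); break
      }
    }
  }
  if (is.null(out))
    data.frame(row = integer(), lab1 = integer(), lab2 = integer())
  else data.frame(row = out[, 1], lab1 = out[, 2], lab2 = out[, 3])
}

## ---------------------------------------------------------------------------
## Decomposition

## Add a labeled link atom bonded to `anchor`; `pair` marks which cut it
## came from so decompositions can be reassembled exactly.
add_link_atom <- function(mol, anchor, class, pair = NA_integer_) {
  mol <- add_atom(mol, "*", isotope = if (class == 0L) NA_integer_
                  else as.integer(class))
  if (is.null(mol$atoms$linkpair))
    mol$atoms$linkpair <- rep(NA_integer_, n_atoms(mol) - 1L)
  mol$atoms$linkpair <- c(mol$atoms$linkpair, as.integer(pair))
  add_bond(mol, n_atoms(mol), anchor, 1)
}

#' Decompose a polymer repeat unit into retrosynthetic fragments
#'
#' Applies the published BRICS bond-cleavage rules to the repeat unit of a
#' PSMILES string.  The two `[*]` endpoint markers are protected: no rule
#' can fire on them, and they remain in their fragments as chain-end link
#' points (class 0).  Every cleaved bond leaves a pair of link atoms
#' labeled with the rule's link classes (`[3*]`, `[4*]`, ...).
#'
#' @param p valid PSMILES string.
#' @return A `brics_fragments` object: list of fragments, each with `mol`
#'   (fragment graph), `key` (canonical fragment string), and `link_types`
#'   (sorted link-class labels; 0 = chain end).
#' @examples
#' brics_decompose("[*]CC([*])c1ccccc1")
#' @export
brics_decompose <- function(p) {
  mol <- parse_psmiles(p)
  cuts <- brics_find_bonds(mol)
  work <- mol
  work$atoms$linkpair <- rep(NA_integer_, n_atoms(work))
  if (nrow(cuts)) {
    for (k in seq_len(nrow(cuts))) {
      r <- cuts$row[k]
      a <- mol$bonds$a1[r]; b <- mol$bonds$a2[r]
      work <- add_link_atom(work, a, cuts$lab1[k], pair = k)
      work <- add_link_atom(work, b, cuts$lab2[k], pair = k)
    }
    work <- remove_bonds(work, cuts$row)
  }
  memb <- mol_components(work)
  frags <- lapply(sort(unique(memb)), function(cc) {
    sub <- remove_atoms(work, which(memb != cc))
    st <- star_idx(sub)
    classes <- ifelse(is.na(sub$atoms$isotope[st]), 0L, sub$atoms$isotope[st])
    list(mol = sub, key = canon_smiles(strip_linkpairs(sub)),
         link_types = sort(as.integer(classes)))
  })
  structure(list(fragments = frags, source = p, n_cuts = nrow(cuts)),
            class = "brics_fragments")
}

strip_linkpairs <- function(mol) {
  mol$atoms$linkpair <- NULL
  mol
}

#' @export
print.brics_fragments <- function(x, ...) {
  cat(sprintf("%d BRICS fragment(s) from %s (%d cut bonds):\n",
              length(x$fragments), x$source, x$n_cuts))
  for (f in x$fragments)
    cat("  ", f$key, "  links:", paste(f$link_types, collapse = ","), "\n")
  invisible(x)
}

#' Reassemble BRICS fragments at their cleaved bonds
#'
#' Inverse of [brics_decompose()]: rejoins the fragments at the recorded
#' cut pairs (7-7 junctions as double bonds, all others single) and caps
#' the chain ends as `[*]`.  The result canonicalizes to the canonical
#' form of the decomposed polymer.
#'
#' @param fr a `brics_fragments` object.
#' @return PSMILES string.
#' @export
brics_reassemble <- function(fr) {
  acc <- NULL
  for (f in fr$fragments) {
    acc <- if (is.null(acc)) f$mol else mol_union(acc, f$mol)$mol
  }
  pairs <- unique(stats::na.omit(acc$atoms$linkpair))
  for (pid in pairs) {
    links <- which(!is.na(acc$atoms$linkpair) & acc$atoms$linkpair == pid)
    stopifnot(length(links) == 2L)
    anchors <- vapply(links, function(v) mol_neighbors(acc, v)[1], integer(1))
    classes <- ifelse(is.na(acc$atoms$isotope[links]), 0L,
                      acc$atoms$isotope[links])
    acc <- add_bond(acc, anchors[1], anchors[2],
                    link_bond_order(classes[1], classes[2]))
    acc <- remove_atoms(acc, links)
  }
  st <- star_idx(acc)
  stopifnot(length(st) == 2L)
  write_smiles(strip_linkpairs(acc), start = st[1])
}

## ---------------------------------------------------------------------------
## Fragment library

#' Build a deduplicated fragment library from a polymer corpus
#'
#' Decomposes every corpus member and merges the fragments, deduplicated by
#' canonical fragment string, with occurrence counts.
#'
#' @param corpus non-empty character vector of valid PSMILES strings.
#' @param provenance free-text identifier stored with the library.
#' @return A `fragment_library`: list of unique fragments (`mol`, `key`,
#'   `link_types`, `count`) plus provenance.
#' @export
build_library <- function(corpus, provenance = "corpus") {
  if (!length(corpus)) stop("empty corpus")
  bad <- which(!vapply(corpus, function(p) validate_psmiles(p)$valid, logical(1)))
  if (length(bad))
    stop("invalid corpus member(s) at index: ", paste(bad, collapse = ", "))
  frags <- list()
  for (p in corpus) {
    dec <- brics_decompose(p)
    for (f in dec$fragments) {
      if (!is.null(frags[[f$key]])) {
        frags[[f$key]]$count <- frags[[f$key]]$count + 1L
      } else {
        ## forget which cut each link came from; keep only classes
        m <- f$mol
        m$atoms$linkpair <- NULL
        frags[[f$key]] <- list(mol = m, key = f$key,
                               link_types = f$link_types, count = 1L)
      }
    }
  }
  structure(list(fragments = unname(frags), provenance = provenance),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("fragment library '%s': %d unique fragments\n",
              x$provenance, length(x$fragments)))
  invisible(x)
}

#' Serialize / read a fragment library as a text table
#'
#' @param lib a `fragment_library`.
#' @param path file path.
#' @export
write_library <- function(lib, path) {
  df <- data.frame(
    canonical_key = vapply(lib$fragments, `[[`, character(1), "key"),
    link_types = vapply(lib$fragments, function(f)
      paste(f$link_types, collapse = "+"), character(1)),
    count = vapply(lib$fragments, `[[`, integer(1), "count"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  ## SMILES keys may contain '#' (triple bonds); disable comment/quote
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "")
  frags <- lapply(seq_len(nrow(df)), function(i) {
    mol <- suppressMessages(parse_smiles(df$canonical_key[i]))
    lt <- if (nzchar(as.character(df$link_types[i])))
      as.integer(strsplit(as.character(df$link_types[i]), "+", fixed = TRUE)[[1]])
    else integer()
    list(mol = mol, key = df$canonical_key[i], link_types = lt,
         count = as.integer(df$count[i]))
  })
  structure(list(fragments = frags, provenance = path),
            class = "fragment_library")
}

## ---------------------------------------------------------------------------
## Recombination

## Join chain's open link atom to one link atom of a fragment.
join_at_links <- function(chain, open_link, frag, frag_link) {
  w <- mol_union(chain, frag)
  acc <- w$mol
  fl <- frag_link + w$offset
  a1 <- mol_neighbors(acc, open_link)[1]
  a2 <- mol_neighbors(acc, fl)[1]
  c1 <- acc$atoms$isotope[open_link]; c1 <- if (is.na(c1)) 0L else c1
  c2 <- acc$atoms$isotope[fl]; c2 <- if (is.na(c2)) 0L else c2
  acc <- add_bond(acc, a1, a2, link_bond_order(c1, c2))
  remove_atoms(acc, c(open_link, fl))
}

frag_links <- function(mol) star_idx(mol)

link_class_of <- function(mol, v) {
  iso <- mol$atoms$isotope[v]
  if (is.na(iso)) 0L else as.integer(iso)
}

## Cap all remaining link atoms as plain [*] endpoints.
cap_ends <- function(mol) {
  st <- star_idx(mol)
  mol$atoms$isotope[st] <- NA_integer_
  mol
}

#' Generate hypothetical polymers by recombining library fragments
#'
#' Chains 1 to `max_fragments` two-link fragments, joining them at
#' link-class-compatible points (7-7 junctions as double bonds); the two
#' unsatisfied terminal links become the `[*]` endpoints.  Outputs are
#' validated, canonicalized, and deduplicated.  `random` mode samples
#' fragments uniformly with bounded rejection of incompatible draws;
#' `enumerate` mode walks fragment tuples in deterministic order.
#'
#' @param lib a `fragment_library`.
#' @param n number of hypothetical polymers requested.
#' @param seed integer seed (random mode).
#' @param mode `"random"` or `"enumerate"`.
#' @param max_fragments maximal number of fragments per chain (default 4).
#' @return Character vector of canonical PSMILES strings (length `n`, or
#'   fewer if the library is exhausted; identical seeds give identical
#'   output).
#' @export
combine_fragments <- function(lib, n, seed = 1L,
                              mode = c("random", "enumerate"),
                              max_fragments = 4L) {
  mode <- match.arg(mode)
  usable <- Filter(function(f) length(frag_links(f$mol)) == 2L, lib$fragments)
  if (!length(usable)) stop("library has no two-link fragments")
  assemble <- function(frag_seq, orient) {
    ## frag_seq: indices into usable; orient: which link leads (1 or 2)
    f1 <- usable[[frag_seq[1]]]$mol
    links <- frag_links(f1)
    lead <- links[orient[1]]
    open <- links[3L - orient[1]]
    chain <- f1
    for (t in seq_along(frag_seq)[-1]) {
      fr <- usable[[frag_seq[t]]]$mol
      fl <- frag_links(fr)
      pick <- fl[orient[t]]
      if (!link_compatible(link_class_of(chain, open), link_class_of(fr, pick)))
        return(NULL)
      nxt_open_local <- fl[3L - orient[t]]
      noff <- n_atoms(chain)
      chain <- join_at_links(chain, open, fr, pick)
      ## after join, two atoms (open < pick+noff) were removed; remap
      nxt <- nxt_open_local + noff
      nxt <- nxt - sum(c(open, pick + noff) < nxt)
      open <- nxt
    }
    s <- write_smiles(cap_ends(chain), start = star_idx(chain)[1])
    if (!validate_psmiles(s)$valid) return(NULL)
    tryCatch(canonicalize_psmiles(s), error = function(e) NULL)
  }
  out <- character()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  remember <- function(s) {
    if (!is.null(s) && is.null(seen[[s]])) {
      seen[[s]] <- TRUE
      out <<- c(out, s)
    }
  }
  if (mode == "random") {
    with_seed(seed, {
      attempts <- 0L
      max_attempts <- 60L * n
      while (length(out) < n && attempts < max_attempts) {
        attempts <- attempts + 1L
        m <- sample.int(max_fragments, 1)
        fs <- sample.int(length(usable), m, replace = TRUE)
        orient <- sample.int(2, m, replace = TRUE)
        remember(assemble(fs, orient))
      }
    })
    if (length(out) < n)
      warning("generated only ", length(out), " of ", n,
              " requested polymers before the retry budget ran out")
  } else {
    ## deterministic walk over (fragment, orientation) tuples of growing
    ## length, in mixed-radix order; bounded by a global iteration budget
    base <- 2L * length(usable)
    budget <- 1e6
    tried <- 0
    for (m in seq_len(max_fragments)) {
      total <- base^m
      t <- 0
      while (t < total && tried < budget && length(out) < n) {
        d <- t
        fs <- integer(m); orient <- integer(m)
        for (pos in m:1) {
          digit <- d %% base
          fs[pos] <- digit %/% 2L + 1L
          orient[pos] <- digit %% 2L + 1L
          d <- d %/% base
        }
        remember(assemble(fs, orient))
        t <- t + 1
        tried <- tried + 1
      }
      if (length(out) >= n || tried >= budget) break
    }
  }
  out
}
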