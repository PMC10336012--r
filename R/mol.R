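## Minimal molecular-graph layer for PSMILES strings.
##
## A `polyfp_mol` is a plain list of parallel vectors:
##   atoms: element, aromatic, charge, hcount (NA = implicit), isotope (NA;
##          doubles as the link-class label on "*" link atoms)
##   bonds: a1, a2, order (1, 2, 3, or 1.5 for aromatic)
## Endpoint markers and fragment link points are atoms with element "*".
## Hydrogens are implicit throughout; bracket atoms carry explicit hcount.
## Vectors rather than data frames keep the heavily-called graph edits cheap.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

new_mol <- function() {
  structure(list(
    atoms = list(element = character(), aromatic = logical(),
                 charge = integer(), hcount = integer(),
                 isotope = integer()),
    bonds = list(a1 = integer(), a2 = integer(), order = numeric())),
    class = "polyfp_mol")
}

n_atoms <- function(mol) length(mol$atoms$element)

n_bonds <- function(mol) length(mol$bonds$a1)

star_idx <- function(mol) which(mol$atoms$element == "*")

heavy_idx <- function(mol) which(mol$atoms$element != "*")

n_heavy <- function(mol) sum(mol$atoms$element != "*")

bond_between <- function(mol, a, b) {
  which((mol$bonds$a1 == a & mol$bonds$a2 == b) |
        (mol$bonds$a1 == b & mol$bonds$a2 == a))
}

mol_neighbors <- function(mol, v) {
  b <- mol$bonds
  c(b$a2[b$a1 == v], b$a1[b$a2 == v])
}

add_atom <- function(mol, element, aromatic = FALSE, charge = 0L,
                     hcount = NA_integer_, isotope = NA_integer_) {
  a <- mol$atoms
  a$element <- c(a$element, element)
  a$aromatic <- c(a$aromatic, aromatic)
  a$charge <- c(a$charge, as.integer(charge))
  a$hcount <- c(a$hcount, as.integer(hcount))
  a$isotope <- c(a$isotope, as.integer(isotope))
  mol$atoms <- a
  mol
}

add_bond <- function(mol, a1, a2, order = 1) {
  b <- mol$bonds
  b$a1 <- c(b$a1, as.integer(a1))
  b$a2 <- c(b$a2, as.integer(a2))
  b$order <- c(b$order, as.numeric(order))
  mol$bonds <- b
  mol
}

remove_bonds <- function(mol, idx) {
  if (length(idx)) mol$bonds <- lapply(mol$bonds, `[`, -idx)
  mol
}

## Remove atoms and remap bond endpoints.
remove_atoms <- function(mol, idx) {
  if (!length(idx)) return(mol)
  n <- n_atoms(mol)
  keep <- setdiff(seq_len(n), idx)
  map <- integer(n)
  map[keep] <- seq_along(keep)
  sel <- !(mol$bonds$a1 %in% idx) & !(mol$bonds$a2 %in% idx)
  mol$bonds <- list(a1 = map[mol$bonds$a1[sel]],
                    a2 = map[mol$bonds$a2[sel]],
                    order = mol$bonds$order[sel])
  mol$atoms <- lapply(mol$atoms, `[`, keep)
  mol
}

atoms_subset <- function(mol, perm) {
  mol$atoms <- lapply(mol$atoms, `[`, perm)
  mol
}

## Disjoint union; returns list(mol, offset of second part).
mol_union <- function(m1, m2) {
  off <- n_atoms(m1)
  m1$atoms <- Map(c, m1$atoms, m2$atoms)
  m1$bonds <- list(a1 = c(m1$bonds$a1, m2$bonds$a1 + off),
                   a2 = c(m1$bonds$a2, m2$bonds$a2 + off),
                   order = c(m1$bonds$order, m2$bonds$order))
  list(mol = m1, offset = off)
}

## Per-atom invariant key used for canonical ranking and isomorphism colors.
atom_keys <- function(mol) {
  a <- mol$atoms
  paste(a$element, a$aromatic, a$charge,
        ifelse(is.na(a$hcount), -1L, a$hcount),
        ifelse(is.na(a$isotope), 0L, a$isotope), sep = "|")
}

## Plain undirected igraph with isolated vertices preserved.
to_igraph <- function(mol) {
  igraph::add_edges(igraph::make_empty_graph(n_atoms(mol), directed = FALSE),
                    rbind(mol$bonds$a1, mol$bonds$a2))
}

## Bond indices that lie on at least one cycle (non-bridges).
cycle_bond_rows <- function(mol) {
  if (!n_bonds(mol)) return(integer())
  cpp_cycle_bonds(n_atoms(mol), mol$bonds$a1, mol$bonds$a2)
}

mol_components <- function(mol) {
  cpp_components(n_atoms(mol), mol$bonds$a1, mol$bonds$a2)
}

mol_connected <- function(mol) {
  if (n_atoms(mol) <= 1) return(TRUE)
  all(mol_components(mol) == 1L)
}

## Colored-graph isomorphism with bond orders encoded as subdivision
## vertices; the independent oracle route used by equivalence checks.
mol_isomorphic <- function(m1, m2) {
  if (n_atoms(m1) != n_atoms(m2) || n_bonds(m1) != n_bonds(m2))
    return(FALSE)
  k1 <- atom_keys(m1); k2 <- atom_keys(m2)
  o1 <- as.character(m1$bonds$order); o2 <- as.character(m2$bonds$order)
  lev_a <- sort(unique(c(k1, k2)))
  lev_b <- sort(unique(c(o1, o2)))
  if (!identical(tabulate(match(k1, lev_a), length(lev_a)),
                 tabulate(match(k2, lev_a), length(lev_a))))
    return(FALSE)
  build <- function(mol, keys, orders) {
    n <- n_atoms(mol); m <- n_bonds(mol)
    g <- igraph::make_empty_graph(n + m, directed = FALSE)
    g <- igraph::add_edges(g, rbind(c(mol$bonds$a1, mol$bonds$a2),
                                    rep(n + seq_len(m), 2)))
    col <- c(match(keys, lev_a), length(lev_a) + match(orders, lev_b))
    list(g = g, col = as.integer(col))
  }
  g1 <- build(m1, k1, o1); g2 <- build(m2, k2, o2)
  igraph::isomorphic(g1$g, g2$g, method = "vf2",
                     vertex.color1 = g1$col, vertex.color2 = g2$col)
}

## ---------------------------------------------------------------------------
## SMILES subset parser

BOND_CHARS <- c("-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "/" = 1, "\\" = 1)

parse_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s))
    stop("empty SMILES string")
  ## atom accumulators
  el <- character(); ar <- logical(); ch_ <- integer(); hc <- integer()
  iso <- integer()
  b1 <- integer(); b2 <- integer(); bo <- numeric()
  prev <- NA_integer_
  pend <- NA_real_
  stack <- integer()
  rings <- list()   # digit -> c(atom, order)
  dropped_stereo <- FALSE
  i <- 1L
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  emit_atom <- function(element, aromatic, charge, hcount, isotope) {
    el[length(el) + 1L] <<- element
    ar[length(ar) + 1L] <<- aromatic
    ch_[length(ch_) + 1L] <<- as.integer(charge)
    hc[length(hc) + 1L] <<- as.integer(hcount)
    iso[length(iso) + 1L] <<- as.integer(isotope)
    idx <- length(el)
    if (!is.na(prev)) {
      ord <- pend
      if (is.na(ord)) ord <- if (ar[prev] && aromatic) 1.5 else 1
      b1[length(b1) + 1L] <<- prev
      b2[length(b2) + 1L] <<- idx
      bo[length(bo) + 1L] <<- ord
    }
    prev <<- idx
    pend <<- NA_real_
  }
  close_ring <- function(d) {
    if (is.na(prev)) stop("ring-closure digit before any atom")
    key <- as.character(d)
    if (!is.null(rings[[key]])) {
      op <- rings[[key]]
      ord <- pend
      if (!is.na(op[2]) && !is.na(pend) && op[2] != pend)
        stop("conflicting ring-closure bond orders for digit ", d)
      if (is.na(ord)) ord <- op[2]
      if (is.na(ord)) ord <- if (ar[op[1]] && ar[prev]) 1.5 else 1
      if (op[1] == prev) stop("ring closure bonds an atom to itself")
      if (any((b1 == op[1] & b2 == prev) | (b1 == prev & b2 == op[1])))
        stop("duplicate bond via ring closure")
      b1[length(b1) + 1L] <<- as.integer(op[1])
      b2[length(b2) + 1L] <<- prev
      bo[length(bo) + 1L] <<- ord
      rings[[key]] <<- NULL
    } else {
      rings[[key]] <<- c(prev, pend)
    }
    pend <<- NA_real_
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) stop("branch open before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unmatched closing parenthesis")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "-" || ch == "=" || ch == "#" || ch == ":" ||
               ch == "/" || ch == "\\") {
      if (ch == "/" || ch == "\\") dropped_stereo <- TRUE
      pend <- BOND_CHARS[[ch]]
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure")
      d <- suppressWarnings(as.integer(substr(s, i + 1L, i + 2L)))
      if (is.na(d)) stop("malformed %nn ring closure")
      close_ring(d)
      i <- i + 3L
    } else if (ch >= "0" && ch <= "9") {
      close_ring(as.integer(ch))
      i <- i + 1L
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed bracket atom")
      body <- substr(s, i + 1L, i + j - 2L)
      m <- regmatches(body, regexec(
        "^([0-9]+)?([A-Za-z][a-z]?|\\*)(@@?)?(H[0-9]*)?(\\+[0-9]*|-[0-9]*|\\++|-+)?(:[0-9]+)?$",
        body))[[1]]
      if (!length(m)) stop("malformed bracket atom [", body, "]")
      isoval <- if (nzchar(m[2])) as.integer(m[2]) else NA_integer_
      sym <- m[3]
      if (nzchar(m[4])) dropped_stereo <- TRUE
      hcv <- if (nzchar(m[5])) {
        if (m[5] == "H") 1L else as.integer(substr(m[5], 2L, nchar(m[5])))
      } else 0L
      chg <- 0L
      if (nzchar(m[6])) {
        sgn <- if (substr(m[6], 1L, 1L) == "+") 1L else -1L
        num <- gsub("[+-]", "", m[6])
        chg <- if (nzchar(num)) sgn * as.integer(num) else sgn * nchar(m[6])
      }
      if (sym == "*") {
        emit_atom("*", FALSE, 0L, NA_integer_, isoval)
      } else {
        aromatic <- substr(sym, 1L, 1L) %in% letters
        elsym <- if (aromatic) {
          paste0(toupper(substr(sym, 1L, 1L)), substr(sym, 2L, nchar(sym)))
        } else sym
        emit_atom(elsym, aromatic, chg, hcv, isoval)
      }
      i <- i + j
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ch
      if (two == "Cl" || two == "Br") {
        emit_atom(two, FALSE, 0L, NA_integer_, NA_integer_)
        i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        emit_atom(ch, FALSE, 0L, NA_integer_, NA_integer_)
        i <- i + 1L
      } else if (ch %in% AROMATIC_OK) {
        emit_atom(toupper(ch), TRUE, 0L, NA_integer_, NA_integer_)
        i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' at position ", i)
      }
    }
  }
  if (length(stack)) stop("unclosed branch")
  if (length(rings)) stop("unclosed ring bond(s): ",
                          paste(names(rings), collapse = ", "))
  if (dropped_stereo)
    message("polyfp: stereo markers are not retained and were dropped")
  mol <- structure(list(atoms = list(element = el, aromatic = ar, charge = ch_,
                                     hcount = hc, isotope = iso),
                        bonds = list(a1 = b1, a2 = b2, order = bo)),
                   class = "polyfp_mol")
  ## An "aromatic" default bond outside any ring (e.g. biphenyl written
  ## without the explicit single bond) is really a single bond.
  if (any(mol$bonds$order == 1.5)) {
    cyc <- cycle_bond_rows(mol)
    demote <- setdiff(which(mol$bonds$order == 1.5), cyc)
    if (length(demote)) mol$bonds$order[demote] <- 1
  }
  mol
}

## ---------------------------------------------------------------------------
## SMILES writer
##
## Deterministic depth-first writer; neighbor visiting order follows the
## `rank` vector (ties broken by atom index), so a discrete canonical
## ranking yields a unique string.

atom_token <- function(mol, v) {
  a <- mol$atoms
  if (a$element[v] == "*") {
    return(if (is.na(a$isotope[v])) "[*]" else paste0("[", a$isotope[v], "*]"))
  }
  sym <- if (a$aromatic[v]) {
    paste0(tolower(substr(a$element[v], 1L, 1L)),
           substr(a$element[v], 2L, nchar(a$element[v])))
  } else a$element[v]
  plain <- a$element[v] %in% ORGANIC_SUBSET && a$charge[v] == 0L &&
    is.na(a$hcount[v]) && is.na(a$isotope[v]) &&
    (!a$aromatic[v] || sym %in% AROMATIC_OK)
  if (plain) return(sym)
  h <- if (is.na(a$hcount[v]) || a$hcount[v] == 0L) ""
       else if (a$hcount[v] == 1L) "H" else paste0("H", a$hcount[v])
  chg <- if (a$charge[v] == 0L) "" else if (a$charge[v] == 1L) "+"
         else if (a$charge[v] == -1L) "-"
         else if (a$charge[v] > 0L) paste0("+", a$charge[v])
         else as.character(a$charge[v])
  isot <- if (is.na(a$isotope[v])) "" else as.character(a$isotope[v])
  paste0("[", isot, sym, h, chg, "]")
}

bond_token <- function(mol, order, v, w) {
  arom <- mol$atoms$aromatic[v] && mol$atoms$aromatic[w]
  if (order == 1 && !arom) return("")
  if (order == 1.5 && arom) return("")
  if (order == 1) return("-")
  if (order == 2) return("=")
  if (order == 3) return("#")
  if (order == 1.5) return(":")
  stop("unsupported bond order ", order)
}

## Per-molecule token tables for the compiled writer: one token per atom,
## one (possibly empty) bond-symbol token per bond.
mol_tokens <- function(mol) {
  n <- n_atoms(mol)
  atok <- vapply(seq_len(n), function(v) atom_token(mol, v), character(1))
  btok <- vapply(seq_len(n_bonds(mol)), function(r)
    bond_token(mol, mol$bonds$order[r], mol$bonds$a1[r], mol$bonds$a2[r]),
    character(1))
  list(atok = atok, btok = btok)
}

write_smiles <- function(mol, start = 1L, rank = NULL) {
  n <- n_atoms(mol)
  if (n == 0L) stop("empty molecule")
  if (is.null(rank)) rank <- seq_len(n)
  tk <- mol_tokens(mol)
  cpp_write_smiles(n, mol$bonds$a1, mol$bonds$a2, tk$atok, tk$btok,
                   as.integer(start), as.integer(rank))
}
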