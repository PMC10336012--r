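## PSMILES core: validation and graph-based canonicalization.
##
## A PSMILES string is a SMILES string with exactly two "[*]" endpoint
## markers delimiting the polymer repeat unit.  All rewritings of a repeat
## unit -- shifted windows (translation), k-fold multiples (multiplication),
## and syntactic atom-order permutations -- denote the same infinite chain;
## canonicalization reduces them to one unique representative string.
##
## The algorithm: (i) reduce to the shortest repeat unit by detecting
## rotational symmetry of the periodic backbone; (ii) join the two
## endpoint-adjacent atoms with a closure bond to form the periodic graph;
## (iii) rank atoms canonically (iterative neighborhood refinement with
## individualization); (iv) re-open the periodic graph at every admissible
## backbone bond and keep the lexicographically smallest written string.
##
## Internally everything operates on "units": the star-stripped repeat-unit
## graph plus its two attachment anchors and the attachment bond order.
## Strings are parsed once at the API boundary.

## ---------------------------------------------------------------------------
## Validation

mol_issues <- function(mol) {
  issues <- character()
  detail <- character()
  note <- function(code, d) {
    issues <<- c(issues, code)
    detail <<- c(detail, d)
  }
  st <- star_idx(mol)
  if (length(st) != 2L) {
    note("star_count", sprintf("found %d endpoint markers, need 2", length(st)))
  } else {
    if (length(bond_between(mol, st[1], st[2])))
      note("star_star_bond", "the two endpoint markers are bonded to each other")
    deg <- vapply(st, function(v) length(mol_neighbors(mol, v)), integer(1))
    if (any(deg != 1L)) {
      note("star_degree", "endpoint markers must be univalent")
    } else if (!length(bond_between(mol, st[1], st[2]))) {
      o1 <- mol$bonds$order[bond_between(mol, st[1], mol_neighbors(mol, st[1]))]
      o2 <- mol$bonds$order[bond_between(mol, st[2], mol_neighbors(mol, st[2]))]
      if (o1 != o2)
        note("endpoint_bond_orders",
             sprintf("endpoint attachment bond orders differ (%s vs %s)", o1, o2))
      if (o1 == 1.5 || o2 == 1.5)
        note("aromatic_endpoint_bond", "endpoint attachment bonds cannot be aromatic")
    }
    if (!all(is.na(mol$atoms$isotope[st])))
      note("star_label", "endpoint markers must be unlabeled [*]")
  }
  if (!mol_connected(mol))
    note("disconnected", "molecular graph is not connected")
  if (n_heavy(mol) < 1L)
    note("no_heavy_atoms", "repeat unit has no heavy atoms")
  if (any(mol$atoms$aromatic)) {
    cyc <- cycle_bond_rows(mol)
    in_ring <- unique(c(mol$bonds$a1[cyc], mol$bonds$a2[cyc]))
    bad_arom <- setdiff(which(mol$atoms$aromatic), in_ring)
    if (length(bad_arom))
      note("aromatic_outside_ring",
           sprintf("%d aromatic atom(s) not in any ring", length(bad_arom)))
  }
  data.frame(code = issues, detail = detail, stringsAsFactors = FALSE)
}

#' Validate a PSMILES string
#'
#' Checks a raw string against the PSMILES contract: it must parse as a
#' molecular graph, contain exactly two `[*]` endpoint markers, the markers
#' must not be bonded to each other, the two endpoint attachment bonds must
#' have the same (non-aromatic) bond order, the graph must be connected,
#' and aromatic atoms must lie in rings.  All violations are reported;
#' nothing is thrown.
#'
#' @param raw character scalar, candidate PSMILES string.
#' @return An object of class `psmiles_validation`: a list with elements
#'   `valid` (logical) and `issues` (data frame with columns `code` and
#'   `detail`).
#' @examples
#' validate_psmiles("[*]CC[*]")$valid
#' validate_psmiles("CCO")$issues
#' @export
validate_psmiles <- function(raw) {
  mol <- tryCatch(suppressMessages(parse_smiles(raw)), error = identity)
  issues <- if (inherits(mol, "error")) {
    data.frame(code = "parse_error", detail = conditionMessage(mol),
               stringsAsFactors = FALSE)
  } else mol_issues(mol)
  structure(list(valid = nrow(issues) == 0L, issues = issues),
            class = "psmiles_validation")
}

#' @export
print.psmiles_validation <- function(x, ...) {
  if (x$valid) cat("valid PSMILES\n")
  else {
    cat("invalid PSMILES:\n")
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s\n", x$issues$code[i], x$issues$detail[i]))
  }
  invisible(x)
}

## Parse a validated PSMILES; stop with the collected issues otherwise.
parse_psmiles <- function(p) {
  mol <- tryCatch(parse_smiles(p), error = function(e)
    stop("invalid PSMILES '", p, "': parse_error (", conditionMessage(e), ")",
         call. = FALSE))
  issues <- mol_issues(mol)
  if (nrow(issues))
    stop("invalid PSMILES '", p, "': ", paste(issues$code, collapse = ", "),
         call. = FALSE)
  mol
}

## ---------------------------------------------------------------------------
## Units: star-stripped repeat-unit graphs

## unit: list(mol, head, tail, order); head/tail are the former anchors of
## the first and second star, order the attachment bond order.
unit_from_mol <- function(mol) {
  st <- star_idx(mol)
  anchors <- vapply(st, function(v) mol_neighbors(mol, v)[1], integer(1))
  ord <- mol$bonds$order[bond_between(mol, st[1], anchors[1])]
  keep <- setdiff(seq_len(n_atoms(mol)), st)
  map <- integer(n_atoms(mol))
  map[keep] <- seq_along(keep)
  list(mol = remove_atoms(mol, st), head = map[anchors[1]],
       tail = map[anchors[2]], order = ord)
}

unit_to_mol <- function(u) {
  m <- add_atom(u$mol, "*")
  m <- add_bond(m, n_atoms(m), u$head, u$order)
  m <- add_atom(m, "*")
  add_bond(m, n_atoms(m), u$tail, u$order)
}

unit_write <- function(u) {
  m <- unit_to_mol(u)
  write_smiles(m, start = n_atoms(m) - 1L)
}

unit_multiply <- function(u, k) {
  if (k == 1) return(u)
  acc <- u$mol
  tail_cur <- u$tail
  for (i in seq_len(k - 1)) {
    w <- mol_union(acc, u$mol)
    acc <- add_bond(w$mol, tail_cur, w$offset + u$head, u$order)
    tail_cur <- w$offset + u$tail
  }
  list(mol = acc, head = u$head, tail = tail_cur, order = u$order)
}

## Backbone: atoms on a shortest path from head to tail.
unit_backbone <- function(u) {
  if (u$head == u$tail) return(u$head)
  cpp_bfs_path(n_atoms(u$mol), u$mol$bonds$a1, u$mol$bonds$a2,
               u$head, u$tail)
}

## Periodic graph: unit closed head-to-tail.  Units whose backbone is
## shorter than 3 atoms are internally multiplied first (a closure over a
## 1- or 2-atom backbone would create a self-loop or a duplicate bond).
unit_cyclize <- function(u) {
  b <- unit_backbone(u)
  k_internal <- 1L
  if (length(b) < 3L) {
    k_internal <- as.integer(ceiling(3 / length(b)))
    u <- unit_multiply(u, k_internal)
    b <- unit_backbone(u)
  }
  if (length(bond_between(u$mol, u$tail, u$head)))
    stop("closure would duplicate an existing bond")
  G <- add_bond(u$mol, u$tail, u$head, u$order)
  list(mol = G, closure_row = n_bonds(G), backbone = b,
       k_internal = k_internal, order = u$order)
}

## Window shift by j backbone positions (graph level).
unit_rotate <- function(u, j) {
  b <- unit_backbone(u)
  m <- length(b)
  j <- ((j %% m) + m) %% m
  if (j == 0L || m == 1L) return(u)
  cut_row <- bond_between(u$mol, b[j], b[j + 1L])
  if (length(cut_row) != 1L) stop("backbone bond missing; cannot rotate")
  cut_ord <- u$mol$bonds$order[cut_row]
  if (cut_ord == 1.5) stop("cannot cut an aromatic backbone bond during rotation")
  out <- remove_bonds(u$mol, cut_row)
  if (m > 2L && length(bond_between(out, b[m], b[1L])))
    stop("rotation would duplicate an existing bond (ring backbone)")
  out <- add_bond(out, b[m], b[1L], u$order)
  if (!mol_connected(out))
    stop("rotation would disconnect the repeat unit")
  list(mol = out, head = b[j + 1L], tail = b[j], order = cut_ord)
}

## ---------------------------------------------------------------------------
## Rewriting operations (string API)

#' Multiply a PSMILES repeat unit
#'
#' Returns a PSMILES string containing `k` concatenated copies of the repeat
#' unit of `p`; the infinite chain it denotes is unchanged.
#'
#' @param p valid PSMILES string.
#' @param k positive integer repeat count.
#' @return PSMILES string with `k` times the heavy atoms of `p`.
#' @examples
#' multiply_psmiles("[*]CCCCCC(=O)N[*]", 2)
#' @export
multiply_psmiles <- function(p, k) {
  stopifnot(length(k) == 1L, k >= 1, k == round(k))
  u <- unit_from_mol(parse_psmiles(p))
  if (k == 1) return(p)
  unit_write(unit_multiply(u, k))
}

#' Shift the repeat-unit window along the backbone
#'
#' Translates the repeat-unit window of `p` by `j` backbone positions.  The
#' result is an equivalent writing of the same polymer: it canonicalizes to
#' the same string as `p`.
#'
#' @param p valid PSMILES string.
#' @param j integer shift (any sign; reduced modulo the backbone length).
#' @return PSMILES string.
#' @examples
#' rotate_psmiles("[*]CCO[*]", 1)
#' @export
rotate_psmiles <- function(p, j) {
  stopifnot(length(j) == 1L, j == round(j))
  u <- unit_from_mol(parse_psmiles(p))
  u2 <- unit_rotate(u, j)
  if (identical(u2, u)) p else unit_write(u2)
}

#' Close a repeat unit into its periodic molecular graph
#'
#' Joins the two endpoint-adjacent atoms with a closure bond whose order
#' equals the (matching) endpoint attachment orders.  Repeat units whose
#' backbone has fewer than 3 atoms are internally multiplied first so the
#' closure creates neither a self-loop nor a duplicate bond.
#'
#' @param p valid PSMILES string.
#' @return An object of class `periodic_mol`: list with the closed graph
#'   (`mol`), the closure bond index (`closure_row`), the backbone atom
#'   indices in cyclic order (`backbone`), and the number of internal
#'   copies used (`k_internal`).
#' @examples
#' cyclize_psmiles("[*]CCO[*]")
#' @export
cyclize_psmiles <- function(p) {
  u <- unit_from_mol(parse_psmiles(p))
  structure(unit_cyclize(u), class = "periodic_mol")
}

#' @export
print.periodic_mol <- function(x, ...) {
  cat(sprintf("periodic molecule: %d atoms, %d bonds (closure order %s%s)\n",
              n_atoms(x$mol), n_bonds(x$mol),
              x$mol$bonds$order[x$closure_row],
              if (x$k_internal > 1)
                sprintf("; %d internal copies", x$k_internal) else ""))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Canonical ranking: iterative refinement + individualization

initial_colors <- function(mol) {
  k <- atom_keys(mol)
  match(k, sort(unique(k)))
}

## All discrete colorings reachable by individualization-refinement
## (compiled).  Molecular graphs keep this small (it is bounded by the
## automorphism structure); a hard cap guards against pathological inputs.
discrete_colorings <- function(mol, colors, cap = 5000L) {
  cpp_discrete_colorings(n_atoms(mol), mol$bonds$a1, mol$bonds$a2,
                         match(mol$bonds$order, c(1, 1.5, 2, 3)),
                         as.integer(colors), as.integer(cap))
}

## Canonical string of a molecule (invariant to input atom order).
## `starts`: candidate start atoms (defaults to the star atoms, or all
## atoms if there are none); the smallest string over all discrete
## colorings x admissible starts is returned.
canon_smiles <- function(mol, starts = NULL) {
  if (is.null(starts)) {
    starts <- star_idx(mol)
    if (!length(starts)) starts <- seq_len(n_atoms(mol))
  }
  labelings <- discrete_colorings(mol, initial_colors(mol))
  tk <- mol_tokens(mol)
  best <- NULL
  for (lab in labelings) {
    st <- starts[which.min(lab[starts])]
    s <- cpp_write_smiles(n_atoms(mol), mol$bonds$a1, mol$bonds$a2,
                          tk$atok, tk$btok, st, lab)
    if (is.null(best) || s < best) best <- s
  }
  best
}

## ---------------------------------------------------------------------------
## Chain-identity oracle and shortest repeat unit

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

## Graph-level polymer identity: compare the cyclized 3L-fold multiples
## (L = lcm of unit sizes), which equate the cyclic sequences of the two
## chains.  Independent of the canonical writer; used as the test oracle
## and to vet admissible ring-opening bonds.
same_polymer_units <- function(ua, ub, fold = 3L) {
  na <- n_atoms(ua$mol); nb <- n_atoms(ub$mol)
  L <- (na / gcd_int(na, nb)) * nb
  if (L * fold > 900) stop("oracle molecule too large (", L * fold, " atoms)")
  ga <- unit_cyclize(unit_multiply(ua, fold * L / na))
  gb <- unit_cyclize(unit_multiply(ub, fold * L / nb))
  mol_isomorphic(ga$mol, gb$mol)
}

#' Compare two PSMILES strings by the graph oracle
#'
#' Brute-force chain identity: both units are multiplied to a common atom
#' count (three times the least common multiple), cyclized, and compared by
#' colored graph isomorphism.  Independent of [canonicalize_psmiles()];
#' exposed for testing and cross-checks.
#'
#' @param a,b valid PSMILES strings.
#' @return Logical.
#' @export
same_polymer_oracle <- function(a, b) {
  same_polymer_units(unit_from_mol(parse_psmiles(a)),
                     unit_from_mol(parse_psmiles(b)))
}

## Shortest repeat unit at graph level.  For each divisor k of the backbone
## length the periodic graph is cut into k consecutive segments; a segment
## that detaches cleanly with 1/k of the atoms is verified against the
## chain-identity oracle.
unit_reduce <- function(u) {
  n <- n_atoms(u$mol)
  per <- unit_cyclize(u)
  G <- per$mol
  b <- per$backbone
  m <- length(b)
  n_tot <- n * per$k_internal
  u_tot <- if (per$k_internal > 1) unit_multiply(u, per$k_internal) else u
  divs <- which(m %% seq_len(m) == 0)
  divs <- sort(divs[divs > 1L], decreasing = TRUE)
  for (k in divs) {
    if (n_tot %% k != 0) next
    seg <- m %/% k
    e0 <- bond_between(G, b[m], b[1L])
    e1 <- bond_between(G, b[seg], b[seg + 1L])
    if (length(e0) != 1L || length(e1) != 1L) next
    o0 <- G$bonds$order[e0]; o1 <- G$bonds$order[e1]
    if (o0 != o1 || o0 == 1.5) next
    cutg <- remove_bonds(G, sort(c(e0, e1)))
    memb <- mol_components(cutg)
    if (memb[b[1L]] != memb[b[seg]]) next
    unit_atoms <- which(memb == memb[b[1L]])
    if (length(unit_atoms) != n_tot %/% k) next
    if (any(memb[b[seq(seg + 1L, m)]] == memb[b[1L]])) next
    sub <- remove_atoms(cutg, setdiff(seq_len(n_atoms(cutg)), unit_atoms))
    map <- integer(n_atoms(cutg)); map[unit_atoms] <- seq_along(unit_atoms)
    cand <- list(mol = sub, head = map[b[1L]], tail = map[b[seg]], order = o0)
    ok <- tryCatch(same_polymer_units(cand, u_tot), error = function(e) FALSE)
    ## The unit may still be reducible if a larger k was rejected by a
    ## ring crossing the segment boundary; reduce until stable.
    if (ok && n_atoms(cand$mol) < n) return(unit_reduce(cand))
  }
  u
}

#' Shortest repeat unit of a PSMILES string
#'
#' Detects multiplicative repetition by searching for rotational symmetry
#' of the periodic backbone: for each divisor `k` of the backbone length
#' the periodic graph is cut into `k` consecutive segments, and the
#' candidate unit is verified against the chain-identity oracle (graph
#' isomorphism of cyclized multiples).  Returns `p` unchanged if no
#' repetition exists.
#'
#' @param p valid PSMILES string.
#' @return PSMILES string of the shortest repeat unit.
#' @examples
#' shortest_repeat("[*]CCOCCO[*]")
#' @export
shortest_repeat <- function(p) {
  u <- unit_from_mol(parse_psmiles(p))
  u2 <- unit_reduce(u)
  if (n_atoms(u2$mol) < n_atoms(u$mol)) unit_write(u2) else p
}

## ---------------------------------------------------------------------------
## Canonicalization

## Admissible ring-opening bonds of a periodic graph: non-aromatic bonds on
## a cycle whose cleavage yields a unit denoting the same chain.  When the
## open unit is acyclic the periodic graph is unicyclic and every cycle
## bond qualifies; otherwise candidates are vetted by the oracle.
opening_candidates <- function(per, u_ref) {
  G <- per$mol
  cyc <- cycle_bond_rows(G)
  cyc <- cyc[G$bonds$order[cyc] != 1.5]
  open_has_rings <-
    length(cycle_bond_rows(remove_bonds(G, per$closure_row))) > 0
  if (!open_has_rings) return(cyc)
  keep <- vapply(cyc, function(r) {
    cand <- list(mol = remove_bonds(G, r), head = G$bonds$a1[r],
                 tail = G$bonds$a2[r], order = G$bonds$order[r])
    tryCatch(same_polymer_units(cand, u_ref), error = function(e) FALSE)
  }, logical(1))
  cyc[keep]
}

#' Canonicalize a PSMILES string
#'
#' Maps every rewriting (translation of the repeat-unit window, k-fold
#' multiplication, syntactic permutation) of a polymer to one unique
#' string: the repeat unit is reduced to its shortest form, closed into the
#' periodic graph, and re-opened at every admissible backbone bond; each
#' opening is written with a canonical atom ranking and the
#' lexicographically smallest string wins.  The result is idempotent.
#'
#' @param p valid PSMILES string.
#' @return Canonical PSMILES string.
#' @examples
#' canonicalize_psmiles("[*]CCOCCO[*]")   # reduces to the 3-atom unit
#' @export
canonicalize_psmiles <- function(p) {
  u <- unit_reduce(unit_from_mol(parse_psmiles(p)))
  b <- unit_backbone(u)
  m <- length(b)
  if (m < 3L) {
    ## Backbone too short to cyclize without degenerate bonds (vinyl-type
    ## units): enumerate the (at most two) window shifts directly.
    units <- list(u)
    if (m == 2L) {
      u2 <- tryCatch(unit_rotate(u, 1L), error = function(e) NULL)
      if (!is.null(u2)) units <- c(units, list(u2))
    }
    strs <- vapply(units, function(ui) {
      mi <- unit_to_mol(ui)
      canon_smiles(mi, starts = c(n_atoms(mi) - 1L, n_atoms(mi)))
    }, character(1))
    return(min(strs))
  }
  per <- unit_cyclize(u)
  cand <- opening_candidates(per, u)
  if (!length(cand)) stop("no admissible ring-opening bond found for '", p, "'")
  best <- NULL
  for (r in cand) {
    G <- per$mol
    ui <- list(mol = remove_bonds(G, r), head = G$bonds$a1[r],
               tail = G$bonds$a2[r], order = G$bonds$order[r])
    mi <- unit_to_mol(ui)
    s <- canon_smiles(mi, starts = c(n_atoms(mi) - 1L, n_atoms(mi)))
    if (is.null(best) || s < best) best <- s
  }
  best
}

#' Test whether two PSMILES strings denote the same polymer
#'
#' @param a,b valid PSMILES strings.
#' @return Logical: `TRUE` iff their canonical forms are identical.
#' @examples
#' are_same_polymer("[*]CCOCCO[*]", "[*]COC[*]")
#' @export
are_same_polymer <- function(a, b) {
  identical(canonicalize_psmiles(a), canonicalize_psmiles(b))
}
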