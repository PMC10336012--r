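## Cheap graph descriptors and the descriptor-baseline fingerprint.
##
## These are deliberately computable without any learned model: the
## synthetic property generator builds its ground truth on them, so test
## oracles for the prediction stack stay independent of the language model.

DESCRIPTOR_NAMES <- c("n_heavy", "backbone_len", "arom_frac", "n_O", "n_N",
                      "n_S", "n_halogen", "n_rings", "n_double", "n_triple",
                      "longest_side", "mean_degree")

#' Descriptor-baseline fingerprint of a polymer repeat unit
#'
#' A fixed-length vector of cheap, handcrafted graph descriptors of the
#' repeat unit: heavy-atom and backbone length, aromatic fraction,
#' heteroatom and halogen counts, ring count (cycle rank), multiple-bond
#' counts, the longest side chain, and mean heavy-atom degree.  Serves as a
#' reduced handcrafted baseline next to the learned language-model
#' fingerprint and as the input representation for synthetic ground truth.
#'
#' @param p valid PSMILES string.
#' @return Named numeric vector of length 12.
#' @examples
#' descriptor_fingerprint("[*]CC([*])c1ccccc1")
#' @export
descriptor_fingerprint <- function(p) {
  u <- unit_from_mol(parse_psmiles(p))
  open <- u$mol
  bpath <- unit_backbone(u)
  a <- open$atoms
  nh <- n_atoms(open)
  deg <- tabulate(c(open$bonds$a1, open$bonds$a2), nh)
  ## longest side chain: for each non-backbone atom, graph distance to the
  ## nearest backbone atom; 0 when everything is backbone
  longest_side <- 0
  side <- setdiff(seq_len(nh), bpath)
  if (length(side)) {
    g <- to_igraph(open)
    d <- igraph::distances(g, v = side, to = bpath)
    longest_side <- max(apply(d, 1, min))
  }
  ## circuit rank = number of independent rings
  n_rings <- n_bonds(open) - nh + igraph::count_components(to_igraph(open))
  c(n_heavy = nh,
    backbone_len = length(bpath),
    arom_frac = mean(a$aromatic),
    n_O = sum(a$element == "O"),
    n_N = sum(a$element == "N"),
    n_S = sum(a$element == "S"),
    n_halogen = sum(a$element %in% c("F", "Cl", "Br", "I")),
    n_rings = n_rings,
    n_double = sum(open$bonds$order == 2),
    n_triple = sum(open$bonds$order == 3),
    longest_side = longest_side,
    mean_degree = mean(deg))
}
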