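# BRICS decomposition, fragment library, and recombination.

test_that("decomposition handles units with no cleavable bonds", {
  d <- brics_decompose("[*]C[*]")
  expect_length(d$fragments, 1)
  expect_equal(d$n_cuts, 0)
  expect_true(are_same_polymer(brics_reassemble(d), "[*]C[*]"))
})

test_that("polystyrene splits at the ring-chain bond", {
  d <- brics_decompose("[*]CC([*])c1ccccc1")
  keys <- vapply(d$fragments, `[[`, character(1), "key")
  expect_length(d$fragments, 2)
  # one fragment is the aromatic ring with a [16*] link
  expect_true(any(grepl("c1ccccc1", keys) & grepl("16\\*", keys)))
  # endpoint markers were protected: both [*] survive in the backbone part
  backbone <- keys[!grepl("c1ccccc1", keys)]
  expect_equal(lengths(regmatches(backbone, gregexpr("[*]", backbone,
                                                     fixed = TRUE))), 2)
})

test_that("decompose-reassemble is canonical identity on fixtures", {
  for (p in fixture_monomers(12, seed = 8)) {
    d <- brics_decompose(p)
    expect_true(are_same_polymer(brics_reassemble(d), p), info = p)
  }
})

test_that("library construction deduplicates and counts fragments", {
  one <- build_library("[*]CC([*])c1ccccc1")
  two <- build_library(rep("[*]CC([*])c1ccccc1", 2))
  expect_equal(vapply(one$fragments, `[[`, character(1), "key"),
               vapply(two$fragments, `[[`, character(1), "key"))
  expect_equal(vapply(two$fragments, `[[`, integer(1), "count"),
               2L * vapply(one$fragments, `[[`, integer(1), "count"))
  # shared backbone fragment across chemically related polymers
  lib2 <- build_library(c("[*]CC([*])c1ccccc1", "[*]CC([*])c1ccncc1"))
  expect_lt(length(lib2$fragments),
            length(build_library("[*]CC([*])c1ccccc1")$fragments) +
            length(build_library("[*]CC([*])c1ccncc1")$fragments))
  expect_error(build_library(character()), "empty corpus")
  expect_error(build_library(c("[*]CC[*]", "CCO")), "index: 2")
})

test_that("generated polymers are valid, canonical, unique, reproducible", {
  lib <- fixture_library()
  gen <- combine_fragments(lib, 60, seed = 7)
  expect_length(gen, 60)
  expect_false(anyDuplicated(gen) > 0)
  for (s in gen[1:10]) {
    expect_true(validate_psmiles(s)$valid)
    expect_identical(canonicalize_psmiles(s), s)
  }
  expect_identical(combine_fragments(lib, 60, seed = 7), gen)
  expect_false(identical(combine_fragments(lib, 60, seed = 8), gen))
})

test_that("enumerate mode is deterministic and bounded by the tuple count", {
  # toy library from one simple corpus: few two-link fragments
  lib <- build_library(c("[*]CC([*])c1ccccc1", "[*]CCO[*]"))
  two_link <- Filter(function(f)
    sum(f$mol$atoms$element == "*") == 2, lib$fragments)
  n2 <- length(two_link)
  gen <- combine_fragments(lib, 1000, mode = "enumerate", max_fragments = 2)
  # at most (2 n)^1 + (2 n)^2 ordered tuples before canonical dedup
  expect_lte(length(gen), (2 * n2) + (2 * n2)^2)
  expect_identical(gen,
                   combine_fragments(lib, 1000, mode = "enumerate",
                                     max_fragments = 2))
  for (s in gen) expect_identical(canonicalize_psmiles(s), s)
})

test_that("link classes pair according to the published compatibility", {
  expect_true(link_compatible(1L, 3L))
  expect_true(link_compatible(16L, 16L))
  expect_false(link_compatible(1L, 16L))
  expect_false(link_compatible(3L, 3L))
  expect_true(link_compatible(0L, 5L))  # protected chain ends join anything
  expect_equal(link_bond_order(7L, 7L), 2)
  expect_equal(link_bond_order(3L, 4L), 1)
})

test_that("bond finding reproduces the reference BRICS implementation", {
  # independent oracle: RDKit's published BRICS rules via the system python
  mols <- c("CCOC(=O)c1ccccc1", "CC(=O)Nc1ccccc1", "CCOCC",
            "CC(C)CC(=O)OCC", "CCSc1ccccc1", "CCN(CC)C(=O)c1ccccc1",
            "CCCC", "COc1ccccc1", "C1CCNC1C(=O)CC")
  script <- paste(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem import BRICS",
    "for m in sys.argv[1:]:",
    "    bonds = list(BRICS.FindBRICSBonds(Chem.MolFromSmiles(m)))",
    "    labs = sorted('-'.join(sorted([a, b], key=int)) for (_, (a, b)) in bonds)",
    "    print(','.join(labs))",
    sep = "\n")
  ref <- tryCatch(
    system2("python", c("-", shQuote(mols)), input = script, stdout = TRUE,
            stderr = FALSE),
    warning = function(w) NULL, error = function(e) NULL)
  expect_false(is.null(ref))  # the reference interpreter must be present
  for (i in seq_along(mols)) {
    b <- brics_find_bonds(suppressMessages(parse_smiles(mols[i])))
    labs <- if (nrow(b))
      sort(paste0(pmin(b$lab1, b$lab2), "-", pmax(b$lab1, b$lab2)))
    else character(0)
    expect_identical(paste(labs, collapse = ","), ref[i], info = mols[i])
  }
})

test_that("fragment libraries serialize to a text table and back", {
  lib <- fixture_library()
  f <- tempfile(fileext = ".tsv")
  write_library(lib, f)
  lib2 <- read_library(f)
  expect_equal(vapply(lib2$fragments, `[[`, character(1), "key"),
               vapply(lib$fragments, `[[`, character(1), "key"))
  expect_equal(vapply(lib2$fragments, `[[`, integer(1), "count"),
               vapply(lib$fragments, `[[`, integer(1), "count"))
  expect_equal(lapply(lib2$fragments, `[[`, "link_types"),
               lapply(lib$fragments, `[[`, "link_types"))
})
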