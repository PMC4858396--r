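# molecular-graph layer: parsing, canonicalization, weights, matching

test_that("canonical SMILES round-trips and is written-form invariant", {
  cases <- c("CC(=O)[O-].[Na+]", "c1ccccc1", "Cc1ccccc1", "C1CCCCC1",
             "c1ccncc1", "N[C@@H](C)C(=O)O", "c1ccc(-c2ccccc2)cc1",
             "CC(F)(F)F", "O=S(=O)(N)c1ccccc1", "CN(C)C=O",
             "C=CCc1ccccc1", "[NH4+].[Cl-]", "c1ccc2ccccc2c1",
             "CC1=CCCCC1", "O=C1CCCCC1")
  for (s in cases) {
    cs <- canonical_smiles(s)
    expect_identical(canonical_smiles(cs), cs, label = s)
  }
  # same constitution written differently collapses to one string
  expect_identical(canonical_smiles("Cc1ccccc1"), canonical_smiles("c1ccc(C)cc1"))
  expect_identical(canonical_smiles("OC(=O)C"), canonical_smiles("CC(O)=O"))
})

test_that("stereoisomers share one identity", {
  expect_identical(canonical_smiles("N[C@@H](C)C(=O)O"),
                   canonical_smiles("N[C@H](C)C(=O)O"))
  expect_identical(canonical_smiles("N[C@@H](C)C(=O)O"),
                   canonical_smiles("NC(C)C(=O)O"))
  expect_identical(canonical_smiles("F/C=C/F"), canonical_smiles("FC=CF"))
})

test_that("molecular weight matches closed-form alkane masses", {
  # CnH2n+2: n*12.011 + (2n+2)*1.008
  for (n in c(1, 6, 20, 150)) {
    smi <- paste(rep("C", n), collapse = "")
    expect_equal(mol_weight(parse_smiles(smi)),
                 n * 12.011 + (2 * n + 2) * 1.008, tolerance = 1e-9)
  }
  expect_equal(mol_weight(parse_smiles("O")), 15.999 + 2 * 1.008,
               tolerance = 1e-9)
})

test_that("components, metalorganics and safe parsing behave", {
  comps <- mol_components(parse_smiles("CC(=O)[O-].[Na+]"))
  expect_length(comps, 2)
  expect_identical(comps[[1]]$atoms$element, c("C", "C", "O", "O"))
  expect_true(is_metalorganic(parse_smiles("CC[Pb](CC)(CC)CC")))
  expect_false(is_metalorganic(parse_smiles("CC(=O)[O-].[Na+]")))
  expect_false(is_metalorganic(parse_smiles("CCO")))
  expect_null(parse_smiles_safe("C1CC"))       # unclosed ring
  expect_null(parse_smiles_safe("notasmiles!"))
  expect_error(parse_smiles("C(C"), "parenthesis")
})

test_that("substructure matching follows subgraph-isomorphism semantics", {
  expect_true(has_substructure("c1ccccc1", "Cc1ccccc1"))
  expect_false(has_substructure("c1ccccc1", "C1CCCCC1"))  # aromatic mismatch
  expect_true(has_substructure("S(=O)(=O)N", "Cc1ccc(S(=O)(=O)N)cc1"))
  expect_false(has_substructure("C=CC", "Cc1ccccc1"))
  expect_true(has_substructure("C=CC", "C=CCC1CCCCC1"))
  expect_false(has_substructure("N(C)C=O", "CNC"))
})

test_that("matching is monotone: a superstructure never matches more", {
  lib <- make_library(200, seed = 5)$lib
  smi <- stats::setNames(lib$smiles, lib$compound_id)
  pairs <- list(c("C=C", "C=CC"),            # sub, super
                c("S", "S(=O)(=O)N"),
                c("C(F)F", "C(F)(F)F"))
  for (p in pairs) {
    m_sub <- match_fragment(p[1], smi)
    m_super <- match_fragment(p[2], smi)
    expect_true(all(m_super %in% m_sub),
                label = paste(p, collapse = " vs "))
  }
})

test_that("circular fragments are shared exactly by identical environments", {
  fr1 <- circular_fragments("Cc1ccccc1")
  fr2 <- circular_fragments("CCc1ccccc1")
  expect_true("r0:c" %in% fr1 && "r0:c" %in% fr2)
  # methyl-on-benzene r1 env present in both (toluene's methyl, ethyl's CH2)
  expect_true(length(intersect(fr1, fr2)) > 3)
  # deterministic across calls and memoization
  expect_identical(fr1, circular_fragments("Cc1ccccc1"))
  expect_identical(sort(fr1), sort(circular_fragments_memo("Cc1ccccc1")))
})
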