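test_that("SMILES parsing completes implicit hydrogens to the lowest allowed valence", {
  w <- parse_smiles("O")
  expect_equal(sort(w$elements), c("H", "H", "O"))
  expect_equal(nrow(bond_list(w)), 2L)
  expect_true(valence_valid(w))

  e <- parse_smiles("CC")
  expect_equal(molecular_formula(e), "C2H6")
  expect_equal(nrow(bond_list(e)), 7L)

  g <- parse_smiles("OCC(O)C(O)C(O)C(O)C=O")
  expect_equal(molecular_formula(g), "C6H12O6")
  expect_equal(n_atoms(g), 24L)
})

test_that("constitutional isomers written with or without a carbon differ", {
  a <- parse_smiles("C(=O)C")   # acetaldehyde (two heavy-atom skeleton)
  b <- parse_smiles("CC(=O)C")  # propan-2-one
  expect_false(canonical_key(a) == canonical_key(b))
})

test_that("SMILES parser rejects unsupported tokens and bad valences", {
  expect_error(parse_smiles("C[Cl]"), "unsupported")
  expect_error(parse_smiles("[O-]C"), "unsupported")
  expect_error(parse_smiles("C%12CC"), "unsupported")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence")
  expect_error(parse_smiles("C1CC"), "ring")
  expect_error(parse_smiles("CC)"), "unbalanced")
})

test_that("SMILES writer round-trips through the parser", {
  for (nm in fixture_molecules()$name) {
    g <- fixture_molecules(nm)
    back <- parse_smiles(to_smiles(g))
    expect_equal(canonical_key(back), canonical_key(g), label = nm)
  }
  # multi-fragment and H-only components
  h2_plus_ethene <- graph_union(parse_smiles("[H][H]"), parse_smiles("C=C"))
  s <- to_smiles(h2_plus_ethene)
  expect_match(s, "\\[H\\]\\[H\\]")
  expect_equal(canonical_key(parse_smiles(s)), canonical_key(h2_plus_ethene))
})

test_that("molgraph constructor validates shape and elements", {
  expect_error(molgraph("X", matrix(0L, 1, 1)), "unsupported")
  expect_error(molgraph(c("C", "C"), matrix(c(0L, 1L, 2L, 0L), 2)), "symmetric")
  expect_error(molgraph(c("C", "C"), matrix(c(1L, 1L, 1L, 1L), 2)), "diagonal")
})

test_that("split_components conserves atoms and keys each fragment", {
  e <- parse_smiles("CC")
  expect_length(split_components(e), 1L)
  two <- graph_union(parse_smiles("C=C"), parse_smiles("[H][H]"))
  comps <- split_components(two)
  expect_length(comps, 2L)
  expect_equal(sum(vapply(comps, n_atoms, integer(1))), n_atoms(two))
  # conservation over a pool of enumerated product graphs
  pool <- candidate_graph_pool("ethanol")
  for (g in pool) {
    comps <- split_components(g)
    expect_equal(sum(vapply(comps, n_atoms, integer(1))), n_atoms(g))
  }
})

test_that("graph_diff is empty on identity and labels ethane dehydrogenation b2f2", {
  e <- parse_smiles("CC")
  d <- graph_diff(e, e)
  expect_equal(nrow(d$broken), 0L)
  expect_equal(nrow(d$formed), 0L)

  cands <- enumerate_candidates(e)
  expect_equal(nrow(cands), 1L)
  d <- graph_diff(e, cands$product_graph[[1]])
  expect_equal(nrow(d$broken), 2L) # two C-H units
  expect_equal(nrow(d$formed), 2L) # C=C second unit + H-H
  expect_equal(classify_ers(d$broken, d$formed), "b2f2")
})

test_that("graph_diff/apply round-trips over enumerated candidates", {
  pool <- list(fixture_molecules("ethanol"), fixture_molecules("khp"),
               fixture_molecules("propylene_carbonate"),
               fixture_molecules("methyl_butanoate"))
  n_checked <- 0
  for (g in pool) {
    cands <- enumerate_candidates(g)
    for (r in seq_len(nrow(cands))) {
      res <- apply_bond_changes(g, list(broken = cands$broken[[r]],
                                        formed = cands$formed[[r]]))
      expect_true(res$valid)
      expect_identical(res$graph$bonds, cands$product_graph[[r]]$bonds)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 100)
})

test_that("graph_diff errors on element mismatch and apply on missing bonds", {
  a <- parse_smiles("O")
  b <- permute_graph(a, c(2L, 1L, 3L)) # same graph, H first: elements differ
  expect_error(graph_diff(a, b), "mismatch")
  e <- parse_smiles("CC")
  expect_error(
    apply_bond_changes(e, list(broken = matrix(c(3L, 4L), 1), # H-H not bonded
                               formed = matrix(integer(), 0, 2))),
    "no bond left")
})

test_that("apply_bond_changes flags valence-invalid products", {
  e <- parse_smiles("CC")
  hs <- which(e$elements == "H")
  c1_h <- which(e$bonds[1, ] > 0 & e$elements == "H")
  # strip two H from the same carbon, pair them: carbene carbon left at 2
  res <- apply_bond_changes(e, list(
    broken = matrix(c(1L, c1_h[1], 1L, c1_h[2]), 2, byrow = TRUE),
    formed = matrix(c(c1_h[1], c1_h[2]), 1)))
  expect_false(res$valid)
})
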