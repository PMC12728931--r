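test_that("SMILES parsing produces the expected hydrogen-suppressed graphs", {
  b <- parse_smiles("OC(=O)c1ccccc1")
  expect_length(b$elements, 9)
  expect_equal(n_edges(b), 9)
  tab <- table(b$bonds$order)
  expect_equal(as.integer(tab[["aromatic"]]), 6)
  expect_equal(as.integer(tab[["single"]]), 2)  # C-C and C-O
  expect_equal(as.integer(tab[["double"]]), 1)  # C=O

  g <- parse_smiles("C")
  expect_length(g$elements, 1)
  expect_equal(n_edges(g), 0)

  s <- parse_smiles("CC(C)C")
  expect_equal(n_edges(s), 3)
  expect_true(all(s$bonds$order == "single"))
  expect_true(all(s$elements == "C"))

  # bracket atoms, charges, explicit hydrogens
  h <- parse_smiles("[NH4+]")
  expect_equal(h$elements, "N")
  expect_equal(h$charges, 1L)
  e <- parse_smiles("[H]OC([H])([H])O[H]")
  expect_false(any(e$elements == "H"))
  expect_equal(n_edges(e), 2)

  # dot-disconnected components
  d <- parse_smiles("CC.CC")
  expect_equal(n_components(d), 2)
  expect_equal(n_edges(d), 2)

  expect_error(parse_smiles("C&C"), "unrecognised")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
})

test_that("SMILES parsing is invariant to atom reordering", {
  a <- parse_smiles("CCO")
  b <- parse_smiles("OCC")
  expect_true(cyclic_isomorphic(a, rep(TRUE, 2), b, rep(TRUE, 2)))
  expect_equal(assembly_index(a)$ma, assembly_index(b)$ma)

  x <- parse_smiles("OC(=O)c1ccccc1")
  y <- parse_smiles("c1ccc(cc1)C(O)=O")
  expect_true(cyclic_isomorphic(x, rep(TRUE, 9), y, rep(TRUE, 9)))
  expect_equal(assembly_index(y)$ma, 6)
})

test_that("kekulisation assigns alternating ring bonds", {
  k <- parse_smiles("c1ccccc1", kekulize = TRUE)
  expect_equal(sort(as.vector(table(k$bonds$order))), c(3L, 3L))
  expect_false(any(k$bonds$order == "aromatic"))
  # pyrrole-type nitrogen carries the H and takes no double bond
  im <- parse_smiles("c1c[nH]cn1", kekulize = TRUE)
  expect_equal(sum(im$bonds$order == "double"), 2)
})

test_that("MOL/SDF blocks parse with hydrogen suppression", {
  ethane <- paste(c("ethane", "", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0 0.0 0.0 C   0  0", "    1.0 0.0 0.0 C   0  0",
    "    2.0 0.0 0.0 H   0  0", "   -1.0 0.0 0.0 H   0  0",
    "  1  2  1  0", "  2  3  1  0", "  1  4  1  0", "M  END"),
    collapse = "\n")
  g <- parse_molblock(ethane)
  expect_equal(length(g$elements), 2)
  expect_equal(n_edges(g), 1)

  benzene <- paste(c("benzene", "", "",
    "  6  6  0  0  0  0  0  0  0  0999 V2000",
    rep("    0.0 0.0 0.0 C   0  0", 6),
    "  1  2  4  0", "  2  3  4  0", "  3  4  4  0",
    "  4  5  4  0", "  5  6  4  0", "  6  1  4  0", "M  END"),
    collapse = "\n")
  h <- parse_molblock(benzene)
  expect_equal(length(h$elements), 6)
  expect_equal(n_edges(h), 6)
  expect_equal(length(unique(bond_labels <- paste(h$bonds$order))), 1)

  expect_error(parse_molblock("not a molfile"), "malformed")
})

test_that("unique-bond removal keeps exactly the duplicatable labels", {
  b <- parse_smiles("OC(=O)c1ccccc1")
  mask <- remove_unique_bonds(b)
  expect_equal(sum(mask), 6)
  expect_true(all(b$bonds$order[mask] == "aromatic"))

  expect_true(all(remove_unique_bonds(mg_path(4))))

  # all labels distinct: nothing retained, MA = N - 1 immediately
  g <- mg_path(3, orders = c("single", "double", "triple"))
  expect_false(any(remove_unique_bonds(g)))
  expect_equal(assembly_index(g)$ma, 2)

  # single pass is idempotent at the level used
  m1 <- remove_unique_bonds(b)
  expect_identical(m1, remove_unique_bonds(b))

  # agrees with the engine-internal preprocessing
  for (g in fixture_suite())
    expect_identical(remove_unique_bonds(g),
                     massembly:::cpp_retained_mask(massembly:::mg_to_cpp(g)))
})

test_that("connected components split deterministically", {
  g <- molgraph(rep("C", 5),
                data.frame(from = c(1, 2, 4), to = c(2, 3, 5),
                           order = "single"))
  comps <- connected_components(g)
  expect_length(comps, 2)
  expect_equal(edge_idx(comps[[1]]), c(1, 2))
  expect_equal(edge_idx(comps[[2]]), 3)

  expect_length(connected_components(g, rep(FALSE, 3)), 0)
  expect_length(connected_components(mg_cycle(6)), 1)

  # ring minus a 3-edge arc is a single 3-edge arc
  ring <- mg_cycle(6)
  m <- rep(TRUE, 6); m[1:3] <- FALSE
  sp <- disjoint_set_split(ring, m)
  expect_length(sp, 1)
  expect_equal(sum(sp[[1]]), 3)
})

test_that("graph joining re-indexes edges and unifies components", {
  b <- named_molecule("benzoic_acid")
  j <- join_graphs(list(b, b))
  expect_equal(n_edges(j), 18)
  expect_equal(n_components(j), 2)
  e <- mg_path(1)
  expect_identical(join_graphs(list(e)), e)
  # '.'-disconnected SMILES equals joining the parts
  d <- parse_smiles("CCO.CCO")
  j2 <- join_graphs(list(parse_smiles("CCO"), parse_smiles("CCO")))
  expect_true(cyclic_isomorphic(d, rep(TRUE, 4), j2, rep(TRUE, 4)))
})

test_that("molgraph validation rejects malformed input", {
  expect_error(molgraph(c("C", "H")), "hydrogens")
  expect_error(molgraph("Xx"), "unknown element")
  expect_error(molgraph(c("C", "C"),
                        data.frame(from = 1, to = 1, order = "single")),
               "self-loops")
  expect_error(molgraph(c("C", "C"),
                        data.frame(from = c(1, 2), to = c(2, 1),
                                   order = "single")),
               "one bond per vertex pair")
})
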