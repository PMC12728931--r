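test_that("acyclicity is edge count versus vertex count", {
  expect_true(is_acyclic(mg_path(2)))
  expect_false(is_acyclic(mg_cycle(6)))
  expect_true(is_acyclic(mg_random_tree(5, seed = 3)))
  g <- join_graphs(list(mg_path(2), mg_path(2)))
  expect_error(is_acyclic(g), "connected")
})

test_that("tree keys identify labelled trees exactly", {
  expect_identical(tree_key(parse_smiles("CCO")), tree_key(parse_smiles("OCC")))
  expect_false(tree_key(parse_smiles("CCO")) == tree_key(parse_smiles("C=CO")))
  # path vs star over a single atom label
  expect_false(tree_key(mg_path(3)) == tree_key(mg_star(3)))
  expect_error(tree_key(mg_cycle(3)), "acyclic")

  # double-centre determinism: same tree entered in both orientations
  a <- mg_path(4, orders = c("single", "double", "double", "single"))
  b <- mg_path(4, orders = c("single", "double", "double", "single"))
  expect_identical(tree_key(a), tree_key(b))
})

test_that("tree keys scale to long chains without blowup", {
  t0 <- proc.time()[["elapsed"]]
  k <- tree_key(mg_path(50, orders = c("single", "double")))
  expect_true(nchar(k) > 0)
  expect_lt(proc.time()[["elapsed"]] - t0, 1)
})

test_that("cyclic isomorphism respects labels and topology", {
  ring <- mg_cycle(6, orders = "aromatic")
  expect_true(cyclic_isomorphic(ring, rep(TRUE, 6), mg_cycle(6, orders = "aromatic"),
                                rep(TRUE, 6)))
  expect_false(cyclic_isomorphic(mg_cycle(6), rep(TRUE, 6), mg_path(6),
                                 rep(TRUE, 6)))
  # labelled 4-cycle CNCN equals its rotation NCNC
  cn <- molgraph(c("C", "N", "C", "N"),
                 data.frame(from = 1:4, to = c(2, 3, 4, 1), order = "single"))
  nc <- molgraph(c("N", "C", "N", "C"),
                 data.frame(from = 1:4, to = c(2, 3, 4, 1), order = "single"))
  expect_true(cyclic_isomorphic(cn, rep(TRUE, 4), nc, rep(TRUE, 4)))
  # but CCNN is a different class
  ccnn <- molgraph(c("C", "C", "N", "N"),
                   data.frame(from = 1:4, to = c(2, 3, 4, 1), order = "single"))
  expect_false(cyclic_isomorphic(cn, rep(TRUE, 4), ccnn, rep(TRUE, 4)))
})

test_that("class keys are exact for trees and bucket-plus-match for cycles", {
  p <- mg_path(3)
  expect_identical(class_key(p), paste0("T:", tree_key(p)))
  expect_match(class_key(mg_cycle(4)), "^C:")
  # two isomorphic cyclic fragments share key and match explicitly
  r1 <- mg_cycle(5, orders = "aromatic")
  r2 <- mg_cycle(5, orders = "aromatic")
  expect_identical(class_key(r1), class_key(r2))
  expect_true(cyclic_isomorphic(r1, rep(TRUE, 5), r2, rep(TRUE, 5)))
  # CNCN vs CCNN share size and label multiset but are distinct classes
  cn <- molgraph(c("C", "N", "C", "N"),
                 data.frame(from = 1:4, to = c(2, 3, 4, 1), order = "single"))
  ccnn <- molgraph(c("C", "C", "N", "N"),
                   data.frame(from = 1:4, to = c(2, 3, 4, 1), order = "single"))
  expect_false(cyclic_isomorphic(cn, rep(TRUE, 4), ccnn, rep(TRUE, 4)))
})

test_that("class identity agrees with a brute-force permutation oracle", {
  # exhaustive pairs over the <=3-edge family (2 atom x 2 bond labels)
  gs <- exhaustive_small_graphs(3)
  # pairs within the same (edge count, vertex count) bucket, plus a seeded
  # random sample of cross-bucket pairs
  sig <- vapply(gs, function(g) paste(n_edges(g), length(g$elements)), "")
  n_checked <- 0
  for (s in unique(sig)) {
    idx <- which(sig == s)
    for (i in idx) {
      for (j in idx) {
        if (j <= i) next
        gi <- gs[[i]]; gj <- gs[[j]]
        ours <- cyclic_isomorphic(gi, rep(TRUE, n_edges(gi)),
                                  gj, rep(TRUE, n_edges(gj)))
        expect_identical(ours, perm_isomorphic(gi, gj))
        # generator emits one representative per class: never isomorphic
        expect_false(ours)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 50)
  # and each 4-edge graph is isomorphic to a random self-relabelling
  gs <- exhaustive_small_graphs(4)
  set.seed(7)
  for (g in gs[sample(seq_along(gs), 25)]) {
    perm <- sample(length(g$elements))
    h <- permute_molgraph(g, perm)
    expect_true(cyclic_isomorphic(g, rep(TRUE, n_edges(g)),
                                  h, rep(TRUE, n_edges(h))))
    expect_true(perm_isomorphic(g, h))
    expect_identical(class_key(g), class_key(h))
  }
})
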