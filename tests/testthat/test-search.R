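test_that("removal semantics: both occurrences deleted, one copy kept", {
  g <- mg_path(4)
  st <- initial_state(g)
  child <- apply_removal(g, st, list(a = c(1, 2), b = c(3, 4)))
  # the whole chain is consumed: the copy is the only fragment left
  expect_equal(child$fragments, list(c(1, 2)))
  expect_equal(child$S, 1)
  expect_equal(assembly_index(g)$ma, 2)  # = l(4)

  # benzoic acid: removing the 3-edge aromatic arc pair saves 2
  b <- parse_smiles("OC(=O)c1ccccc1")
  en <- enumerate_duplicates(b)
  cl3 <- Filter(function(cl) cl$matchable && cl$k == 3, en$classes)[[1]]
  vp <- valid_pairs(cl3, initial_state(b)$fragments)
  expect_gt(length(vp), 0)
  ch <- apply_removal(b, initial_state(b), vp[[1]])
  expect_equal(ch$S, 2)

  # invalid pair: overlapping occurrences
  expect_error(apply_removal(g, st, list(a = c(1, 2), b = c(2, 3))),
               "overlaps")
  # occurrence straddling fragments
  g2 <- join_graphs(list(mg_path(2), mg_path(2)))
  expect_error(apply_removal(g2, initial_state(g2),
                             list(a = c(1, 2), b = c(2, 3))))
})

test_that("state hashing separates the first element and ignores tail order", {
  s1 <- list(fragments = list(c(1, 2), c(3, 4), c(5, 6)))
  s2 <- list(fragments = list(c(1, 2), c(5, 6), c(3, 4)))
  s3 <- list(fragments = list(c(3, 4), c(1, 2), c(5, 6)))
  expect_identical(hash_state(s1), hash_state(s2))
  expect_false(hash_state(s1) == hash_state(s3))
})

test_that("search reproduces calibration values and trivial cases", {
  r <- assembly_index(parse_smiles("OC(=O)c1ccccc1"))
  expect_equal(r$ma, 6)
  expect_true(r$converged)

  expect_equal(assembly_index(mg_path(1))$ma, 0)
  expect_equal(assembly_index(molgraph("C"))$ma, 0)
  expect_equal(assembly_index(mg_cycle(3))$ma, 2)

  expect_error(assembly_index(mg_path(4), timeout = 0), "budget")
})

test_that("uniform chains reduce to minimal addition chains", {
  for (n in 1:20)
    expect_equal(assembly_index(mg_path(n))$ma, addition_chain_length(n))
})

test_that("search equals the oracle on seeded random labelled trees", {
  set.seed(202)
  sizes <- sample(2:10, 200, replace = TRUE)
  for (i in seq_along(sizes)) {
    g <- mg_random_tree(sizes[i], seed = 1000 + i)
    expect_equal(assembly_index(g)$ma, oracle_ma(g),
                 info = sprintf("tree seed %d size %d", 1000 + i, sizes[i]))
  }
})

test_that("disabling the heuristics never changes the result", {
  for (g in fixture_suite()) {
    ref <- assembly_index(g)$ma
    expect_equal(assembly_index(g, use_bound = FALSE)$ma, ref)
    expect_equal(assembly_index(g, use_table = FALSE)$ma, ref)
    expect_equal(assembly_index(g, use_bound = FALSE, use_table = FALSE)$ma,
                 ref)
  }
})

test_that("anytime trace is monotone and budget expiry is reported honestly", {
  r <- assembly_index(peptide("ACD"))
  expect_true(all(diff(r$trace$ma_upper) <= 0))
  expect_equal(r$trace$ma_upper[nrow(r$trace)], r$ma)
  expect_true(r$converged)

  lim <- assembly_index(join_graphs(lapply(named_molecules()[4:23],
                                           named_molecule)),
                        max_states = 2000)
  expect_false(lim$converged)
  expect_true(all(diff(lim$trace$ma_upper) <= 0))
  # the reported MA is the best upper bound found, never below the log bound
  expect_gte(lim$ma, ceil_log2(lim$n_bonds))
})

test_that("MA always sits between the log lower and naive upper bound", {
  for (g in fixture_suite()) {
    r <- assembly_index(g)
    # doubling bounds the largest buildable fragment, so the log bound is
    # set by the largest component
    n_max <- max(vapply(connected_components(g), sum, 1L))
    expect_gte(r$ma, ceil_log2(n_max))
    expect_lte(r$ma, r$n_bonds - r$n_components)
  }
})

test_that("MA is invariant under input-order permutations", {
  set.seed(99)
  for (g in list(parse_smiles("OC(=O)c1ccccc1"), peptide("AC"),
                 mg_random_tree(8, seed = 17))) {
    ref <- assembly_index(g)$ma
    for (rep in 1:3) {
      h <- permute_molgraph(g, sample(length(g$elements)))
      # also shuffle the edge order
      sh <- sample(n_edges(h))
      h2 <- molgraph(h$elements, h$bonds[sh, ], h$charges, h$aromatic_atoms)
      expect_equal(assembly_index(h2)$ma, ref)
    }
  }
})

test_that("reconstructed pathways replay to the reported best state", {
  for (g in list(mg_path(4), mg_path(16), parse_smiles("OC(=O)c1ccccc1"),
                 peptide("AC"),
                 join_graphs(list(named_molecule("benzoic_acid"),
                                  named_molecule("benzoic_acid"))))) {
    r <- assembly_index(g)
    ks <- vapply(r$pathway, `[[`, 1L, "k")
    expect_equal(sum(ks - 1L), r$best_s)
    st <- initial_state(g)
    for (step in r$pathway) {
      expect_true(all(step$k >= 2))
      expect_length(intersect(step$duplicate, step$partner), 0)
      st <- apply_removal(g, st,
                          list(a = step$duplicate, b = step$partner))
    }
    expect_equal(st$S, r$best_s)
    canon <- function(fr) sort(vapply(fr, function(f)
      paste(sort(f), collapse = "."), ""))
    expect_identical(canon(st$fragments), canon(r$final_fragments))
  }
  # molecule with no duplicates: empty pathway, MA = N - 1
  nod <- mg_path(3, orders = c("single", "double", "triple"))
  r <- assembly_index(nod)
  expect_length(r$pathway, 0)
  expect_equal(r$ma, 2)
})

test_that("results serialise to schema-stable JSON", {
  r <- assembly_index(parse_smiles("OC(=O)c1ccccc1"))
  doc <- jsonlite::fromJSON(as_assembly_json(r), simplifyVector = FALSE)
  expect_setequal(names(doc), c("ma", "best_s", "converged", "n_bonds",
                                "n_components", "trace", "pathway", "stats"))
  expect_equal(doc$ma, 6)
  # identical runs agree byte-for-byte once timing fields are dropped
  strip <- function(x) {
    d <- jsonlite::fromJSON(as_assembly_json(x), simplifyVector = FALSE)
    d$stats <- NULL
    d$trace <- lapply(d$trace, function(row) row["ma_upper"])
    d
  }
  r2 <- assembly_index(parse_smiles("OC(=O)c1ccccc1"))
  expect_identical(strip(r), strip(r2))
})
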