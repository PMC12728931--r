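test_that("duplicate enumeration finds the expected classes on fixtures", {
  # uniform 4-chain: the 2-edge path is matchable with 3 occurrences; the
  # 3-edge path has 2 overlapping occurrences and is non-matchable
  en <- enumerate_duplicates(mg_path(4))
  ks <- vapply(en$classes, `[[`, 1L, "k")
  mt <- vapply(en$classes, `[[`, TRUE, "matchable")
  two <- which(ks == 2)
  expect_length(two, 1)
  expect_true(mt[two])
  expect_length(en$classes[[two]]$occurrences, 3)
  three <- which(ks == 3)
  expect_length(three, 1)
  expect_false(mt[three])
  expect_length(en$classes[[three]]$occurrences, 2)

  # triangle: one 2-edge class, 3 pairwise-overlapping occurrences
  en <- enumerate_duplicates(mg_cycle(3))
  expect_false(any(vapply(en$classes, `[[`, TRUE, "matchable")))

  # benzoic acid: matchable classes are the 2- and 3-edge aromatic paths
  en <- enumerate_duplicates(parse_smiles("OC(=O)c1ccccc1"))
  mt <- Filter(function(cl) cl$matchable, en$classes)
  expect_setequal(vapply(mt, `[[`, 1L, "k"), c(2, 3))
  b <- parse_smiles("OC(=O)c1ccccc1")
  for (cl in mt)
    for (o in cl$occurrences)
      expect_true(all(b$bonds$order[o] == "aromatic"))
})

test_that("occurrences are connected, mutually isomorphic, and the DAG is sound", {
  for (g in fixture_suite()) {
    en <- enumerate_duplicates(g)
    for (cl in en$classes) {
      expect_gte(length(cl$occurrences), 2)
      for (o in cl$occurrences) {
        expect_length(o, cl$k)
        expect_true(massembly:::cpp_is_connected(
          massembly:::mg_to_cpp(g), massembly:::mask_from_idx(o, n_edges(g))))
      }
      # spot-check isomorphism of first against the others
      m1 <- massembly:::mask_from_idx(cl$occurrences[[1]], n_edges(g))
      for (o in cl$occurrences[-1])
        expect_true(cyclic_isomorphic(g, m1, g,
          massembly:::mask_from_idx(o, n_edges(g))))
      # one stored parent, one edge smaller
      if (cl$k > 2) {
        expect_false(is.na(cl$parent))
        expect_equal(en$classes[[cl$parent]]$k, cl$k - 1L)
      } else {
        expect_true(is.na(cl$parent))
      }
    }
    # cover mask: a bit is set iff the bond occurs in some occurrence
    occ_union <- as.integer(sort(unique(unlist(lapply(en$classes, function(cl)
      unlist(cl$occurrences))))))
    expect_equal(which(en$cover), occ_union)
  }
})

test_that("matchable classes equal the brute-force duplicatable list on small graphs", {
  # brute force: all connected subgraphs with >= 2 edge-disjoint isomorphic
  # embeddings, via exhaustive edge-subset enumeration
  brute_matchable <- function(g) {
    n <- n_edges(g)
    subs <- list()
    for (sz in 2:n) {
      for (comb in utils::combn(n, sz, simplify = FALSE)) {
        m <- massembly:::mask_from_idx(comb, n)
        if (massembly:::cpp_is_connected(massembly:::mg_to_cpp(g), m))
          subs[[length(subs) + 1]] <- comb
      }
    }
    classes <- list()
    for (s in subs) {
      placed <- FALSE
      for (ci in seq_along(classes)) {
        rep1 <- classes[[ci]][[1]]
        if (length(rep1) == length(s) &&
            cyclic_isomorphic(g, massembly:::mask_from_idx(rep1, n),
                              g, massembly:::mask_from_idx(s, n))) {
          classes[[ci]][[length(classes[[ci]]) + 1]] <- s
          placed <- TRUE
          break
        }
      }
      if (!placed) classes[[length(classes) + 1]] <- list(s)
    }
    keys <- character()
    for (cl in classes) {
      ok <- FALSE
      for (i in seq_along(cl)) {
        for (j in seq_along(cl)) {
          if (i < j && length(intersect(cl[[i]], cl[[j]])) == 0) ok <- TRUE
        }
      }
      if (ok)
        keys <- c(keys, class_key(g, massembly:::mask_from_idx(cl[[1]], n)))
    }
    sort(keys)
  }
  suite <- list(mg_path(4), mg_path(6, orders = c("single", "double")),
                mg_cycle(3), mg_cycle(6), mg_star(5),
                parse_smiles("OC(=O)c1ccccc1"),
                mg_random_tree(6, seed = 11), mg_random_tree(7, seed = 12))
  for (g in suite) {
    en <- enumerate_duplicates(g)
    ours <- sort(vapply(Filter(function(cl) cl$matchable, en$classes),
                        `[[`, "", "key"))
    expect_identical(ours, brute_matchable(g))
  }
})

test_that("valid pairs are edge-disjoint, in-fragment and normalised", {
  g <- mg_path(4)
  en <- enumerate_duplicates(g)
  st <- initial_state(g)
  two <- en$classes[[which(vapply(en$classes, `[[`, 1L, "k") == 2)]]
  vp <- valid_pairs(two, st$fragments)
  expect_length(vp, 1)
  expect_equal(vp[[1]]$a, c(1, 2))
  expect_equal(vp[[1]]$b, c(3, 4))

  en3 <- enumerate_duplicates(mg_cycle(3))
  for (cl in en3$classes)
    expect_length(valid_pairs(cl, initial_state(mg_cycle(3))$fragments), 0)

  # two disconnected identical 2-edge paths: one cross-fragment pair
  g2 <- join_graphs(list(mg_path(2), mg_path(2)))
  en2 <- enumerate_duplicates(g2)
  cl <- Filter(function(c) c$matchable, en2$classes)[[1]]
  vp2 <- valid_pairs(cl, initial_state(g2)$fragments)
  expect_length(vp2, 1)
  expect_equal(vp2[[1]]$a, c(1, 2))
  expect_equal(vp2[[1]]$b, c(3, 4))
})

test_that("available duplicates respect the monotone size rule", {
  g <- mg_path(8)
  en <- enumerate_duplicates(g)
  st <- initial_state(g)
  av <- available_duplicates(en, st$fragments)
  expect_gt(length(av), 0)
  expect_equal(av[[1]]$class$k, 4)  # m = 4: disjoint 4-edge sub-paths exist
  sizes <- vapply(av, function(o) o$class$k, 1L)
  expect_true(all(diff(sizes) <= 0))

  # after removing a size-2 class, only size-<=2 classes are offered
  rank2 <- Filter(function(cl) cl$k == 2, en$classes)[[1]]$rank
  av2 <- available_duplicates(en, st$fragments, max_rank = rank2)
  expect_true(all(vapply(av2, function(o) o$class$k, 1L) <= 2))

  # a state with no matchable pairs is a leaf
  expect_length(available_duplicates(enumerate_duplicates(mg_cycle(3)),
                                     initial_state(mg_cycle(3))$fragments), 0)
})
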