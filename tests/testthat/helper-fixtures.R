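# Shared helpers for the test suite. All fixtures are built in code.

edge_idx <- function(mask) which(mask)

# brute-force labelled-graph isomorphism by trying every vertex permutation;
# independent of the package's canonisation/matching code
perm_isomorphic <- function(g1, g2) {
  n <- length(g1$elements)
  if (n != length(g2$elements) || n_edges(g1) != n_edges(g2)) return(FALSE)
  if (n > 8) stop("permutation oracle capped at 8 vertices")
  key <- function(g, perm) {
    b <- g$bonds
    u <- perm[b$from]; v <- perm[b$to]
    lab <- paste(pmin(u, v), pmax(u, v), b$order)
    paste(sort(lab), collapse = ";")
  }
  target <- key(g2, seq_len(n))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (p in perms(seq_len(n))) {
    # p maps g1 vertex i onto g2 vertex p[i]: labels and edges must agree
    if (all(g1$elements == g2$elements[p]) && key(g1, p) == target)
      return(TRUE)
  }
  FALSE
}

# permute the atoms of a molgraph (relabelled but isomorphic molecule)
permute_molgraph <- function(g, perm) {
  inv <- order(perm)
  b <- g$bonds
  molgraph(g$elements[inv],
           data.frame(from = perm[b$from], to = perm[b$to], order = b$order),
           charges = g$charges[inv],
           aromatic_atoms = g$aromatic_atoms[inv])
}

# a small standard fixture suite used by several property tests
fixture_suite <- function() {
  list(
    path4 = mg_path(4),
    path6_mixed = mg_path(6, orders = c("single", "double")),
    triangle = mg_cycle(3),
    star4 = mg_star(4),
    ring6 = mg_cycle(6, orders = "aromatic"),
    benzoic = parse_smiles("OC(=O)c1ccccc1"),
    two_paths = join_graphs(list(mg_path(3), mg_path(3))),
    tree = mg_random_tree(7, seed = 42)
  )
}
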