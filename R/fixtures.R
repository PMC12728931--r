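# Synthetic fixture generators: labelled paths/cycles/stars/trees, a peptide
# builder from one-letter codes, and a small named-molecule dictionary.
# Generation is a pure function of the arguments.

#' Labelled path, cycle and star graphs
#'
#' `mg_path(n)` is a chain of `n` bonds (n+1 atoms); with one atom type and
#' one bond type its assembly index equals the minimal addition-chain length
#' l(n). With one atom type and two bond types the family of chains of
#' length n maps onto the binary numbers with n digits (`mg_binary_chain`).
#'
#' @param n number of bonds (`n >= 1`; for cycles `n >= 3`).
#' @param element element symbol for every atom.
#' @param orders bond-order vector, recycled to length n.
#' @export
mg_path <- function(n, element = "C", orders = "single") {
  stopifnot(n >= 1)
  molgraph(rep(element, n + 1),
           data.frame(from = 1:n, to = 2:(n + 1),
                      order = rep_len(orders, n)))
}

#' @rdname mg_path
#' @export
mg_cycle <- function(n, element = "C", orders = "single") {
  stopifnot(n >= 3)
  molgraph(rep(element, n),
           data.frame(from = 1:n, to = c(2:n, 1),
                      order = rep_len(orders, n)))
}

#' @rdname mg_path
#' @export
mg_star <- function(n, element = "C", orders = "single") {
  stopifnot(n >= 1)
  molgraph(rep(element, n + 1),
           data.frame(from = rep(1L, n), to = 2:(n + 1),
                      order = rep_len(orders, n)))
}

#' @rdname mg_path
#' @param value non-negative integer encoded as the bond pattern (bit i of
#'   `value` selects the order of bond i: 0 = first order, 1 = second).
#' @export
mg_binary_chain <- function(n, value,
                            element = "C", orders = c("single", "double")) {
  stopifnot(n >= 1, value >= 0, value < 2^n)
  bits <- as.integer(intToBits(value))[1:n]
  mg_path(n, element, orders[bits + 1L])
}

#' Random labelled tree
#'
#' Deterministic in `seed`: a Pruefer-style construction over the given
#' label alphabets. The global RNG state is left untouched.
#'
#' @param n_edges number of edges (tree has n_edges + 1 vertices).
#' @param elements,orders label alphabets sampled uniformly.
#' @param seed integer seed.
#' @export
mg_random_tree <- function(n_edges, elements = c("C", "N"),
                           orders = c("single", "double"), seed = 1) {
  stopifnot(n_edges >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  nv <- n_edges + 1
  els <- sample(elements, nv, replace = TRUE)
  ords <- sample(orders, n_edges, replace = TRUE)
  if (nv == 2) {
    edges <- cbind(1L, 2L)
  } else {
    pruefer <- sample.int(nv, nv - 2, replace = TRUE)
    degree <- tabulate(pruefer, nv) + 1L
    edges <- matrix(0L, n_edges, 2)
    ptr <- 0L
    for (p in pruefer) {
      leaf <- which(degree == 1L)[1]
      ptr <- ptr + 1L
      edges[ptr, ] <- c(leaf, p)
      degree[leaf] <- 0L
      degree[p] <- degree[p] - 1L
    }
    last <- which(degree == 1L)
    edges[n_edges, ] <- last
  }
  molgraph(els, data.frame(from = edges[, 1], to = edges[, 2], order = ords))
}

# side-chain SMILES attached at the alpha carbon (hydrogen-suppressed);
# glycine has none and proline is handled as a cyclic special case
AA_SIDE_CHAINS <- c(
  A = "C", R = "CCCNC(=N)N", N = "CC(N)=O", D = "CC(=O)O", C = "CS",
  E = "CCC(=O)O", Q = "CCC(N)=O", G = "", H = "Cc1c[nH]cn1", I = "C(C)CC",
  L = "CC(C)C", K = "CCCCN", M = "CCSC", F = "Cc1ccccc1",
  S = "CO", T = "C(O)C", V = "C(C)C", W = "Cc1c[nH]c2ccccc12",
  Y = "Cc1ccc(O)cc1"
)

#' Build a peptide from one-letter codes
#'
#' Standard residue topologies joined N-to-C with free termini (neutral
#' forms), hydrogen-suppressed. Covers the 20 standard amino acids; proline
#' contributes its pyrrolidine ring fused to the backbone nitrogen.
#'
#' @param code character like `"ACD"` (or a vector of single letters).
#' @return a `molgraph`.
#' @export
#' @examples
#' peptide("ACD")  # tripeptide Ala-Cys-Asp, 19 bonds
peptide <- function(code) {
  letters1 <- if (length(code) == 1) strsplit(code, "")[[1]] else code
  bad <- setdiff(letters1, c(names(AA_SIDE_CHAINS), "P"))
  if (length(bad)) stop("unknown amino-acid code(s): ", paste(bad, collapse = ", "))
  res <- vapply(letters1, function(aa) {
    if (aa == "P") return("N1CCCC1C(=O)")
    side <- AA_SIDE_CHAINS[[aa]]
    if (side == "") "NCC(=O)" else paste0("NC(", side, ")C(=O)")
  }, "")
  parse_smiles(paste0(paste(res, collapse = ""), "O"))
}

# small embedded dictionary of named structures used in examples and tests
NAMED_SMILES <- c(
  benzene = "c1ccccc1",
  benzoic_acid = "OC(=O)c1ccccc1",
  ethane = "CC",
  alanine = "NC(C)C(=O)O", arginine = "NC(CCCNC(=N)N)C(=O)O",
  asparagine = "NC(CC(N)=O)C(=O)O", aspartate = "NC(CC(=O)O)C(=O)O",
  cysteine = "NC(CS)C(=O)O", glutamate = "NC(CCC(=O)O)C(=O)O",
  glutamine = "NC(CCC(N)=O)C(=O)O", glycine = "NCC(=O)O",
  histidine = "NC(Cc1c[nH]cn1)C(=O)O", isoleucine = "NC(C(C)CC)C(=O)O",
  leucine = "NC(CC(C)C)C(=O)O", lysine = "NC(CCCCN)C(=O)O",
  methionine = "NC(CCSC)C(=O)O", phenylalanine = "NC(Cc1ccccc1)C(=O)O",
  proline = "OC(=O)C1CCCN1", serine = "NC(CO)C(=O)O",
  threonine = "NC(C(O)C)C(=O)O", tryptophan = "NC(Cc1c[nH]c2ccccc12)C(=O)O",
  tyrosine = "NC(Cc1ccc(O)cc1)C(=O)O", valine = "NC(C(C)C)C(=O)O"
)

#' Named fixture molecules
#'
#' Embedded SMILES dictionary (benzoic acid, benzene, the 20 standard amino
#' acids) so the whole test surface runs offline.
#'
#' @param name one of `names(named_molecules())`.
#' @return a `molgraph`; `named_molecules()` lists the available names.
#' @export
named_molecule <- function(name) {
  if (!name %in% names(NAMED_SMILES))
    stop("unknown molecule name: ", name)
  parse_smiles(NAMED_SMILES[[name]])
}

#' @rdname named_molecule
#' @export
named_molecules <- function() names(NAMED_SMILES)

#' All connected labelled graphs up to a size
#'
#' Exhaustive generation up to labelled isomorphism over the given alphabet,
#' by one-edge growth with canonical deduplication. Used by the oracle
#' property suites.
#'
#' @param max_edges maximum edge count (keep small; the family grows fast).
#' @param elements,orders label alphabets.
#' @param max_graphs safety cap on the number of generated graphs.
#' @return list of `molgraph` objects.
#' @export
exhaustive_small_graphs <- function(max_edges, elements = c("C", "N"),
                                    orders = c("single", "double"),
                                    max_graphs = 2e6) {
  stopifnot(max_edges >= 1, max_edges <= 7)
  codes <- unname(ELEMENT_CODES[elements])
  raw <- cpp_gen_small_graphs(max_edges, as.integer(codes),
                              as.integer(match(orders, BOND_ORDERS)),
                              as.numeric(max_graphs))
  back <- stats::setNames(names(ELEMENT_CODES), ELEMENT_CODES)
  lapply(raw, function(gl) {
    molgraph(back[as.character(gl$vlab_code)],
             data.frame(from = gl$edge_from, to = gl$edge_to,
                        order = BOND_ORDERS[gl$edge_lab]))
  })
}

#' Generate a fixture from a specification
#'
#' Fixture specs are plain lists (`kind`, `n`, label/seed fields) and can be
#' stored as JSON for reproducible suites ([fixtures_from_json()]).
#'
#' @param spec list with `kind` in `path`, `cycle`, `star`, `binary_chain`,
#'   `random_tree`, `peptide`, `named`, plus the fields that kind needs.
#' @return a `molgraph`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$kind))
  switch(spec$kind,
    path = mg_path(spec$n, spec$element %||% "C", spec$orders %||% "single"),
    cycle = mg_cycle(spec$n, spec$element %||% "C", spec$orders %||% "single"),
    star = mg_star(spec$n, spec$element %||% "C", spec$orders %||% "single"),
    binary_chain = mg_binary_chain(spec$n, spec$value),
    random_tree = mg_random_tree(spec$n, spec$elements %||% c("C", "N"),
                                 spec$orders %||% c("single", "double"),
                                 spec$seed %||% 1),
    peptide = peptide(spec$code),
    named = named_molecule(spec$name),
    stop("unknown fixture kind: ", spec$kind))
}

#' @rdname generate_fixture
#' @param path JSON file holding a list of fixture specs.
#' @export
fixtures_from_json <- function(path) {
  specs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(specs, generate_fixture)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
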