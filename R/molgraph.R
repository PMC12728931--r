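# Molecular-graph data model, chemical file parsing, label conventions and
# bond-level preprocessing.

BOND_ORDERS <- c("single", "double", "triple", "aromatic")

# atomic numbers for the element symbols this package accepts
ELEMENT_CODES <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L,
  Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L, S = 16L,
  Cl = 17L, Ar = 18L, K = 19L, Ca = 20L, Ti = 22L, Cr = 24L, Mn = 25L,
  Fe = 26L, Co = 27L, Ni = 28L, Cu = 29L, Zn = 30L, Ga = 31L, Ge = 32L,
  As = 33L, Se = 34L, Br = 35L, Kr = 36L, Rb = 37L, Sr = 38L, Mo = 42L,
  Ru = 44L, Rh = 45L, Pd = 46L, Ag = 47L, Cd = 48L, Sn = 50L, Sb = 51L,
  Te = 52L, I = 53L, Xe = 54L, Cs = 55L, Ba = 56L, W = 74L, Pt = 78L,
  Au = 79L, Hg = 80L, Pb = 82L, Bi = 83L
)

#' Construct a molecular graph
#'
#' A hydrogen-suppressed vertex/edge-labelled graph. Vertices carry an element
#' symbol (and a formal charge, ignored by default in all labelling);
#' edges carry a bond-order category, with aromatic bonds their own category.
#' Edge indices follow the supplied order and are stable for the lifetime of
#' the object: every edge mask in the package refers to this fixed indexing.
#'
#' @param elements character vector of element symbols (no hydrogens).
#' @param bonds data frame or matrix with columns `from`, `to` (1-based vertex
#'   indices) and `order` (one of `"single"`, `"double"`, `"triple"`,
#'   `"aromatic"`, or the integer codes 1:4).
#' @param charges integer vector of formal charges (default 0).
#' @param aromatic_atoms logical vector marking atoms written in aromatic
#'   form (display/kekulisation metadata; atom labels are element-only).
#' @return an object of class `molgraph`.
#' @export
molgraph <- function(elements, bonds = NULL, charges = 0L,
                     aromatic_atoms = FALSE) {
  elements <- as.character(elements)
  if (any(elements == "H"))
    stop("hydrogens must not appear as vertices of a molgraph")
  unknown <- setdiff(unique(elements), names(ELEMENT_CODES))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  n <- length(elements)
  charges <- rep_len(as.integer(charges), n)
  aromatic_atoms <- rep_len(as.logical(aromatic_atoms), n)

  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- data.frame(from = integer(), to = integer(),
                        order = character(), stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    stopifnot(all(c("from", "to", "order") %in% names(bonds)))
    bonds$from <- as.integer(bonds$from)
    bonds$to <- as.integer(bonds$to)
    if (is.numeric(bonds$order)) bonds$order <- BOND_ORDERS[bonds$order]
    if (!all(bonds$order %in% BOND_ORDERS))
      stop("bond orders must be one of: ", paste(BOND_ORDERS, collapse = ", "))
    if (any(bonds$from < 1 | bonds$from > n | bonds$to < 1 | bonds$to > n))
      stop("bond endpoint out of range")
    if (any(bonds$from == bonds$to)) stop("self-loops are not allowed")
    key <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
    if (anyDuplicated(key)) stop("at most one bond per vertex pair")
  }
  g <- structure(
    list(elements = elements, charges = charges,
         aromatic_atoms = aromatic_atoms, bonds = bonds),
    class = "molgraph")
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d atoms, %d bonds, %d component(s)\n",
              length(x$elements), n_edges(x), n_components(x)))
  if (n_edges(x) > 0) {
    tab <- table(bond_labels(x))
    cat("  bond labels: ",
        paste(sprintf("%s x%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of bonds of a molecular graph
#' @param g a `molgraph`.
#' @export
n_edges <- function(g) nrow(g$bonds)

#' Number of edge-bearing connected components
#'
#' Isolated atoms carry no edges and do not count here; this is the `c` in
#' the assembly-index formula MA = N - c - S.
#' @param g a `molgraph`.
#' @export
n_components <- function(g) {
  if (n_edges(g) == 0) return(0L)
  length(cpp_components(mg_to_cpp(g), rep(TRUE, n_edges(g))))
}

# canonical bond-label strings: unordered element pair + order
bond_labels <- function(g) {
  if (n_edges(g) == 0) return(character())
  e1 <- g$elements[g$bonds$from]
  e2 <- g$elements[g$bonds$to]
  paste0(pmin(e1, e2), "-", pmax(e1, e2), ":", g$bonds$order)
}

# compact representation handed to the compiled core
mg_to_cpp <- function(g, charge_labels = FALSE) {
  code <- unname(ELEMENT_CODES[g$elements])
  if (charge_labels) code <- code * 32L + (g$charges + 8L)
  list(vlab_code = as.integer(code),
       edge_from = as.integer(g$bonds$from),
       edge_to = as.integer(g$bonds$to),
       edge_lab = as.integer(match(g$bonds$order, BOND_ORDERS)))
}

#' Delete all unique bonds
#'
#' A bond whose label (unordered element pair plus bond order) occurs only
#' once cannot be part of any duplicatable subgraph, so the duplicate
#' enumeration never needs to consider it. Single pass on bond-label
#' multiplicity; removed bonds still count towards N in the assembly-index
#' formula.
#'
#' @param g a `molgraph`.
#' @return logical edge mask of retained bonds (length `n_edges(g)`).
#' @export
remove_unique_bonds <- function(g) {
  lab <- bond_labels(g)
  tab <- table(lab)
  as.logical(as.vector(tab[lab]) >= 2)
}

#' Connected components of an edge mask
#'
#' Partitions the set bits of `mask` into edge sets of connected subgraphs
#' via union-find over the endpoints (disjoint-set construction and
#' splitting). Components are ordered by their smallest contained edge index.
#'
#' @param g a `molgraph`.
#' @param mask logical edge mask (defaults to all edges).
#' @return list of logical edge masks.
#' @export
connected_components <- function(g, mask = rep(TRUE, n_edges(g))) {
  stopifnot(length(mask) == n_edges(g))
  if (!any(mask)) return(list())
  comps <- cpp_components(mg_to_cpp(g), as.logical(mask))
  lapply(comps, function(idx) {
    m <- rep(FALSE, n_edges(g))
    m[idx] <- TRUE
    m
  })
}

#' @rdname connected_components
#' @export
disjoint_set_split <- connected_components

#' Disjoint union of molecular graphs
#'
#' Joins several molecules into one graph with disjoint components and
#' re-indexed edges; the building-block alphabet of a joint assembly space is
#' the union of the members' atom and bond types.
#'
#' @param mols list of `molgraph` objects (at least one).
#' @return a `molgraph`.
#' @export
join_graphs <- function(mols) {
  if (is.null(mols) || length(mols) == 0) stop("need at least one molecule")
  stopifnot(all(vapply(mols, inherits, TRUE, "molgraph")))
  if (length(mols) == 1) return(mols[[1]])
  off <- 0L
  elements <- character()
  charges <- integer()
  arom <- logical()
  bonds <- NULL
  for (m in mols) {
    elements <- c(elements, m$elements)
    charges <- c(charges, m$charges)
    arom <- c(arom, m$aromatic_atoms)
    if (n_edges(m) > 0) {
      b <- m$bonds
      b$from <- b$from + off
      b$to <- b$to + off
      bonds <- rbind(bonds, b)
    }
    off <- off + length(m$elements)
  }
  molgraph(elements, bonds, charges, arom)
}
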