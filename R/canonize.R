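# Isomorphism testing and canonical keys for fragments. A fragment is a
# (graph, logical edge mask) pair and must be connected.

as_mask <- function(g, mask) {
  if (is.numeric(mask)) {
    m <- rep(FALSE, n_edges(g))
    m[mask] <- TRUE
    m
  } else {
    stopifnot(length(mask) == n_edges(g))
    as.logical(mask)
  }
}

#' Is a connected fragment acyclic?
#'
#' True iff the fragment's edge count equals its vertex count minus one.
#'
#' @param g a `molgraph`.
#' @param mask logical edge mask or integer edge indices (default all edges).
#' @export
is_acyclic <- function(g, mask = rep(TRUE, n_edges(g))) {
  m <- as_mask(g, mask)
  if (!cpp_is_connected(mg_to_cpp(g), m))
    stop("fragment must be connected")
  cpp_is_acyclic(mg_to_cpp(g), m)
}

#' Canonical key of an acyclic fragment
#'
#' Rooted-at-centre canonical string carrying atom and bond labels: two
#' acyclic fragments get equal keys iff they are isomorphic as labelled
#' graphs. For double-centre trees the lexicographically smaller of the two
#' centre-rooted encodings is used.
#'
#' @inheritParams is_acyclic
#' @return character key.
#' @export
tree_key <- function(g, mask = rep(TRUE, n_edges(g))) {
  m <- as_mask(g, mask)
  if (!is_acyclic(g, m)) stop("tree_key requires an acyclic fragment")
  cpp_tree_key(mg_to_cpp(g), m)
}

#' Label-preserving isomorphism of two connected fragments
#'
#' Backtracking search with degree and label pruning; used to resolve cyclic
#' fragments whose invariant bucket keys collide.
#'
#' @param g1,g2 `molgraph` objects.
#' @param m1,m2 edge masks (logical or indices) selecting the fragments.
#' @export
cyclic_isomorphic <- function(g1, m1, g2, m2) {
  cpp_isomorphic(mg_to_cpp(g1), as_mask(g1, m1),
                 mg_to_cpp(g2), as_mask(g2, m2))
}

#' Class key of a connected fragment
#'
#' Equal keys identify the isomorphism class exactly for acyclic fragments
#' (tree canonical form); for cyclic fragments the key is an invariant bucket
#' (label multiset, degree sequence, edge count, cycle rank) and equal keys
#' are necessary but not sufficient -- final class identity is resolved with
#' [cyclic_isomorphic()] inside the bucket.
#'
#' @inheritParams is_acyclic
#' @export
class_key <- function(g, mask = rep(TRUE, n_edges(g))) {
  m <- as_mask(g, mask)
  if (!cpp_is_connected(mg_to_cpp(g), m))
    stop("fragment must be connected")
  cpp_class_key(mg_to_cpp(g), m)
}
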