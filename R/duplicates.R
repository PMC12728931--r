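# Enumeration of duplicatable subgraph classes and valid occurrence pairs.

#' Enumerate duplicatable subgraphs
#'
#' Breadth-wise growth from 2-edge connected subgraphs of the preprocessed
#' graph (after [remove_unique_bonds()]), one adjacent edge at a time.
#' Occurrences are grouped into isomorphism classes ([class_key()] plus
#' explicit matching inside cyclic buckets); only classes with at least two
#' occurrences are kept and grown further. Classes are linked parent-to-child
#' by one-edge growth (first parent encountered), forming the duplicate DAG.
#' The enumeration is performed once per molecule and reused across all
#' search passes.
#'
#' @param g a `molgraph`.
#' @return an object of class `duplicate_enumeration`: a list with
#'   `classes` (each with `k`, `key`, `matchable`, `parent`, `occurrences`
#'   as lists of edge-index vectors, and `rank`), `order` (class ids sorted
#'   by size descending then key), `retained` and `cover` logical masks.
#' @export
enumerate_duplicates <- function(g) {
  en <- cpp_enumerate(mg_to_cpp(g))
  rank <- integer(length(en$classes))
  rank[en$order] <- seq_along(en$order)
  for (i in seq_along(en$classes)) en$classes[[i]]$rank <- rank[i]
  en$n_edges <- n_edges(g)
  class(en) <- "duplicate_enumeration"
  en
}

#' @export
print.duplicate_enumeration <- function(x, ...) {
  nm <- sum(vapply(x$classes, `[[`, TRUE, "matchable"))
  cat(sprintf("<duplicate_enumeration> %d classes (%d matchable), sizes %s\n",
              length(x$classes), nm,
              paste(sort(unique(vapply(x$classes, `[[`, 1L, "k"))),
                    collapse = ",")))
  invisible(x)
}

mask_from_idx <- function(idx, n) {
  m <- rep(FALSE, n)
  m[idx] <- TRUE
  m
}

# lexicographic comparison of two sorted edge-index vectors (pair ordering)
idx_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

#' Valid occurrence pairs of a duplicate class in a state
#'
#' A pair of occurrences is a valid match when the two edge masks do not
#' overlap and each occurrence lies entirely inside a single fragment of the
#' current state (possibly different fragments -- cross-fragment matches are
#' what make joint assembly spaces work). Vertex sharing is allowed: validity
#' is defined purely on edge sets. Pairs are order-normalised.
#'
#' @param class one element of `enumerate_duplicates(g)$classes`.
#' @param fragments list of edge-index vectors (the state's fragments).
#' @return list of pairs, each `list(a =, b =)` of edge-index vectors.
#' @export
valid_pairs <- function(class, fragments) {
  occ <- class$occurrences
  contained <- vapply(occ, function(o) {
    any(vapply(fragments, function(f) all(o %in% f), TRUE))
  }, TRUE)
  idx <- which(contained)
  out <- list()
  if (length(idx) < 2) return(out)
  for (x in seq_along(idx)) {
    for (y in seq_along(idx)) {
      if (y <= x) next
      a <- occ[[idx[x]]]
      b <- occ[[idx[y]]]
      if (length(intersect(a, b)) > 0) next
      if (!idx_less(a, b)) { tmp <- a; a <- b; b <- tmp }
      out[[length(out) + 1]] <- list(a = a, b = b)
    }
  }
  out
}

#' Available duplicates of a state
#'
#' All matchable (class, pair) options permitted by the monotone-order rule:
#' along any pathway, duplicate sizes never increase, so only classes no
#' larger than the most recently removed duplicate are offered. Options are
#' ordered by the global class order (size descending, then key); the first
#' option's size is the state's m, the cap entering the conditional
#' addition-chain bound.
#'
#' @param enum a `duplicate_enumeration`.
#' @param fragments list of edge-index vectors.
#' @param max_rank rank of the state's last-removed class (`Inf` for the
#'   initial state).
#' @return list of `list(class =, pair =)` options.
#' @export
available_duplicates <- function(enum, fragments, max_rank = Inf) {
  out <- list()
  last_k <- if (is.infinite(max_rank)) Inf else {
    cl <- enum$classes[[enum$order[max_rank]]]
    cl$k
  }
  for (cid in enum$order) {
    cl <- enum$classes[[cid]]
    if (!cl$matchable || cl$k > last_k) next
    for (p in valid_pairs(cl, fragments)) {
      out[[length(out) + 1]] <- list(class = cl, pair = p)
    }
  }
  out
}
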