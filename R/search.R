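# Top-down assembly-state search: fragmentation by disjoint-set splitting,
# dynamic programming over hashed states, branch-and-bound, anytime results
# and pathway reconstruction.

#' Compute the molecular assembly index
#'
#' Exact top-down search for the fragmentation pathway with the maximum
#' duplicate sum S. Starting from the whole molecule, each step removes a
#' duplicatable subgraph: both edge-disjoint occurrences are deleted and one
#' copy of the duplicate is kept as a new fragment, saving k-1 joining
#' operations for a k-edge duplicate. The assembly index is
#' `MA = N - c - max(S)` with N the number of bonds and c the number of
#' edge-bearing components.
#'
#' Three heuristics prune the recursion without affecting exactness:
#' duplicates are processed largest-first and sizes never increase along a
#' pathway; identical assembly states are hashed and re-expanded only with a
#' strictly higher S; and states are discarded when the conditional
#' addition-chain bound shows they cannot beat the best S found. On budget
#' expiry the best bound found so far is returned with `converged = FALSE`
#' (anytime semantics); the improvement trace is always recorded.
#'
#' @param mol a [molgraph()] (or a SMILES string, parsed with defaults).
#' @param timeout wall-clock budget in seconds.
#' @param max_states cap on expanded search states (`Inf` for none).
#' @param use_bound,use_table disable individual heuristics (diagnostics;
#'   the result must not change, only the work done).
#' @param charge_labels include formal charges in atom labels (default:
#'   element-only labels).
#' @return an object of class `assembly_result`.
#' @export
#' @examples
#' r <- assembly_index(parse_smiles("OC(=O)c1ccccc1"))
#' r$ma  # 6
assembly_index <- function(mol, timeout = 600, max_states = Inf,
                           use_bound = TRUE, use_table = TRUE,
                           charge_labels = FALSE) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "molgraph"))
  if (timeout <= 0) stop("budget must be positive")
  res <- cpp_search(mg_to_cpp(mol, charge_labels = charge_labels),
                    use_bound, use_table, as.numeric(timeout),
                    if (is.infinite(max_states)) -1 else as.numeric(max_states))
  out <- list(
    ma = res$ma,
    best_s = res$best_s,
    converged = res$converged,
    n_bonds = res$n_edges,
    n_components = res$n_components,
    trace = data.frame(elapsed = res$trace_time, ma_upper = res$trace_ma),
    pathway = res$pathway,
    final_fragments = res$final_fragments,
    stats = res$stats,
    molecule = mol)
  class(out) <- "assembly_result"
  out
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("Molecular assembly index: %d (%s)\n", x$ma,
              if (x$converged) "exact" else "upper bound, budget expired"))
  cat(sprintf("  bonds N = %d, components c = %d, duplicate sum S = %d\n",
              x$n_bonds, x$n_components, x$best_s))
  cat(sprintf("  pathway: %d removal step(s); states expanded: %s\n",
              length(x$pathway),
              format(x$stats$states_expanded, big.mark = ",")))
  invisible(x)
}

#' @export
summary.assembly_result <- function(object, ...) {
  x <- object
  print(x)
  if (length(x$pathway)) {
    ks <- vapply(x$pathway, `[[`, 1L, "k")
    cat("  removal sizes:", paste(ks, collapse = ", "),
        sprintf("(sum of k-1: %d)\n", sum(ks - 1L)))
  }
  cat(sprintf("  pruned by bound: %s, pruned by state table: %s\n",
              format(x$stats$pruned_bound, big.mark = ","),
              format(x$stats$pruned_table, big.mark = ",")))
  invisible(x)
}

#' Plot the anytime trace of an assembly search
#'
#' Step plot of the best (lowest) MA upper bound against elapsed time; the
#' final level equals the exact MA when the search converged.
#'
#' @param x an `assembly_result`.
#' @param ... passed to [plot()].
#' @export
plot.assembly_result <- function(x, ...) {
  tr <- x$trace
  plot(tr$elapsed, tr$ma_upper, type = "s", xlab = "elapsed (s)",
       ylab = "MA upper bound",
       main = if (x$converged) "Assembly search (converged)"
              else "Assembly search (budget expired)", ...)
  graphics::points(tr$elapsed, tr$ma_upper, pch = 16, cex = 0.6)
  invisible(x)
}

#' Apply a duplicate removal to an assembly state
#'
#' Deletes the edges of both occurrences of the pair from their fragments,
#' splits the remnants into connected components (union-find), and prepends
#' one copy of the duplicate as the new first fragment. Single-edge remnants
#' are building blocks and are not stored. `S` grows by k-1.
#'
#' @param g the `molgraph` the state lives on.
#' @param state list with `fragments` (list of edge-index vectors, first =
#'   last-removed duplicate), `S`, and optionally `last_k`.
#' @param pair a pair `list(a =, b =)` of edge-index vectors (see
#'   [valid_pairs()]).
#' @return the child state.
#' @export
apply_removal <- function(g, state, pair) {
  a <- sort(pair$a)
  b <- sort(pair$b)
  if (length(intersect(a, b)) > 0) stop("occurrence pair overlaps")
  ok_a <- any(vapply(state$fragments, function(f) all(a %in% f), TRUE))
  ok_b <- any(vapply(state$fragments, function(f) all(b %in% f), TRUE))
  if (!ok_a || !ok_b)
    stop("both occurrences must lie inside single fragments of the state")
  del <- c(a, b)
  frags <- list(a)
  for (f in state$fragments) {
    rem <- setdiff(f, del)
    if (length(rem) == length(f)) {
      frags[[length(frags) + 1]] <- f
      next
    }
    if (length(rem) == 0) next
    comps <- connected_components(g, mask_from_idx(rem, n_edges(g)))
    for (cm in comps) {
      idx <- which(cm)
      if (length(idx) >= 2) frags[[length(frags) + 1]] <- idx
    }
  }
  tail <- frags[-1]
  if (length(tail) > 1) {
    ord <- order(vapply(tail, function(f) paste(sprintf("%04d", f), collapse = ""),
                        ""))
    tail <- tail[ord]
  }
  list(fragments = c(frags[1], tail), S = state$S + length(a) - 1L,
       last_k = length(a))
}

#' Hash key of an assembly state
#'
#' Sequence hash over per-fragment keys with the first element (the
#' last-removed duplicate) kept out of the sorting: permuting the remaining
#' fragments does not change the key, changing the first element does.
#'
#' @param state list with `fragments` (list of edge-index vectors).
#' @return character key.
#' @export
hash_state <- function(state) {
  enc <- vapply(state$fragments, function(f)
    paste(sort(f), collapse = "."), "")
  paste(enc[1], paste(sort(enc[-1]), collapse = "|"), sep = "||")
}

#' Initial assembly state of a molecule
#'
#' Fragments are the edge-bearing connected components (single-edge
#' components are building blocks and are dropped), S = 0, no size cap.
#'
#' @param g a `molgraph`.
#' @export
initial_state <- function(g) {
  comps <- connected_components(g)
  frags <- list()
  for (cm in comps) {
    idx <- which(cm)
    if (length(idx) >= 2) frags[[length(frags) + 1]] <- idx
  }
  list(fragments = frags, S = 0L, last_k = Inf)
}

#' Serialise an assembly result as JSON
#'
#' Schema-stable JSON document: `ma`, `best_s`, `converged`, `n_bonds`,
#' `n_components`, the anytime `trace`, the reconstructed `pathway`
#' (duplicate and remnant edge lists per step) and search `stats` (timing
#' and work counters are segregated here so result comparison can exclude
#' them).
#'
#' @param x an `assembly_result`.
#' @param pretty pretty-print.
#' @return JSON string.
#' @export
as_assembly_json <- function(x, pretty = FALSE) {
  stopifnot(inherits(x, "assembly_result"))
  doc <- list(
    ma = x$ma, best_s = x$best_s, converged = x$converged,
    n_bonds = x$n_bonds, n_components = x$n_components,
    trace = x$trace,
    pathway = lapply(x$pathway, function(st) list(
      k = st$k,
      duplicate_edges = st$duplicate,
      partner_edges = st$partner,
      remnant_edges = st$remnants)),
    stats = x$stats)
  jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = pretty)
}
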