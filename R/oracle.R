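# Independent brute-force oracles for the exactness claims of the search.

#' Brute-force assembly index
#'
#' Exhaustive top-down removal search with none of the production search's
#' heuristics: no size ordering, no addition-chain bound, no state table --
#' only the trivial completeness of the recursion. Exponential, so capped.
#'
#' @param g a `molgraph` (or SMILES string).
#' @param max_edges hard size cap (default 12 edges).
#' @export
#' @examples
#' oracle_ma(mg_path(4))  # 2
oracle_ma <- function(g, max_edges = 12) {
  if (is.character(g)) g <- parse_smiles(g)
  if (n_edges(g) > max_edges)
    stop("oracle size cap exceeded (", n_edges(g), " > ", max_edges, " edges)")
  cpp_oracle_ma(mg_to_cpp(g), as.integer(max_edges))
}

#' Brute-force best duplicate sum under a size cap
#'
#' Exhaustive restricted search: the best achievable S when no duplicate
#' larger than `cap_k` edges may be removed. Used to verify admissibility of
#' the conditional addition-chain bound.
#'
#' @param g a `molgraph`.
#' @param cap_k duplicate-size cap (0 for unrestricted).
#' @param max_edges hard size cap.
#' @export
oracle_best_s <- function(g, cap_k = 0, max_edges = 12) {
  if (is.character(g)) g <- parse_smiles(g)
  if (n_edges(g) > max_edges)
    stop("oracle size cap exceeded (", n_edges(g), " > ", max_edges, " edges)")
  cpp_oracle_best_s(mg_to_cpp(g), as.integer(cap_k), as.integer(max_edges))
}

#' Bulk oracle-equivalence check on exhaustive small graphs
#'
#' Generates all connected labelled graphs up to `max_edges` over the given
#' alphabet and compares the optimised search MA against the brute-force
#' oracle MA on every one; optionally also re-runs the search with the
#' branch-and-bound and/or the state table disabled, which must never change
#' the result.
#'
#' @param max_edges maximum edge count (<= 7).
#' @param elements,orders label alphabets.
#' @param check_variants also run the heuristic-disabled searches.
#' @return list with `n_graphs`, `per_level` counts, `n_mismatch`,
#'   `n_variant_mismatch`, and up to 10 mismatch `examples`.
#' @export
check_oracle_equivalence <- function(max_edges = 7,
                                     elements = c("C", "N"),
                                     orders = c("single", "double"),
                                     check_variants = FALSE) {
  stopifnot(max_edges <= 7)
  codes <- unname(ELEMENT_CODES[elements])
  cpp_check_equivalence(as.integer(max_edges), as.integer(codes),
                        as.integer(match(orders, BOND_ORDERS)),
                        check_variants, 2e6)
}

#' Bound admissibility over every reachable state of a graph
#'
#' Enumerates all assembly states reachable by the unrestricted removal
#' recursion and checks, for every state and every duplicate-size cap m up
#' to the largest fragment, that the exhaustive restricted best S never
#' exceeds [conditional_smax_bound()].
#'
#' @param g a `molgraph` (or SMILES string).
#' @param max_edges hard size cap.
#' @return list with `n_states`, `n_checks`, `n_violations`.
#' @export
check_bound_admissibility <- function(g, max_edges = 12) {
  if (is.character(g)) g <- parse_smiles(g)
  cpp_check_admissibility(mg_to_cpp(g), as.integer(max_edges))
}

#' Verify exact assembly indices for a supplied reference set
#'
#' Slow-suite runner for benchmarking against externally supplied structures
#' (e.g. drug molecules given as SMILES): computes each MA to convergence
#' under the budget and compares with the expected value where one is given.
#'
#' @param structures named character vector of SMILES.
#' @param expected named numeric vector of expected MAs (NA to skip the
#'   comparison for a structure).
#' @param timeout per-molecule budget in seconds.
#' @return data frame with name, n_bonds, ma, converged, expected, ok.
#' @export
run_reference_set <- function(structures, expected = NULL, timeout = 3600) {
  stopifnot(length(structures) >= 1, !is.null(names(structures)))
  rows <- lapply(names(structures), function(nm) {
    g <- parse_smiles(structures[[nm]])
    r <- assembly_index(g, timeout = timeout)
    exp_ma <- if (!is.null(expected) && nm %in% names(expected))
      expected[[nm]] else NA_real_
    data.frame(name = nm, n_bonds = n_edges(g), ma = r$ma,
               converged = r$converged, expected = exp_ma,
               ok = if (is.na(exp_ma)) NA else r$ma == exp_ma,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
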