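# Conditional addition-chain bounds used by the branch-and-bound search.

#' Smallest t with 2^t >= n
#' @param n positive integer.
#' @export
ceil_log2 <- function(n) {
  stopifnot(length(n) == 1, n >= 1)
  cpp_ceil_log2(as.numeric(n))
}

#' Exact minimal addition-chain length l(n)
#'
#' Iterative-deepening search over ascending addition chains. Finding the
#' assembly index of a uniform chain of n bonds (one atom and bond type) is
#' the same problem, which makes this an independent cross-check for the
#' graph search.
#'
#' @param n positive integer (capped at 4096).
#' @export
#' @examples
#' addition_chain_length(15)  # 5
addition_chain_length <- function(n) {
  stopifnot(length(n) == 1, n >= 1)
  cpp_addition_chain_length(as.integer(n))
}

#' Single-fragment conditional bound
#'
#' Maximum duplicate sum S achievable for one fragment of `L` edges when no
#' duplicate larger than `m` may be removed:
#' `L - ceiling(L/m) - ceil_log2(m)`. May be negative; callers clamp at zero.
#'
#' @param L fragment size (edges), `L >= 1`.
#' @param m duplicate-size cap, `m >= 2`.
#' @export
chain_bound_single <- function(L, m) {
  stopifnot(L >= 1, m >= 2)
  cpp_chain_bound_single(as.integer(L), as.integer(m))
}

#' Multi-fragment conditional addition-chain bound
#'
#' Upper bound on the residual duplicate sum S of an assembly state whose
#' fragments have sizes `sizes` when every later duplicate has at most `m`
#' edges: the best over chain caps x in 2..m of
#' `-ceil_log2(x) + sum(L_i - ceiling(L_i/x))`, clamped at zero. The
#' logarithmic construction term is shared across fragments (it is paid
#' once). This is the pruning bound of the search: a state is discarded when
#' `S + bound <= best_S` found so far.
#'
#' @param sizes integer vector of fragment edge counts.
#' @param m duplicate-size cap (`m >= 2`; smaller caps give bound 0).
#' @export
conditional_smax_bound <- function(sizes, m) {
  if (length(sizes) == 0 || m < 2) return(0L)
  cpp_conditional_smax_bound(as.integer(sizes), as.integer(m))
}

#' Two-part refined conditional bound
#'
#' Splits the bonds of a state into the `Lm` bonds coverable by duplicates of
#' size exactly `m` (bounded with cap m) and the remainder (bounded with cap
#' m-1), sharing the single logarithmic term. Degenerate cases reduce to
#' [conditional_smax_bound()] at cap m (when `Lm` is everything) or cap m-1
#' (when `Lm = 0`).
#'
#' @param sizes integer vector of fragment edge counts.
#' @param m duplicate-size cap.
#' @param Lm total bonds coverable at size m, `0 <= Lm <= sum(sizes)`.
#' @export
refined_split_bound <- function(sizes, m, Lm) {
  cpp_refined_split_bound(as.integer(sizes), as.integer(m), as.integer(Lm))
}
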