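#pragma once

#include <vector>
#include "canon.h"

// Exhaustive top-down removal search: no size ordering, no addition-chain
// bound, no state table. Correct by trivial completeness of the recursion;
// independent of the optimised search's heuristics. `cap_k` restricts the
// duplicate size (<=0 means unrestricted). Throws if `max_edges` exceeded.
int oracle_best_s(const Graph& g, int cap_k, int max_edges);
int oracle_ma(const Graph& g, int max_edges);

// restricted best S from an arbitrary fragment list (used for admissibility
// checks of the conditional bound)
int oracle_best_s_frags(const Graph& g, const std::vector<Mask>& frags,
                        int cap_k);

// all connected subgraphs (>= 2 edges, optionally capped) of one fragment
std::vector<Mask> oracle_subgraphs(const Graph& g, const Mask& frag,
                                   int cap_k);
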