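#pragma once

#include <string>
#include "graph.h"

// Fragment canonisation / isomorphism. A fragment is (graph, edge mask) and is
// assumed connected wherever stated.

// true iff the connected fragment has edge count == vertex count - 1
bool frag_is_acyclic(const Graph& g, const Mask& m);

// true iff the fragment's set bits form one connected subgraph (>=1 edge)
bool frag_is_connected(const Graph& g, const Mask& m);

// Canonical string for a connected acyclic fragment: rooted-at-centre AHU
// encoding carrying both atom and bond labels. Equal keys <=> labelled
// isomorphism for trees.
std::string frag_tree_key(const Graph& g, const Mask& m);

// Invariant bucket key for any connected fragment (label multiset, degree
// sequence, edge count, cycle rank). Equal keys are necessary but not
// sufficient for isomorphism of cyclic fragments.
std::string frag_bucket_key(const Graph& g, const Mask& m);

// "T:" + tree key when acyclic, "C:" + bucket key otherwise.
std::string frag_class_key(const Graph& g, const Mask& m);

// Label-preserving graph isomorphism between two connected fragments
// (possibly from different graphs), by backtracking with degree/label pruning.
bool frag_isomorphic(const Graph& g1, const Mask& m1,
                     const Graph& g2, const Mask& m2);

#include <unordered_map>

// Interned AHU codes: an exact, allocation-light alternative to the string
// tree key, used by the exhaustive small-graph generator where millions of
// candidates must be deduplicated. Equal codes <=> equal canonical trees.
struct AhuIntern {
  std::unordered_map<std::string, uint32_t> tab;
  uint32_t intern(const std::string& key) {
    auto it = tab.find(key);
    if (it != tab.end()) return it->second;
    uint32_t id = (uint32_t)tab.size() + 1;
    tab.emplace(key, id);
    return id;
  }
};

// canonical integer code of a connected acyclic fragment
uint64_t frag_tree_code(const Graph& g, const Mask& m, AhuIntern& interner);
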