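#pragma once

#include <vector>
#include <array>
#include <stdexcept>
#include "mask.h"

// Hydrogen-suppressed vertex/edge-labelled molecular graph with a fixed edge
// indexing (input order). Vertex labels are integer atom-type codes (atomic
// numbers as supplied from R); edge labels are bond-order categories
// (1 single, 2 double, 3 triple, 4 aromatic).
struct Graph {
  int nv = 0;
  std::vector<int> vlab;                                  // size nv
  std::vector<int> eu, ev, elab;                          // size ne
  std::vector<std::vector<std::pair<int, int>>> adj;      // vertex -> (edge, other)

  int ne() const { return (int)eu.size(); }

  void add_edge(int u, int v, int lab) {
    eu.push_back(u);
    ev.push_back(v);
    elab.push_back(lab);
  }

  void build_adj() {
    adj.assign(nv, {});
    for (int e = 0; e < ne(); ++e) {
      adj[eu[e]].push_back({e, ev[e]});
      adj[ev[e]].push_back({e, eu[e]});
    }
  }

  Mask full_mask() const {
    Mask m;
    for (int e = 0; e < ne(); ++e) m.set(e);
    return m;
  }
};

// Edge-disjoint connected components of the edges in `m`, via union-find over
// the endpoints of set bits. Output is deterministic: components ordered by
// their smallest contained edge index.
std::vector<Mask> split_components(const Graph& g, const Mask& m);

// Number of edge-bearing connected components of the full graph.
int count_edge_components(const Graph& g);
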