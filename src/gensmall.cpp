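#include "gensmall.h"

#include <algorithm>
#include <map>
#include <stdexcept>
#include <unordered_map>

Mask retained_mask(const Graph& g) {
  std::map<std::array<int, 3>, int> mult;
  auto lab = [&](int e) {
    int la = g.vlab[g.eu[e]], lb = g.vlab[g.ev[e]];
    return std::array<int, 3>{std::min(la, lb), std::max(la, lb), g.elab[e]};
  };
  for (int e = 0; e < g.ne(); ++e) mult[lab(e)]++;
  Mask m;
  for (int e = 0; e < g.ne(); ++e)
    if (mult[lab(e)] >= 2) m.set(e);
  return m;
}

namespace {

// registry of one level's graphs, deduplicated: acyclic graphs by interned
// AHU tree code (exact), cyclic graphs by invariant bucket + explicit
// isomorphism
struct Registry {
  std::vector<Graph> graphs;
  std::unordered_map<uint64_t, int> tree_codes;
  std::unordered_map<std::string, std::vector<int>> buckets;
  AhuIntern* interner;

  explicit Registry(AhuIntern* it) : interner(it) {}

  bool insert(Graph&& g) {
    Mask full = g.full_mask();
    if (g.ne() == g.nv - 1) {
      uint64_t code = frag_tree_code(g, full, *interner);
      if (tree_codes.count(code)) return false;
      tree_codes.emplace(code, (int)graphs.size());
      g.build_adj();
      graphs.push_back(std::move(g));
      return true;
    }
    std::string key = frag_bucket_key(g, full);
    auto& ids = buckets[key];
    for (int id : ids)
      if (frag_isomorphic(graphs[id], graphs[id].full_mask(), g, full))
        return false;
    ids.push_back((int)graphs.size());
    g.build_adj();
    graphs.push_back(std::move(g));
    return true;
  }
};

}  // namespace

std::vector<Graph> gen_small_graphs(int max_edges,
                                    const std::vector<int>& vlabs,
                                    const std::vector<int>& elabs,
                                    long long max_graphs) {
  if (max_edges < 1) throw std::invalid_argument("max_edges must be >= 1");
  std::vector<Graph> all;
  AhuIntern interner;
  Registry level(&interner);
  // level 1: single labelled edges
  for (size_t i = 0; i < vlabs.size(); ++i) {
    for (size_t j = i; j < vlabs.size(); ++j) {
      for (int el : elabs) {
        Graph g;
        g.nv = 2;
        g.vlab = {vlabs[i], vlabs[j]};
        g.add_edge(0, 1, el);
        level.insert(std::move(g));
      }
    }
  }
  for (int k = 1; k <= max_edges; ++k) {
    for (const Graph& g : level.graphs) {
      all.push_back(g);
      if ((long long)all.size() > max_graphs)
        throw std::runtime_error("small-graph generation limit exceeded");
    }
    if (k == max_edges) break;
    Registry next(&interner);
    auto core = [](const Graph& g) {
      Graph h;
      h.nv = g.nv;
      h.vlab = g.vlab;
      h.eu = g.eu;
      h.ev = g.ev;
      h.elab = g.elab;
      return h;
    };
    for (const Graph& g : level.graphs) {
      // (a) close an edge between two existing non-adjacent vertices
      for (int u = 0; u < g.nv; ++u) {
        for (int v = u + 1; v < g.nv; ++v) {
          bool adjacent = false;
          for (auto& [e, w] : g.adj[u]) {
            (void)e;
            if (w == v) adjacent = true;
          }
          if (adjacent) continue;
          for (int el : elabs) {
            Graph h = core(g);
            h.add_edge(u, v, el);
            next.insert(std::move(h));
          }
        }
      }
      // (b) hang a new labelled vertex off an existing one
      for (int u = 0; u < g.nv; ++u) {
        for (int vl : vlabs) {
          for (int el : elabs) {
            Graph h = core(g);
            h.vlab.push_back(vl);
            h.nv++;
            h.add_edge(u, h.nv - 1, el);
            next.insert(std::move(h));
          }
        }
      }
    }
    level = std::move(next);
  }
  return all;
}
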