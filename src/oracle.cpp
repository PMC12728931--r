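#include "oracle.h"

#include <algorithm>
#include <stdexcept>
#include <unordered_map>
#include <unordered_set>

namespace {

// all connected subgraphs (>= 2 edges) of one fragment, by naive growth
void connected_subgraphs(const Graph& g, const Mask& frag, int cap_k,
                         std::vector<Mask>& out) {
  std::unordered_set<Mask, MaskHash> seen;
  std::vector<Mask> level;
  // seeds: adjacent edge pairs inside the fragment
  for (int v = 0; v < g.nv; ++v) {
    const auto& inc = g.adj[v];
    for (size_t i = 0; i < inc.size(); ++i) {
      if (!frag.get(inc[i].first)) continue;
      for (size_t j = i + 1; j < inc.size(); ++j) {
        if (!frag.get(inc[j].first)) continue;
        Mask m;
        m.set(inc[i].first);
        m.set(inc[j].first);
        if (seen.insert(m).second) level.push_back(m);
      }
    }
  }
  while (!level.empty()) {
    for (const Mask& m : level) out.push_back(m);
    if (cap_k > 0 && level[0].count() >= cap_k) break;
    std::vector<Mask> nxt;
    for (const Mask& m : level) {
      for (int e = 0; e < g.ne(); ++e) {
        if (!frag.get(e) || m.get(e)) continue;
        // adjacent iff an endpoint touches the subgraph
        bool adj = false;
        for (int e2 = 0; e2 < g.ne() && !adj; ++e2) {
          if (!m.get(e2)) continue;
          adj = g.eu[e] == g.eu[e2] || g.eu[e] == g.ev[e2] ||
                g.ev[e] == g.eu[e2] || g.ev[e] == g.ev[e2];
        }
        if (!adj) continue;
        Mask m2 = m;
        m2.set(e);
        if (seen.insert(m2).second) nxt.push_back(m2);
      }
    }
    level = std::move(nxt);
  }
}

int best_s_rec(const Graph& g, const std::vector<Mask>& frags, int cap_k) {
  // every connected subgraph of every fragment, grouped into isomorphism
  // classes: canonical tree keys are exact, cyclic fragments are compared
  // explicitly against the representatives sharing their invariant bucket
  std::vector<Mask> subs;
  for (const Mask& f : frags) connected_subgraphs(g, f, cap_k, subs);
  std::vector<std::vector<Mask>> classes;
  std::unordered_map<std::string, std::vector<int>> bykey;
  for (const Mask& s : subs) {
    std::string key = frag_class_key(g, s);
    auto& ids = bykey[key];
    bool placed = false;
    if (key[0] == 'T' && !ids.empty()) {
      classes[ids[0]].push_back(s);
      placed = true;
    } else {
      for (int id : ids) {
        if (frag_isomorphic(g, classes[id][0], g, s)) {
          classes[id].push_back(s);
          placed = true;
          break;
        }
      }
    }
    if (!placed) {
      ids.push_back((int)classes.size());
      classes.push_back({s});
    }
  }
  int best = 0;
  for (auto& cl : classes) {
    int k = cl[0].count();
    for (size_t i = 0; i < cl.size(); ++i) {
      for (size_t j = 0; j < cl.size(); ++j) {
        if (i == j || !cl[i].disjoint(cl[j])) continue;
        // delete both occurrences, keep a copy (cl[i]) as a new fragment;
        // iterating ordered pairs means either member may be the copy
        Mask del = cl[i] | cl[j];
        std::vector<Mask> child{cl[i]};
        for (const Mask& f : frags) {
          if (f.disjoint(del)) {
            if (f.count() >= 2) child.push_back(f);
            continue;
          }
          Mask rem = f.and_not(del);
          if (rem.empty()) continue;
          for (const Mask& comp : split_components(g, rem))
            if (comp.count() >= 2) child.push_back(comp);
        }
        int s = (k - 1) + best_s_rec(g, child, cap_k);
        best = std::max(best, s);
      }
    }
  }
  return best;
}

}  // namespace

int oracle_best_s_frags(const Graph& g, const std::vector<Mask>& frags,
                        int cap_k) {
  return best_s_rec(g, frags, cap_k);
}

std::vector<Mask> oracle_subgraphs(const Graph& g, const Mask& frag,
                                   int cap_k) {
  std::vector<Mask> out;
  connected_subgraphs(g, frag, cap_k, out);
  return out;
}

int oracle_best_s(const Graph& g, int cap_k, int max_edges) {
  if (g.ne() > max_edges)
    throw std::invalid_argument("oracle size cap exceeded");
  std::vector<Mask> frags;
  for (const Mask& c : split_components(g, g.full_mask()))
    if (c.count() >= 2) frags.push_back(c);
  return best_s_rec(g, frags, cap_k);
}

int oracle_ma(const Graph& g, int max_edges) {
  int c_eff = count_edge_components(g);
  return g.ne() - c_eff - oracle_best_s(g, 0, max_edges);
}
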