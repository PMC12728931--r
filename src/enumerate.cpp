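#include "enumerate.h"

#include <algorithm>
#include <unordered_map>
#include <unordered_set>

namespace {

// classify a fragment mask into the class registry; creates the class if new.
// Cyclic bucket collisions are resolved by explicit isomorphism against each
// class representative (first occurrence).
int classify(const Graph& g, const Mask& m,
             std::vector<DupClass>& classes,
             std::unordered_map<std::string, std::vector<int>>& buckets,
             int parent_class) {
  std::string key = frag_class_key(g, m);
  bool exact = key[0] == 'T';  // tree keys are exact class identifiers
  auto& ids = buckets[key];
  if (exact) {
    if (!ids.empty()) {
      classes[ids[0]].occ.push_back(m);
      return ids[0];
    }
  } else {
    for (int id : ids) {
      if (frag_isomorphic(g, classes[id].occ[0], g, m)) {
        classes[id].occ.push_back(m);
        return id;
      }
    }
  }
  DupClass c;
  c.id = (int)classes.size();
  c.k = m.count();
  c.key = key;
  c.occ.push_back(m);
  c.parent = parent_class;
  classes.push_back(std::move(c));
  ids.push_back((int)classes.size() - 1);
  return (int)classes.size() - 1;
}

}  // namespace

Enumeration enumerate_dups(const Graph& g, const Mask& retained) {
  Enumeration en;
  en.retained = retained;

  std::vector<DupClass>& classes = en.classes;
  std::unordered_map<std::string, std::vector<int>> buckets;

  // level 2: all connected 2-edge subgraphs (adjacent retained edge pairs)
  std::unordered_set<Mask, MaskHash> seen;
  std::vector<int> level;  // class ids created/fed this level
  std::unordered_set<int> level_set;
  for (int v = 0; v < g.nv; ++v) {
    const auto& inc = g.adj[v];
    for (size_t i = 0; i < inc.size(); ++i) {
      if (!retained.get(inc[i].first)) continue;
      for (size_t j = i + 1; j < inc.size(); ++j) {
        if (!retained.get(inc[j].first)) continue;
        Mask m;
        m.set(inc[i].first);
        m.set(inc[j].first);
        if (!seen.insert(m).second) continue;
        int id = classify(g, m, classes, buckets, -1);
        if (level_set.insert(id).second) level.push_back(id);
      }
    }
  }

  // breadth-wise growth, one adjacent retained edge at a time; only classes
  // with >= 2 occurrences are grown further (a subgraph of a duplicatable
  // subgraph with an edge-disjoint partner always has >= 2 occurrences, so
  // this pruning loses no matchable class)
  while (!level.empty()) {
    std::vector<int> growers;
    for (int id : level)
      if (classes[id].occ.size() >= 2) growers.push_back(id);
    seen.clear();
    level.clear();
    level_set.clear();
    for (int id : growers) {
      for (const Mask& occm : classes[id].occ) {
        // collect fragment vertices, then adjacent retained edges not in mask
        std::vector<int> verts;
        std::vector<char> infrag(g.nv, 0);
        for (int e = 0; e < g.ne(); ++e) {
          if (!occm.get(e)) continue;
          for (int v : {g.eu[e], g.ev[e]}) {
            if (!infrag[v]) {
              infrag[v] = 1;
              verts.push_back(v);
            }
          }
        }
        for (int v : verts) {
          for (auto& [e, w] : g.adj[v]) {
            (void)w;
            if (!retained.get(e) || occm.get(e)) continue;
            Mask m2 = occm;
            m2.set(e);
            if (!seen.insert(m2).second) continue;
            int cid = classify(g, m2, classes, buckets, id);
            if (level_set.insert(cid).second) level.push_back(cid);
          }
        }
      }
    }
  }

  // drop single-occurrence classes; flag matchability; build cover masks
  std::vector<DupClass> kept;
  std::vector<int> remap(classes.size(), -1);
  for (auto& c : classes) {
    if (c.occ.size() < 2) continue;
    std::sort(c.occ.begin(), c.occ.end());
    c.matchable = false;
    for (size_t i = 0; i < c.occ.size() && !c.matchable; ++i)
      for (size_t j = i + 1; j < c.occ.size(); ++j)
        if (c.occ[i].disjoint(c.occ[j])) {
          c.matchable = true;
          break;
        }
    remap[c.id] = (int)kept.size();
    c.id = (int)kept.size();
    kept.push_back(c);
  }
  for (auto& c : kept) {
    c.parent = (c.parent >= 0) ? remap[c.parent] : -1;
    for (const Mask& m : c.occ) {
      en.cover = en.cover | m;
      if (c.matchable) en.cover_matchable = en.cover_matchable | m;
    }
  }
  en.classes = std::move(kept);

  // global sort order: size descending, then class key ascending
  en.order.resize(en.classes.size());
  for (size_t i = 0; i < en.order.size(); ++i) en.order[i] = (int)i;
  std::sort(en.order.begin(), en.order.end(), [&](int x, int y) {
    if (en.classes[x].k != en.classes[y].k)
      return en.classes[x].k > en.classes[y].k;
    return en.classes[x].key < en.classes[y].key;
  });
  return en;
}
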