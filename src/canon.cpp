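#include "canon.h"

#include <algorithm>
#include <cstdio>
#include <functional>
#include <map>
#include <numeric>

namespace {

// Compact local view of a fragment: vertices re-indexed 0..nv-1.
struct Frag {
  std::vector<int> vlab;                                // local labels
  std::vector<std::vector<std::pair<int, int>>> adj;    // local: (other, elab)
  int ne = 0;
};

Frag extract(const Graph& g, const Mask& m) {
  Frag f;
  std::vector<int> local(g.nv, -1);
  std::vector<int> verts;
  for (int e = 0; e < g.ne(); ++e) {
    if (!m.get(e)) continue;
    for (int v : {g.eu[e], g.ev[e]}) {
      if (local[v] < 0) {
        local[v] = (int)verts.size();
        verts.push_back(v);
      }
    }
  }
  f.vlab.resize(verts.size());
  f.adj.assign(verts.size(), {});
  for (size_t i = 0; i < verts.size(); ++i) f.vlab[i] = g.vlab[verts[i]];
  for (int e = 0; e < g.ne(); ++e) {
    if (!m.get(e)) continue;
    int u = local[g.eu[e]], v = local[g.ev[e]];
    f.adj[u].push_back({v, g.elab[e]});
    f.adj[v].push_back({u, g.elab[e]});
    f.ne++;
  }
  return f;
}

// AHU encoding of the subtree rooted at v, entered through bond label `via`.
std::string ahu(const Frag& f, int v, int parent, int via) {
  std::vector<std::string> kids;
  for (auto& [w, el] : f.adj[v]) {
    if (w == parent) continue;
    kids.push_back(ahu(f, w, v, el));
  }
  std::sort(kids.begin(), kids.end());
  std::string s = "(";
  s += std::to_string(f.vlab[v]);
  s += '|';
  s += std::to_string(via);
  for (auto& k : kids) s += k;
  s += ')';
  return s;
}

// centre vertices of a tree by iterative leaf stripping
std::vector<int> tree_centres(const Frag& f) {
  int n = (int)f.vlab.size();
  if (n == 1) return {0};
  std::vector<int> deg(n);
  for (int i = 0; i < n; ++i) deg[i] = (int)f.adj[i].size();
  std::vector<int> layer;
  std::vector<bool> removed(n, false);
  for (int i = 0; i < n; ++i)
    if (deg[i] <= 1) layer.push_back(i);
  int left = n;
  while (left > 2) {
    std::vector<int> nxt;
    for (int v : layer) {
      removed[v] = true;
      --left;
      for (auto& [w, el] : f.adj[v]) {
        (void)el;
        if (!removed[w] && --deg[w] == 1) nxt.push_back(w);
      }
    }
    layer = nxt;
  }
  std::vector<int> cs;
  for (int i = 0; i < n; ++i)
    if (!removed[i]) cs.push_back(i);
  return cs;
}

}  // namespace

bool frag_is_connected(const Graph& g, const Mask& m) {
  if (m.empty()) return false;
  return split_components(g, m).size() == 1;
}

bool frag_is_acyclic(const Graph& g, const Mask& m) {
  Frag f = extract(g, m);
  return f.ne == (int)f.vlab.size() - 1;
}

std::string frag_tree_key(const Graph& g, const Mask& m) {
  Frag f = extract(g, m);
  std::vector<int> cs = tree_centres(f);
  // double-centre trees: lexicographically smaller of the two centre-rooted
  // encodings (determinism)
  std::string best;
  for (size_t i = 0; i < cs.size(); ++i) {
    std::string s = ahu(f, cs[i], -1, 0);
    if (i == 0 || s < best) best = s;
  }
  return std::to_string(f.ne) + ":" + best;
}

namespace {

uint32_t ahu_code(const Frag& f, int v, int parent, int via, AhuIntern& it) {
  std::vector<uint32_t> kids;
  for (auto& [w, el] : f.adj[v]) {
    if (w == parent) continue;
    kids.push_back(ahu_code(f, w, v, el, it));
  }
  std::sort(kids.begin(), kids.end());
  std::string key;
  key.reserve(8 + 4 * kids.size());
  auto push32 = [&key](uint32_t x) {
    key.push_back((char)(x & 0xff));
    key.push_back((char)((x >> 8) & 0xff));
    key.push_back((char)((x >> 16) & 0xff));
    key.push_back((char)((x >> 24) & 0xff));
  };
  push32((uint32_t)f.vlab[v]);
  push32((uint32_t)via);
  for (uint32_t k : kids) push32(k);
  return it.intern(key);
}

}  // namespace

uint64_t frag_tree_code(const Graph& g, const Mask& m, AhuIntern& interner) {
  Frag f = extract(g, m);
  std::vector<int> cs = tree_centres(f);
  uint32_t best = 0;
  for (size_t i = 0; i < cs.size(); ++i) {
    uint32_t c = ahu_code(f, cs[i], -1, 0, interner);
    if (i == 0 || c < best) best = c;
  }
  return ((uint64_t)f.ne << 32) | best;
}

std::string frag_bucket_key(const Graph& g, const Mask& m) {
  // invariant, not complete: label multiset, degree sequence, edge count
  // and cycle rank; false collisions are allowed and resolved by explicit
  // isomorphism inside the bucket
  // vertex colours refined Weisfeiler-Lehman style with deterministic
  // integer hashing: isomorphic fragments always produce identical sorted
  // colour multisets, non-isomorphic ones usually differ
  Frag f = extract(g, m);
  int nv = (int)f.vlab.size();
  auto mix = [](uint64_t h, uint64_t x) {
    h ^= x + 0x9e3779b97f4a7c15ull + (h << 6) + (h >> 2);
    h *= 0xff51afd7ed558ccdull;
    h ^= h >> 33;
    return h;
  };
  std::vector<uint64_t> col(nv), nxt(nv);
  for (int i = 0; i < nv; ++i)
    col[i] = mix(0x42ull, (uint64_t)f.vlab[i]);
  std::vector<uint64_t> nb;
  for (int round = 0; round < 3; ++round) {
    for (int i = 0; i < nv; ++i) {
      nb.clear();
      for (auto& [w, el] : f.adj[i])
        nb.push_back(mix((uint64_t)el, col[w]));
      std::sort(nb.begin(), nb.end());
      uint64_t h = mix(0x7full, col[i]);
      for (uint64_t x : nb) h = mix(h, x);
      nxt[i] = h;
    }
    col.swap(nxt);
  }
  std::sort(col.begin(), col.end());
  uint64_t h = mix(0x11ull, (uint64_t)f.ne);
  h = mix(h, (uint64_t)nv);
  for (uint64_t c : col) h = mix(h, c);
  char buf[64];
  snprintf(buf, sizeof(buf), "e%dv%dr%d;%016llx", f.ne, nv, f.ne - nv + 1,
           (unsigned long long)h);
  return std::string(buf);
}

std::string frag_class_key(const Graph& g, const Mask& m) {
  if (frag_is_acyclic(g, m)) return "T:" + frag_tree_key(g, m);
  return "C:" + frag_bucket_key(g, m);
}

namespace {

// backtracking labelled-isomorphism search (VF2-style candidate pruning)
struct IsoSearch {
  const Frag& A;
  const Frag& B;
  std::vector<int> map_ab, map_ba;
  std::vector<int> order;  // A vertices in BFS order from a max-degree vertex

  IsoSearch(const Frag& a, const Frag& b) : A(a), B(b) {
    int n = (int)A.vlab.size();
    map_ab.assign(n, -1);
    map_ba.assign(n, -1);
    // BFS order keeps each new vertex adjacent to the mapped core
    int start = 0;
    for (int i = 1; i < n; ++i)
      if (A.adj[i].size() > A.adj[start].size()) start = i;
    std::vector<bool> seen(n, false);
    order.push_back(start);
    seen[start] = true;
    for (size_t q = 0; q < order.size(); ++q) {
      for (auto& [w, el] : A.adj[order[q]]) {
        (void)el;
        if (!seen[w]) {
          seen[w] = true;
          order.push_back(w);
        }
      }
    }
  }

  bool feasible(int a, int b) const {
    if (A.vlab[a] != B.vlab[b]) return false;
    if (A.adj[a].size() != B.adj[b].size()) return false;
    // every mapped neighbour of a must be a neighbour of b with same bond label
    for (auto& [w, el] : A.adj[a]) {
      int bw = map_ab[w];
      if (bw < 0) continue;
      bool ok = false;
      for (auto& [x, el2] : B.adj[b]) {
        if (x == bw && el2 == el) {
          ok = true;
          break;
        }
      }
      if (!ok) return false;
    }
    // and conversely for mapped neighbours of b
    for (auto& [x, el2] : B.adj[b]) {
      int aw = map_ba[x];
      if (aw < 0) continue;
      bool ok = false;
      for (auto& [w, el] : A.adj[a]) {
        if (w == aw && el == el2) {
          ok = true;
          break;
        }
      }
      if (!ok) return false;
    }
    return true;
  }

  bool rec(size_t depth) {
    if (depth == order.size()) return true;
    int a = order[depth];
    for (int b = 0; b < (int)B.vlab.size(); ++b) {
      if (map_ba[b] >= 0) continue;
      if (!feasible(a, b)) continue;
      map_ab[a] = b;
      map_ba[b] = a;
      if (rec(depth + 1)) return true;
      map_ab[a] = -1;
      map_ba[b] = -1;
    }
    return false;
  }
};

}  // namespace

bool frag_isomorphic(const Graph& g1, const Mask& m1,
                     const Graph& g2, const Mask& m2) {
  if (m1.count() != m2.count()) return false;
  Frag A = extract(g1, m1), B = extract(g2, m2);
  if (A.vlab.size() != B.vlab.size()) return false;
  IsoSearch s(A, B);
  return s.rec(0);
}

// ---- shared graph utilities -------------------------------------------------

std::vector<Mask> split_components(const Graph& g, const Mask& m) {
  // union-find over endpoints of set bits (disjoint-set construction), then
  // splitting into per-root edge masks
  std::vector<int> parent(g.nv, -1);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] >= 0 && parent[x] != x) {
      if (parent[parent[x]] >= 0) parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };
  for (int e = 0; e < g.ne(); ++e) {
    if (!m.get(e)) continue;
    int u = g.eu[e], v = g.ev[e];
    if (parent[u] < 0) parent[u] = u;
    if (parent[v] < 0) parent[v] = v;
    int ru = find(u), rv = find(v);
    if (ru != rv) parent[ru] = rv;
  }
  std::map<int, Mask> comps;           // keyed by root; rebuilt in edge order
  std::vector<int> first_edge_of_root;
  std::map<int, int> order_key;        // root -> smallest edge index
  for (int e = 0; e < g.ne(); ++e) {
    if (!m.get(e)) continue;
    int r = find(g.eu[e]);
    comps[r].set(e);
    if (!order_key.count(r)) order_key[r] = e;
  }
  std::vector<std::pair<int, Mask>> out;
  for (auto& [r, msk] : comps) out.push_back({order_key[r], msk});
  std::sort(out.begin(), out.end(),
            [](const auto& x, const auto& y) { return x.first < y.first; });
  std::vector<Mask> res;
  for (auto& p : out) res.push_back(p.second);
  return res;
}

int count_edge_components(const Graph& g) {
  return (int)split_components(g, g.full_mask()).size();
}
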