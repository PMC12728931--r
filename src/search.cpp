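#include "search.h"

#include <algorithm>
#include <chrono>
#include <climits>
#include <unordered_map>
#include "bounds.h"

namespace {

using Clock = std::chrono::steady_clock;

struct StateRec {
  std::vector<Mask> frags;  // frags[0] = last-removed duplicate (the copy)
  int S = 0;
  int parent = -1;          // arena index of the generating state
  PathStep step;            // removal that produced this state
};

uint64_t key_hash(const std::vector<Mask>& frags) {
  uint64_t h = 0x2545f4914f6cdd1dull;
  for (const Mask& m : frags) {
    h ^= m.hash() + 0x9e3779b97f4a7c15ull + (h << 6) + (h >> 2);
  }
  return h;
}

struct Engine {
  const Graph& g;
  const Enumeration& en;
  const SearchOpts& opts;
  int N, c_eff;

  std::vector<StateRec> arena;
  // state key hash -> arena indices holding current-best records
  std::unordered_map<uint64_t, std::vector<int>> table;

  int bestS = 0;
  int bestIdx = 0;
  bool aborted = false;
  long long expanded = 0, pruned_bound = 0, pruned_table = 0;
  Clock::time_point t0 = Clock::now();
  std::vector<std::pair<double, int>> trace;

  Engine(const Graph& g_, const Enumeration& en_, const SearchOpts& o,
         int N_, int c_)
      : g(g_), en(en_), opts(o), N(N_), c_eff(c_) {}

  double elapsed() const {
    return std::chrono::duration<double>(Clock::now() - t0).count();
  }

  // per-fragment sizes entering the bound: bonds that occur in at least one
  // occurrence of a matchable class (others can never join a duplicate)
  std::vector<int> bound_sizes(const std::vector<Mask>& frags) const {
    std::vector<int> sizes;
    for (const Mask& f : frags) {
      int L = (f & en.cover_matchable).count();
      if (L >= 2) sizes.push_back(L);
    }
    return sizes;
  }

  // child fragments after deleting both occurrences and disconnecting the
  // replicated structure: copy first, remnant components sorted after it;
  // single-edge remnants are building blocks and are not stored
  std::vector<Mask> child_frags(const std::vector<Mask>& frags,
                                const Mask& a, const Mask& b) const {
    Mask del = a | b;
    std::vector<Mask> out;
    out.push_back(a);
    for (const Mask& f : frags) {
      if (f.disjoint(del)) {
        if (f.count() >= 2) out.push_back(f);
        continue;
      }
      Mask rem = f.and_not(del);
      if (rem.empty()) continue;
      for (const Mask& comp : split_components(g, rem))
        if (comp.count() >= 2) out.push_back(comp);
    }
    std::sort(out.begin() + 1, out.end());
    return out;
  }

  // lookup a state; returns arena index or -1; `improved` set when an existing
  // record has strictly smaller S
  int lookup(const std::vector<Mask>& frags, uint64_t h) const {
    auto it = table.find(h);
    if (it == table.end()) return -1;
    for (int idx : it->second)
      if (arena[idx].frags == frags) return idx;
    return -1;
  }

  void note_best(int idx) {
    if (arena[idx].S > bestS) {
      bestS = arena[idx].S;
      bestIdx = idx;
      trace.push_back({elapsed(), N - c_eff - bestS});
    }
  }

  void rec(int stateIdx, int last_k) {
    if (aborted) return;
    ++expanded;
    if (opts.max_states > 0 && expanded > opts.max_states) {
      aborted = true;
      return;
    }
    if ((expanded & 1023) == 0 && elapsed() > opts.timeout) {
      aborted = true;
      return;
    }

    // local copies: the arena may reallocate while children are stored
    const std::vector<Mask> frags = arena[stateIdx].frags;
    const int S = arena[stateIdx].S;

    // collect the available duplicates: matchable classes not larger than the
    // last removal, with a valid edge-disjoint occurrence pair whose members
    // each lie inside a single current fragment
    struct Opt {
      int cid;
      std::vector<std::pair<int, int>> pairs;  // occurrence index pairs, i<j
    };
    std::vector<Opt> options;
    int m = 0;
    std::vector<int> cont;
    for (int cid : en.order) {  // size descending
      const DupClass& c = en.classes[cid];
      if (c.k > last_k) continue;
      if (!c.matchable) continue;
      cont.clear();
      for (int i = 0; i < (int)c.occ.size(); ++i) {
        for (const Mask& f : frags) {
          if (c.occ[i].subset_of(f)) {
            cont.push_back(i);
            break;
          }
        }
      }
      Opt o;
      o.cid = cid;
      for (size_t x = 0; x < cont.size(); ++x)
        for (size_t y = x + 1; y < cont.size(); ++y)
          if (c.occ[cont[x]].disjoint(c.occ[cont[y]]))
            o.pairs.push_back({cont[x], cont[y]});
      if (!o.pairs.empty()) {
        if (m == 0) m = c.k;  // first (largest) available size
        options.push_back(std::move(o));
      }
    }
    if (options.empty()) return;  // leaf: no duplicatable subgraph remains

    if (opts.use_bound) {
      int bnd = conditional_smax_bound(bound_sizes(frags), m);
      if (S + bnd <= bestS) {
        ++pruned_bound;
        return;
      }
    }

    for (const auto& o : options) {  // descending class size
      const DupClass& c = en.classes[o.cid];
      for (auto& [i, j] : o.pairs) {
        const Mask& a = c.occ[i];
        const Mask& b = c.occ[j];
        std::vector<Mask> cf = child_frags(frags, a, b);
        int Sc = S + c.k - 1;
        if (opts.use_bound) {
          // second application of the heuristic, on the split fragments;
          // every later duplicate is capped by this class's size
          int bnd = conditional_smax_bound(bound_sizes(cf), c.k);
          if (Sc + bnd <= bestS) {
            ++pruned_bound;
            continue;
          }
        }
        uint64_t h = key_hash(cf);
        if (opts.use_table) {
          int prev = lookup(cf, h);
          if (prev >= 0 && arena[prev].S >= Sc) {
            ++pruned_table;
            continue;
          }
        }
        StateRec recNew;
        recNew.frags = std::move(cf);
        recNew.S = Sc;
        recNew.parent = stateIdx;
        recNew.step = {o.cid, a, b};
        int idx = (int)arena.size();
        arena.push_back(std::move(recNew));
        if (opts.use_table) {
          // keep the best record per state; superseded records stay frozen so
          // stored parent chains remain internally consistent
          auto& slot = table[h];
          bool replaced = false;
          for (int& sidx : slot) {
            if (arena[sidx].frags == arena[idx].frags) {
              sidx = idx;
              replaced = true;
              break;
            }
          }
          if (!replaced) slot.push_back(idx);
        }
        note_best(idx);
        rec(idx, c.k);
        if (aborted) return;
      }
    }
  }
};

}  // namespace

SearchOutput run_search(const Graph& g, const Mask& retained,
                        const SearchOpts& opts) {
  SearchOutput out;
  out.n_edges = g.ne();
  std::vector<Mask> comps = split_components(g, g.full_mask());
  out.n_components = (int)comps.size();

  Enumeration en = enumerate_dups(g, retained);
  out.n_classes = (int)en.classes.size();
  for (auto& c : en.classes)
    if (c.matchable) ++out.n_matchable;

  Engine eng(g, en, opts, out.n_edges, out.n_components);
  StateRec root;
  for (const Mask& cmask : comps)
    if (cmask.count() >= 2) root.frags.push_back(cmask);
  // root has no removed duplicate; keep a deterministic fragment order
  std::sort(root.frags.begin(), root.frags.end());
  root.S = 0;
  root.parent = -1;
  eng.arena.push_back(std::move(root));
  eng.trace.push_back({0.0, out.n_edges - out.n_components});
  eng.rec(0, INT_MAX);

  out.best_s = eng.bestS;
  out.ma = out.n_edges - out.n_components - eng.bestS;
  out.converged = !eng.aborted;
  out.trace = std::move(eng.trace);
  out.expanded = eng.expanded;
  out.pruned_bound = eng.pruned_bound;
  out.pruned_table = eng.pruned_table;
  out.stored = (long long)eng.arena.size();

  // pathway: climb parent pointers from the best state to the root
  std::vector<PathStep> steps;
  int idx = eng.bestIdx;
  while (idx > 0) {
    steps.push_back(eng.arena[idx].step);
    idx = eng.arena[idx].parent;
  }
  std::reverse(steps.begin(), steps.end());
  out.path = std::move(steps);
  return out;
}
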