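#include <Rcpp.h>

#include <algorithm>
#include <functional>
#include <set>

#include "bounds.h"
#include "enumerate.h"
#include "gensmall.h"
#include "oracle.h"
#include "search.h"

using namespace Rcpp;

namespace {

Graph graph_from_r(const List& gl) {
  Graph g;
  IntegerVector vlab = gl["vlab_code"];
  IntegerVector eu = gl["edge_from"];
  IntegerVector ev = gl["edge_to"];
  IntegerVector el = gl["edge_lab"];
  g.nv = vlab.size();
  g.vlab = as<std::vector<int>>(vlab);
  for (int i = 0; i < eu.size(); ++i)
    g.add_edge(eu[i] - 1, ev[i] - 1, el[i]);
  if (g.ne() > MASK_MAX_EDGES)
    stop("graphs with more than %d edges are not supported", MASK_MAX_EDGES);
  g.build_adj();
  return g;
}

Mask mask_from_r(const LogicalVector& lv) {
  Mask m;
  for (int i = 0; i < lv.size(); ++i)
    if (lv[i]) m.set(i);
  return m;
}

LogicalVector mask_to_r(const Mask& m, int n) {
  LogicalVector lv(n);
  for (int i = 0; i < n; ++i) lv[i] = m.get(i);
  return lv;
}

IntegerVector mask_to_idx(const Mask& m, int n) {
  std::vector<int> idx;
  for (int i = 0; i < n; ++i)
    if (m.get(i)) idx.push_back(i + 1);
  return wrap(idx);
}

List graph_to_r(const Graph& g) {
  IntegerVector eu(g.ne()), ev(g.ne()), el(g.ne());
  for (int e = 0; e < g.ne(); ++e) {
    eu[e] = g.eu[e] + 1;
    ev[e] = g.ev[e] + 1;
    el[e] = g.elab[e];
  }
  return List::create(_["vlab_code"] = wrap(g.vlab), _["edge_from"] = eu,
                      _["edge_to"] = ev, _["edge_lab"] = el);
}

}  // namespace

// [[Rcpp::export]]
LogicalVector cpp_retained_mask(List g) {
  Graph gg = graph_from_r(g);
  return mask_to_r(retained_mask(gg), gg.ne());
}

// [[Rcpp::export]]
List cpp_components(List g, LogicalVector mask) {
  Graph gg = graph_from_r(g);
  std::vector<Mask> comps = split_components(gg, mask_from_r(mask));
  List out(comps.size());
  for (size_t i = 0; i < comps.size(); ++i)
    out[i] = mask_to_idx(comps[i], gg.ne());
  return out;
}

// [[Rcpp::export]]
bool cpp_is_connected(List g, LogicalVector mask) {
  Graph gg = graph_from_r(g);
  return frag_is_connected(gg, mask_from_r(mask));
}

// [[Rcpp::export]]
bool cpp_is_acyclic(List g, LogicalVector mask) {
  Graph gg = graph_from_r(g);
  return frag_is_acyclic(gg, mask_from_r(mask));
}

// [[Rcpp::export]]
std::string cpp_tree_key(List g, LogicalVector mask) {
  Graph gg = graph_from_r(g);
  return frag_tree_key(gg, mask_from_r(mask));
}

// [[Rcpp::export]]
std::string cpp_class_key(List g, LogicalVector mask) {
  Graph gg = graph_from_r(g);
  return frag_class_key(gg, mask_from_r(mask));
}

// [[Rcpp::export]]
bool cpp_isomorphic(List g1, LogicalVector m1, List g2, LogicalVector m2) {
  Graph a = graph_from_r(g1), b = graph_from_r(g2);
  return frag_isomorphic(a, mask_from_r(m1), b, mask_from_r(m2));
}

// [[Rcpp::export]]
List cpp_enumerate(List g) {
  Graph gg = graph_from_r(g);
  Enumeration en = enumerate_dups(gg, retained_mask(gg));
  int nc = (int)en.classes.size();
  List classes(nc);
  for (int i = 0; i < nc; ++i) {
    const DupClass& c = en.classes[i];
    List occ(c.occ.size());
    for (size_t j = 0; j < c.occ.size(); ++j)
      occ[j] = mask_to_idx(c.occ[j], gg.ne());
    classes[i] = List::create(
        _["id"] = c.id + 1, _["k"] = c.k, _["key"] = c.key,
        _["matchable"] = c.matchable,
        _["parent"] = c.parent >= 0 ? c.parent + 1 : NA_INTEGER,
        _["occurrences"] = occ);
  }
  IntegerVector ord(en.order.size());
  for (size_t i = 0; i < en.order.size(); ++i) ord[i] = en.order[i] + 1;
  return List::create(_["classes"] = classes, _["order"] = ord,
                      _["retained"] = mask_to_r(en.retained, gg.ne()),
                      _["cover"] = mask_to_r(en.cover, gg.ne()),
                      _["cover_matchable"] =
                          mask_to_r(en.cover_matchable, gg.ne()));
}

// [[Rcpp::export]]
List cpp_search(List g, bool use_bound, bool use_table, double timeout,
                double max_states) {
  Graph gg = graph_from_r(g);
  SearchOpts opts;
  opts.use_bound = use_bound;
  opts.use_table = use_table;
  opts.timeout = timeout;
  opts.max_states = max_states > 0 ? (long long)max_states : -1;
  SearchOutput res = run_search(gg, retained_mask(gg), opts);

  NumericVector tr_t(res.trace.size());
  IntegerVector tr_ma(res.trace.size());
  for (size_t i = 0; i < res.trace.size(); ++i) {
    tr_t[i] = res.trace[i].first;
    tr_ma[i] = res.trace[i].second;
  }

  // replay the best pathway to report duplicate/remnant structures per step
  std::vector<Mask> frags;
  for (const Mask& c : split_components(gg, gg.full_mask()))
    if (c.count() >= 2) frags.push_back(c);
  std::sort(frags.begin(), frags.end());
  List steps(res.path.size());
  for (size_t si = 0; si < res.path.size(); ++si) {
    const PathStep& st = res.path[si];
    Mask del = st.a | st.b;
    std::vector<Mask> remnants, nxt;
    nxt.push_back(st.a);
    for (const Mask& f : frags) {
      if (f.disjoint(del)) {
        nxt.push_back(f);
        continue;
      }
      Mask rem = f.and_not(del);
      if (!rem.empty())
        for (const Mask& comp : split_components(gg, rem))
          remnants.push_back(comp);
    }
    List remn(remnants.size());
    for (size_t j = 0; j < remnants.size(); ++j)
      remn[j] = mask_to_idx(remnants[j], gg.ne());
    steps[si] = List::create(
        _["k"] = st.a.count(), _["duplicate"] = mask_to_idx(st.a, gg.ne()),
        _["partner"] = mask_to_idx(st.b, gg.ne()), _["remnants"] = remn);
    // advance the fragment list (stored states drop single-edge remnants)
    std::vector<Mask> stepped{st.a};
    for (const Mask& f : frags) {
      if (f.disjoint(del)) {
        if (f.count() >= 2) stepped.push_back(f);
        continue;
      }
      Mask rem = f.and_not(del);
      if (rem.empty()) continue;
      for (const Mask& comp : split_components(gg, rem))
        if (comp.count() >= 2) stepped.push_back(comp);
    }
    std::sort(stepped.begin() + 1, stepped.end());
    frags = std::move(stepped);
  }
  List final_frags(frags.size());
  for (size_t i = 0; i < frags.size(); ++i)
    final_frags[i] = mask_to_idx(frags[i], gg.ne());

  return List::create(
      _["ma"] = res.ma, _["best_s"] = res.best_s,
      _["converged"] = res.converged, _["n_edges"] = res.n_edges,
      _["n_components"] = res.n_components,
      _["trace_time"] = tr_t, _["trace_ma"] = tr_ma, _["pathway"] = steps,
      _["final_fragments"] = final_frags,
      _["stats"] = List::create(
          _["states_expanded"] = (double)res.expanded,
          _["pruned_bound"] = (double)res.pruned_bound,
          _["pruned_table"] = (double)res.pruned_table,
          _["states_stored"] = (double)res.stored,
          _["n_duplicate_classes"] = res.n_classes,
          _["n_matchable_classes"] = res.n_matchable));
}

// [[Rcpp::export]]
int cpp_oracle_ma(List g, int max_edges) {
  Graph gg = graph_from_r(g);
  return oracle_ma(gg, max_edges);
}

// [[Rcpp::export]]
int cpp_oracle_best_s(List g, int cap_k, int max_edges) {
  Graph gg = graph_from_r(g);
  return oracle_best_s(gg, cap_k, max_edges);
}

// [[Rcpp::export]]
int cpp_ceil_log2(double n) {
  if (n < 1) stop("ceil_log2 requires n >= 1");
  return ceil_log2_int((long long)n);
}

// [[Rcpp::export]]
int cpp_addition_chain_length(int n) { return addition_chain_len(n); }

// [[Rcpp::export]]
int cpp_chain_bound_single(int L, int m) { return chain_bound_single(L, m); }

// [[Rcpp::export]]
int cpp_conditional_smax_bound(IntegerVector sizes, int m) {
  return conditional_smax_bound(as<std::vector<int>>(sizes), m);
}

// [[Rcpp::export]]
int cpp_refined_split_bound(IntegerVector sizes, int m, int Lm) {
  return refined_split_bound(as<std::vector<int>>(sizes), m, Lm);
}

// [[Rcpp::export]]
List cpp_gen_small_graphs(int max_edges, IntegerVector vlabs,
                          IntegerVector elabs, double max_graphs) {
  std::vector<Graph> gs =
      gen_small_graphs(max_edges, as<std::vector<int>>(vlabs),
                       as<std::vector<int>>(elabs), (long long)max_graphs);
  List out(gs.size());
  for (size_t i = 0; i < gs.size(); ++i) out[i] = graph_to_r(gs[i]);
  return out;
}

// [[Rcpp::export]]
int cpp_gen_count(int max_edges, IntegerVector vlabs, IntegerVector elabs) {
  return (int)gen_small_graphs(max_edges, as<std::vector<int>>(vlabs),
                               as<std::vector<int>>(elabs), (long long)4e6)
      .size();
}

// Bulk oracle-equivalence check over the exhaustive small-graph family.
// For each graph: brute-force oracle MA vs optimised search MA, optionally
// also the search with bound and/or state table disabled.
// [[Rcpp::export]]
List cpp_check_equivalence(int max_edges, IntegerVector vlabs,
                           IntegerVector elabs, bool check_variants,
                           double max_graphs) {
  std::vector<Graph> gs =
      gen_small_graphs(max_edges, as<std::vector<int>>(vlabs),
                       as<std::vector<int>>(elabs), (long long)max_graphs);
  int n_mismatch = 0, n_variant_mismatch = 0;
  std::vector<int> per_level(max_edges + 1, 0);
  List examples;
  for (const Graph& g : gs) {
    per_level[g.ne()]++;
    int oma = oracle_ma(g, 64);
    SearchOpts full;
    full.timeout = 3600;
    int sma = run_search(g, retained_mask(g), full).ma;
    if (sma != oma) {
      ++n_mismatch;
      if (examples.size() < 10)
        examples.push_back(List::create(_["graph"] = graph_to_r(g),
                                        _["oracle"] = oma, _["search"] = sma));
    }
    if (check_variants) {
      for (int v = 0; v < 3; ++v) {
        SearchOpts o;
        o.use_bound = (v == 1);
        o.use_table = (v == 0);
        o.timeout = 3600;
        if (run_search(g, retained_mask(g), o).ma != sma) ++n_variant_mismatch;
      }
    }
  }
  return List::create(_["n_graphs"] = (int)gs.size(),
                      _["per_level"] = wrap(per_level),
                      _["n_mismatch"] = n_mismatch,
                      _["n_variant_mismatch"] = n_variant_mismatch,
                      _["examples"] = examples);
}

// Bound admissibility over every reachable assembly state of a graph:
// residual best S under duplicate-size cap m (exhaustive restricted search)
// must never exceed the conditional bound at m.
// [[Rcpp::export]]
List cpp_check_admissibility(List g, int max_edges) {
  Graph gg = graph_from_r(g);
  if (gg.ne() > max_edges) stop("graph too large for admissibility check");

  long long n_states = 0, n_checks = 0, n_violations = 0;

  // reachable states under the unrestricted removal recursion
  std::vector<Mask> init;
  for (const Mask& c : split_components(gg, gg.full_mask()))
    if (c.count() >= 2) init.push_back(c);
  std::sort(init.begin(), init.end());
  std::set<std::vector<Mask>> seen;
  std::function<void(std::vector<Mask>)> visit = [&](std::vector<Mask> frags) {
    std::sort(frags.begin(), frags.end());
    if (!seen.insert(frags).second) return;
    ++n_states;
    int maxL = 0;
    std::vector<int> sizes;
    for (const Mask& f : frags) {
      sizes.push_back(f.count());
      maxL = std::max(maxL, f.count());
    }
    if (!sizes.empty()) {
      for (int m = 2; m <= maxL; ++m) {
        int rs = oracle_best_s_frags(gg, frags, m);
        int bd = conditional_smax_bound(sizes, m);
        ++n_checks;
        if (rs > bd) ++n_violations;
      }
    }
    // children: every disjoint isomorphic occurrence pair of every size
    std::vector<Mask> subs;
    for (const Mask& f : frags) {
      std::vector<Mask> s = oracle_subgraphs(gg, f, 0);
      subs.insert(subs.end(), s.begin(), s.end());
    }
    for (size_t i = 0; i < subs.size(); ++i) {
      for (size_t j = 0; j < subs.size(); ++j) {
        if (i == j) continue;
        if (subs[i].count() != subs[j].count()) continue;
        if (!subs[i].disjoint(subs[j])) continue;
        if (!frag_isomorphic(gg, subs[i], gg, subs[j])) continue;
        Mask del = subs[i] | subs[j];
        std::vector<Mask> child{subs[i]};
        for (const Mask& f : frags) {
          if (f.disjoint(del)) {
            if (f.count() >= 2) child.push_back(f);
            continue;
          }
          Mask rem = f.and_not(del);
          if (rem.empty()) continue;
          for (const Mask& comp : split_components(gg, rem))
            if (comp.count() >= 2) child.push_back(comp);
        }
        visit(child);
      }
    }
  };
  visit(init);
  return List::create(_["n_states"] = (double)n_states,
                      _["n_checks"] = (double)n_checks,
                      _["n_violations"] = (double)n_violations);
}
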