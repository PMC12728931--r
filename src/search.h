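#pragma once

#include <utility>
#include <vector>
#include "enumerate.h"

struct SearchOpts {
  bool use_bound = true;    // conditional addition-chain branch-and-bound
  bool use_table = true;    // dynamic programming over hashed states
  bool refined_bound = false;
  double timeout = 600.0;   // seconds of wall clock
  long long max_states = -1;  // expanded-state cap; -1 = unlimited
};

struct PathStep {
  int class_id = -1;
  Mask a, b;  // the removed occurrence pair; a (copy) becomes fragments[0]
};

struct SearchOutput {
  int ma = 0;
  int best_s = 0;
  bool converged = true;
  int n_edges = 0;
  int n_components = 0;  // edge-bearing components of the input
  std::vector<std::pair<double, int>> trace;  // (elapsed s, MA upper bound)
  std::vector<PathStep> path;                 // best pathway, removal order
  long long expanded = 0, pruned_bound = 0, pruned_table = 0, stored = 0;
  int n_classes = 0, n_matchable = 0;
};

SearchOutput run_search(const Graph& g, const Mask& retained,
                        const SearchOpts& opts);
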