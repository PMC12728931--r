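#pragma once

#include <string>
#include <vector>
#include "canon.h"

// One isomorphism class of connected subgraphs with >= 2 occurrences in the
// preprocessed molecular graph.
struct DupClass {
  int id = -1;
  int k = 0;                    // edge count of every occurrence
  std::string key;              // class key ("T:..." exact, "C:..." bucket)
  std::vector<Mask> occ;        // occurrence edge masks, sorted
  bool matchable = false;       // has at least one edge-disjoint pair
  int parent = -1;              // growth DAG: first parent class encountered
};

struct Enumeration {
  std::vector<DupClass> classes;
  Mask retained;                // edges surviving unique-bond removal
  Mask cover;                   // edges occurring in >= 1 occurrence
  Mask cover_matchable;         // as cover, matchable classes only
  std::vector<int> order;       // class ids sorted by (k desc, key asc)
};

// Algorithm: breadth-wise growth from 2-edge connected subgraphs inside
// `retained`, one adjacent edge at a time; classes grouped by class key with
// explicit isomorphism inside cyclic buckets; only classes with >= 2
// occurrences are kept and grown further.
Enumeration enumerate_dups(const Graph& g, const Mask& retained);
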