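#pragma once

#include <vector>
#include "canon.h"

// All connected labelled graphs with <= max_edges edges over the given
// atom/bond label alphabets, up to labelled isomorphism. Grown one edge at a
// time (every connected graph arises from a connected one-edge-smaller
// subgraph), deduplicated per level by class key + explicit isomorphism.
std::vector<Graph> gen_small_graphs(int max_edges,
                                    const std::vector<int>& vlabs,
                                    const std::vector<int>& elabs,
                                    long long max_graphs);

// an edge is retained iff its bond label (endpoint atom labels + order)
// occurs at least twice; single pass on label multiplicity
Mask retained_mask(const Graph& g);
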