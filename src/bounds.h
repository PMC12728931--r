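#pragma once

#include <vector>

// smallest t with 2^t >= n (n >= 1)
int ceil_log2_int(long long n);

// exact minimal addition-chain length l(n), iterative-deepening search
int addition_chain_len(int n);

// maximum duplicate sum S achievable for one fragment of L edges when no
// duplicate larger than m may be taken: L - ceil(L/m) - ceil(log2 m)
// (may be negative; callers clamp)
int chain_bound_single(int L, int m);

// multi-fragment conditional addition-chain bound, sharing one logarithmic
// term: max over x in 2..m of [ -ceil(log2 x) + sum_i (L_i - ceil(L_i/x)) ],
// clamped at 0
int conditional_smax_bound(const std::vector<int>& sizes, int m);

// two-part refinement: bonds coverable at size m (total Lm) bounded at cap m,
// the remainder at cap m-1, sharing the single logarithmic term
int refined_split_bound(const std::vector<int>& sizes, int m, int Lm);
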