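#include "bounds.h"

#include <algorithm>
#include <stdexcept>

int ceil_log2_int(long long n) {
  if (n < 1) throw std::invalid_argument("ceil_log2 requires n >= 1");
  int t = 0;
  long long p = 1;
  while (p < n) {
    p <<= 1;
    ++t;
  }
  return t;
}

namespace {

// depth-limited DFS over ascending addition chains; minimal chains can always
// be written strictly ascending, and doubling bounds the reachable maximum
bool chain_dfs(std::vector<int>& chain, int n, int limit) {
  int last = chain.back();
  if (last == n) return true;
  int depth = (int)chain.size() - 1;
  int remaining = limit - depth;
  if (remaining <= 0) return false;
  // cannot reach n even by doubling every remaining step
  long long reach = (long long)last << remaining;
  if (reach < n) return false;
  // candidate sums, largest first (tends to find doublings quickly)
  std::vector<int> cands;
  for (int i = (int)chain.size() - 1; i >= 0; --i) {
    for (int j = i; j >= 0; --j) {
      int s = chain[i] + chain[j];
      if (s > last && s <= n) cands.push_back(s);
    }
  }
  std::sort(cands.begin(), cands.end(), std::greater<int>());
  cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
  for (int s : cands) {
    chain.push_back(s);
    if (chain_dfs(chain, n, limit)) return true;
    chain.pop_back();
  }
  return false;
}

}  // namespace

int addition_chain_len(int n) {
  if (n < 1) throw std::invalid_argument("addition chain requires n >= 1");
  if (n > 4096) throw std::invalid_argument("addition chain limit is 4096");
  if (n == 1) return 0;
  for (int limit = ceil_log2_int(n);; ++limit) {
    std::vector<int> chain{1};
    if (chain_dfs(chain, n, limit)) return limit;
  }
}

namespace {
inline int ceildiv(int a, int b) { return (a + b - 1) / b; }
}  // namespace

int chain_bound_single(int L, int m) {
  return L - ceildiv(L, m) - ceil_log2_int(m);
}

int conditional_smax_bound(const std::vector<int>& sizes, int m) {
  if (sizes.empty() || m < 2) return 0;
  int best = 0;
  for (int x = 2; x <= m; ++x) {
    int v = -ceil_log2_int(x);
    for (int L : sizes) v += L - ceildiv(L, x);
    best = std::max(best, v);
  }
  return best;
}

int refined_split_bound(const std::vector<int>& sizes, int m, int Lm) {
  int total = 0;
  for (int L : sizes) total += L;
  if (Lm < 0 || Lm > total)
    throw std::invalid_argument("Lm must lie in [0, sum(sizes)]");
  if (Lm == total) return conditional_smax_bound(sizes, m);
  if (Lm == 0) return conditional_smax_bound(sizes, m - 1);
  if (m < 3) throw std::invalid_argument("refined split needs m >= 3 when Lm < sum(sizes)");
  // cap-m part over the Lm coverable bonds, cap-(m-1) part over the rest,
  // one logarithmic term for the largest designated integer
  int rem = total - Lm;
  int v = (Lm - ceildiv(Lm, m)) + (rem - ceildiv(rem, m - 1)) - ceil_log2_int(m);
  int alt = conditional_smax_bound(sizes, m - 1);  // pathways never using size m
  return std::max(0, std::max(v, alt));
}
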