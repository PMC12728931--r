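#pragma once

#include <cstdint>
#include <cstddef>

// Fixed-width boolean edge list over the owning graph's edge indices.
// 256 bits covers single molecules well past the practical exact-search
// range and joint inputs like the 20 standard amino acids (173 bonds).
constexpr int MASK_MAX_EDGES = 256;
constexpr int MASK_WORDS = MASK_MAX_EDGES / 64;

struct Mask {
  uint64_t w[MASK_WORDS] = {0, 0, 0, 0};

  void set(int i) { w[i >> 6] |= (1ull << (i & 63)); }
  void clear(int i) { w[i >> 6] &= ~(1ull << (i & 63)); }
  bool get(int i) const { return (w[i >> 6] >> (i & 63)) & 1ull; }
  bool empty() const {
    for (int k = 0; k < MASK_WORDS; ++k)
      if (w[k]) return false;
    return true;
  }
  int count() const {
    int c = 0;
    for (int k = 0; k < MASK_WORDS; ++k) c += __builtin_popcountll(w[k]);
    return c;
  }
  int min_bit() const {
    for (int k = 0; k < MASK_WORDS; ++k)
      if (w[k]) return 64 * k + __builtin_ctzll(w[k]);
    return -1;
  }
  friend Mask operator|(const Mask& x, const Mask& y) {
    Mask r;
    for (int k = 0; k < MASK_WORDS; ++k) r.w[k] = x.w[k] | y.w[k];
    return r;
  }
  friend Mask operator&(const Mask& x, const Mask& y) {
    Mask r;
    for (int k = 0; k < MASK_WORDS; ++k) r.w[k] = x.w[k] & y.w[k];
    return r;
  }
  Mask and_not(const Mask& y) const {
    Mask r;
    for (int k = 0; k < MASK_WORDS; ++k) r.w[k] = w[k] & ~y.w[k];
    return r;
  }
  bool disjoint(const Mask& y) const {
    for (int k = 0; k < MASK_WORDS; ++k)
      if (w[k] & y.w[k]) return false;
    return true;
  }
  bool subset_of(const Mask& y) const {
    for (int k = 0; k < MASK_WORDS; ++k)
      if (w[k] & ~y.w[k]) return false;
    return true;
  }
  bool operator==(const Mask& y) const {
    for (int k = 0; k < MASK_WORDS; ++k)
      if (w[k] != y.w[k]) return false;
    return true;
  }
  bool operator!=(const Mask& y) const { return !(*this == y); }
  // deterministic total order (used to normalise occurrence pairs and sort
  // state fragments; any consistent comparator is acceptable)
  bool operator<(const Mask& y) const {
    for (int k = 0; k < MASK_WORDS; ++k)
      if (w[k] != y.w[k]) return w[k] < y.w[k];
    return false;
  }
  uint64_t hash() const {
    uint64_t h = 0x9e3779b97f4a7c15ull;
    for (int k = 0; k < MASK_WORDS; ++k) {
      h ^= w[k] + 0x9e3779b97f4a7c15ull + (h << 6) + (h >> 2);
      h *= 0xff51afd7ed558ccdull;
      h ^= h >> 33;
    }
    return h;
  }
};

struct MaskHash {
  size_t operator()(const Mask& m) const { return (size_t)m.hash(); }
};
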