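#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// [[Rcpp::export]]
std::string comp_cpp(std::string s) {
  for (size_t i = 0; i < s.size(); ++i) s[i] = comp_base(s[i]);
  return s;
}

// [[Rcpp::export]]
std::string rev_cpp(std::string s) {
  return std::string(s.rbegin(), s.rend());
}

// Maximal exact matches between a and b found by k-mer seeding and
// mismatch-free extension. A match is a triple (start_a, start_b, len) with
// a[start_a + t] == b[start_b + t] for t in [0, len), not extendable at either
// end within {A,C,G,T}. Every maximal match of length >= max(k, min_len) is
// found because all k-mer start positions of b are probed. Per-diagonal
// coverage bookkeeping keeps seeds inside an already-extended match O(1).
// If self_pairs is false, a and b are taken to be the same string and matches
// with start_a <= start_b are dropped (each unordered pair is kept once, and
// the trivial self-diagonal never reported). cap_len > 0 truncates extension
// (used for doubled circular sequences).
// [[Rcpp::export]]
DataFrame max_matches_cpp(std::string a, std::string b, int min_len,
                          bool self_pairs = true, int cap_len = -1) {
  int an = (int)a.size(), bn = (int)b.size();
  int k = min_len < 15 ? min_len : 15;
  if (k < 2) k = 2;
  if (k > 16) k = 16;
  uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);

  // hash all valid k-mer starts of a
  std::unordered_map<uint32_t, std::vector<int> > idx;
  idx.reserve((size_t)an);
  {
    uint32_t h = 0; int run = 0;
    for (int i = 0; i < an; ++i) {
      int c = base_code(a[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)c) & mask;
      if (++run >= k) idx[h].push_back(i - k + 1);
    }
  }

  std::unordered_map<long long, int> cov; // diagonal -> end (excl.) in b coords
  std::vector<int> ra, rb, rl;

  uint32_t h = 0; int run = 0;
  for (int p = 0; p < bn; ++p) {
    int c = base_code(b[p]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)c) & mask;
    if (++run < k) continue;
    int p0k = p - k + 1;
    auto it = idx.find(h);
    if (it == idx.end()) continue;
    for (int i : it->second) {
      if (!self_pairs && i == p0k) continue;
      long long d = (long long)i - p0k + bn;
      auto cit = cov.find(d);
      if (cit != cov.end() && p0k < cit->second) continue;
      // verify (hash collisions impossible for k<=16 2-bit packing, but a
      // k-mer containing no N is guaranteed; check chars anyway)
      int i0 = i, p0 = p0k;
      while (i0 > 0 && p0 > 0 && base_code(a[i0 - 1]) >= 0 &&
             a[i0 - 1] == b[p0 - 1]) { --i0; --p0; }
      int ie = i + k, pe = p0k + k;
      while (ie < an && pe < bn && base_code(a[ie]) >= 0 && a[ie] == b[pe] &&
             (cap_len <= 0 || ie - i0 < cap_len)) { ++ie; ++pe; }
      cov[d] = pe;
      int L = ie - i0;
      if (L >= min_len) {
        if (!self_pairs && i0 <= p0) continue;
        ra.push_back(i0); rb.push_back(p0); rl.push_back(L);
      }
    }
  }
  return DataFrame::create(_["start_a"] = ra, _["start_b"] = rb,
                           _["len"] = rl);
}
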