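// Symmetric-DUST perfect-interval scan.
//
// Score of a window of length >= 3: with n = length-2 overlapping triplets
// and c_t the count of triplet type t, score = sum_t c_t*(c_t-1)/2 / (n-1)
// (0 when n == 1).  A perfect interval is a window of length <= `window`
// with score > threshold such that no proper subinterval has a strictly
// greater score and that is not properly contained in another reported
// interval.
//
// The caller splits the sequence on non-ACGT characters; this scan assumes a
// pure {A,C,G,T} string.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int code3(const std::string& s, size_t i) {
  auto b = [](char c) {
    switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2; default: return 3; }
  };
  return (b(s[i]) << 4) | (b(s[i + 1]) << 2) | b(s[i + 2]);
}

// [[Rcpp::export]]
List cpp_sdust_perfect(std::string seq, int window, double threshold) {
  const long L = (long)seq.size();
  std::vector<long> outs, oute;
  std::vector<double> outsc;
  if (L >= 3) {
    const int W = window;
    const long nt = L - 2;          // number of triplets
    std::vector<int> tri(nt);
    for (long i = 0; i < nt; ++i) tri[i] = code3(seq, i);

    // score[i][len] for len in 3..min(W, L-i); stored as flat rows of width
    // W-2 (index len-3).  maxall[i][len] = best score of any subinterval
    // (including itself) of [i, i+len).
    const int nl = W - 2;
    std::vector<double> score((size_t)L * nl, -1.0), maxall((size_t)L * nl, -1.0);
    std::vector<int> cnt(256, 0);
    for (long i = 0; i + 3 <= L; ++i) {
      long r = 0;            // sum of c*(c-1)/2
      int maxlen = (int)std::min((long)W, L - i);
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int len = 3; len <= maxlen; ++len) {
        int c = tri[i + len - 3];
        r += cnt[c];
        ++cnt[c];
        int n = len - 2;
        score[(size_t)i * nl + (len - 3)] = (n == 1) ? 0.0 : (double)r / (n - 1);
      }
    }
    for (int len = 3; len <= W; ++len) {
      for (long i = 0; i + len <= L; ++i) {
        double m = score[(size_t)i * nl + (len - 3)];
        if (len > 3) {
          m = std::max(m, maxall[(size_t)i * nl + (len - 4)]);
          m = std::max(m, maxall[(size_t)(i + 1) * nl + (len - 4)]);
        }
        maxall[(size_t)i * nl + (len - 3)] = m;
      }
    }
    // candidates: score > threshold and no proper subinterval strictly greater
    struct Cand { long s, e; double sc; };
    std::vector<Cand> cands;
    for (long i = 0; i + 3 <= L; ++i) {
      int maxlen = (int)std::min((long)W, L - i);
      for (int len = 3; len <= maxlen; ++len) {
        double sc = score[(size_t)i * nl + (len - 3)];
        if (sc <= threshold) continue;
        double sub = -1.0;
        if (len > 3) {
          sub = std::max(maxall[(size_t)i * nl + (len - 4)],
                         maxall[(size_t)(i + 1) * nl + (len - 4)]);
        }
        if (sub > sc) continue;
        cands.push_back({i, i + len, sc});
      }
    }
    // drop candidates properly contained in a reported interval
    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      if (a.s != b.s) return a.s < b.s;
      return a.e > b.e;
    });
    long max_end = -1;
    for (const Cand& c : cands) {
      if (c.e <= max_end) continue;          // properly contained
      outs.push_back(c.s); oute.push_back(c.e); outsc.push_back(c.sc);
      max_end = std::max(max_end, c.e);
    }
  }
  return List::create(_["start"] = wrap(outs), _["end"] = wrap(oute),
                      _["score"] = wrap(outsc));
}
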