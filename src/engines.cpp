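// All-hits approximate k-mer search engines.
//
// Two engines with an identical contract: report every end-to-end placement
// of a query k-mer in a text within a bounded unit-cost edit distance.  Per
// candidate start only the minimum achievable distance is reported, together
// with the smallest end position attaining it.
//
//  * exact engine: full dynamic programming over all windows, O(L*k).
//    The per-start minima are obtained in one pass by running the DP on the
//    reversed strings (an alignment anchored at start s in the forward text
//    is an alignment anchored at end L-s in the reversed text).
//  * seeded engine: pigeonhole seeding (max_d+1 non-overlapping exact seeds;
//    any placement with <= max_d edits contains one exact seed) followed by
//    banded DP verification of candidate starts.  Identical output.
//
// Text characters outside {A,C,G,T} never match anything (assembly gaps).

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // never matches
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static const int BIG = 1 << 28;

// Minimum edit distance of query aligned end-to-end against text starting at
// position s (free end), by banded DP; exact for results <= max_d.  Returns
// distance (> max_d means "no hit") and writes the smallest attaining end.
static int anchored_dist(const std::vector<int>& q, const std::vector<int>& t,
                         long s, int max_d, long* end_out) {
  const int k = (int)q.size();
  const long L = (long)t.size();
  const long wlen = std::min((long)(k + max_d), L - s);
  if (wlen < (long)(k - max_d)) return BIG;
  // D[i][j]: query prefix i vs window prefix j; band |i-j| <= max_d.
  std::vector<int> prev(wlen + 1), cur(wlen + 1);
  for (long j = 0; j <= std::min((long)max_d, wlen); ++j) prev[j] = (int)j;
  int best = BIG;
  long best_end = -1;
  for (int i = 1; i <= k; ++i) {
    long lo = std::max(0L, (long)i - max_d), hi = std::min(wlen, (long)i + max_d);
    int rowmin = BIG;
    for (long j = lo; j <= hi; ++j) {
      int v = BIG;
      // vertical: D[i-1][j], valid iff j inside row i-1's band
      if (j <= (long)(i - 1) + max_d) v = std::min(v, prev[j] + 1);
      if (j > 0) {
        int sub = (q[i - 1] == t[s + j - 1] && q[i - 1] < 4) ? 0 : 1;
        v = std::min(v, prev[j - 1] + sub); // diagonal, always in row i-1's band
        if (j - 1 >= lo) v = std::min(v, cur[j - 1] + 1);
      } else {
        v = std::min(v, i); // D[i][0] = i
      }
      cur[j] = v;
      rowmin = std::min(rowmin, v);
    }
    if (rowmin > max_d) return BIG; // early abandon
    std::swap(prev, cur);
  }
  long lo = std::max(0L, (long)k - max_d), hi = std::min(wlen, (long)k + max_d);
  for (long j = lo; j <= hi; ++j) {
    if (prev[j] < best) { best = prev[j]; best_end = s + j; }
  }
  if (end_out) *end_out = best_end;
  return best;
}

// Exact engine: per-start minimum distance for every start, via reversed DP.
// dists[s] = min over e of edit distance(query, text[s:e]).
static void per_start_minima(const std::vector<int>& q, const std::vector<int>& t,
                             int max_d, std::vector<int>& dists) {
  const int k = (int)q.size();
  const long L = (long)t.size();
  dists.assign(L, BIG);
  // reversed query vs reversed text, free alignment start (first row 0):
  // column value at reversed position j (row k) = min over starts i<=j of
  // Lev(rev q, rev t[i:j]) = min over e of Lev(q, t[L-j:e]).
  std::vector<int> col(k + 1);
  std::vector<int> qr(q.rbegin(), q.rend());
  for (int i = 0; i <= k; ++i) col[i] = i;
  // j = 0: empty window, distance k (only relevant if k <= max_d; starts at L
  // are not reportable anyway).
  for (long j = 1; j <= L; ++j) {
    int tc = t[L - j];
    int diag = col[0]; // D[i-1][j-1] before overwrite
    col[0] = 0;
    int colmin = 0;
    for (int i = 1; i <= k; ++i) {
      int sub = (qr[i - 1] == tc && tc < 4) ? diag : diag + 1;
      int v = std::min(sub, std::min(col[i] + 1, col[i - 1] + 1));
      diag = col[i];
      col[i] = v;
      colmin = std::min(colmin, v);
    }
    long s = L - j;
    if (col[k] <= max_d) dists[s] = col[k];
  }
}

static List hits_to_list(const std::vector<long>& starts,
                         const std::vector<long>& ends,
                         const std::vector<int>& ds) {
  return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                      _["dist"] = wrap(ds));
}

// [[Rcpp::export]]
List cpp_hits_exact(std::string query, std::string text, int max_d) {
  std::vector<int> q = encode(query), t = encode(text);
  std::vector<int> dists;
  per_start_minima(q, t, max_d, dists);
  std::vector<long> starts, ends;
  std::vector<int> ds;
  for (long s = 0; s < (long)t.size(); ++s) {
    if (dists[s] <= max_d) {
      long e = -1;
      int d = anchored_dist(q, t, s, max_d, &e);
      starts.push_back(s);
      ends.push_back(e);
      ds.push_back(d);
    }
  }
  return hits_to_list(starts, ends, ds);
}

// ---- seeded engine ---------------------------------------------------------

// Non-overlapping seed layout covering the query: max_d+1 pieces.
static void seed_layout(int k, int max_d, std::vector<int>& off, std::vector<int>& len) {
  int n = max_d + 1;
  off.clear(); len.clear();
  int base = k / n, extra = k % n, pos = 0;
  for (int i = 0; i < n; ++i) {
    int l = base + (i < extra ? 1 : 0);
    if (l <= 0) continue; // cannot happen for max_d < k
    off.push_back(pos); len.push_back(l);
    pos += l;
  }
}

// Exact occurrences of pattern (encoded, no N) in text; naive scan.
static void find_exact(const std::vector<int>& t, const std::vector<int>& p,
                       long from, std::vector<long>& out) {
  long L = (long)t.size(), m = (long)p.size();
  for (long i = from; i + m <= L; ++i) {
    long j = 0;
    while (j < m && t[i + j] == p[j] && t[i + j] < 4) ++j;
    if (j == m) out.push_back(i);
  }
}

static void seeded_candidates(const std::vector<int>& q, const std::vector<int>& t,
                              int max_d, std::vector<long>& cand) {
  const int k = (int)q.size();
  const long L = (long)t.size();
  std::vector<int> off, len;
  seed_layout(k, max_d, off, len);
  std::vector<long> occ;
  for (size_t i = 0; i < off.size(); ++i) {
    std::vector<int> p(q.begin() + off[i], q.begin() + off[i] + len[i]);
    occ.clear();
    find_exact(t, p, 0, occ);
    for (long pos : occ) {
      long c0 = pos - off[i] - max_d, c1 = pos - off[i] + max_d;
      for (long s = std::max(0L, c0); s <= std::min(L - 1, c1); ++s)
        cand.push_back(s);
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
}

// [[Rcpp::export]]
List cpp_hits_seeded(std::string query, std::string text, int max_d) {
  std::vector<int> q = encode(query), t = encode(text);
  std::vector<long> cand;
  seeded_candidates(q, t, max_d, cand);
  std::vector<long> starts, ends;
  std::vector<int> ds;
  for (long s : cand) {
    long e = -1;
    int d = anchored_dist(q, t, s, max_d, &e);
    if (d <= max_d) { starts.push_back(s); ends.push_back(e); ds.push_back(d); }
  }
  return hits_to_list(starts, ends, ds);
}

// ---- batch collapsed counting ---------------------------------------------

// q-gram chain index over the text for one seed length.
struct QGramIndex {
  int q;                       // indexed prefix length (<= seed length)
  std::vector<long> head;      // 4^q entries, -1 terminated chains
  std::vector<long> nxt;
  void build(const std::vector<int>& t, int q_) {
    q = q_;
    head.assign(1L << (2 * q), -1);
    nxt.assign(t.size(), -1);
    long L = (long)t.size();
    if (L < q) return;
    // rolling code right-to-left so chains come out in ascending position
    for (long i = L - q; i >= 0; --i) {
      long code = 0; bool ok = true;
      for (int j = 0; j < q; ++j) {
        if (t[i + j] >= 4) { ok = false; break; }
        code = (code << 2) | t[i + j];
      }
      if (!ok) continue;
      nxt[i] = head[code];
      head[code] = i;
    }
  }
};

// Collapsed hit count (single-linkage grouping: a new group starts when the
// gap between successive hit starts exceeds max_d) for one query against one
// text, one strand; stops early once `cap` groups are seen.
static int count_collapsed_one(const std::vector<int>& q, const std::vector<int>& t,
                               int max_d, int cap,
                               const std::vector<QGramIndex>& idx,
                               const std::vector<int>& off, const std::vector<int>& len) {
  const long L = (long)t.size();
  std::vector<long> cand;
  for (size_t i = 0; i < off.size(); ++i) {
    const QGramIndex& ix = idx[i];
    long code = 0; bool ok = true;
    for (int j = 0; j < ix.q; ++j) {
      if (q[off[i] + j] >= 4) { ok = false; break; }
      code = (code << 2) | q[off[i] + j];
    }
    if (!ok) continue;
    for (long p = ix.head[code]; p >= 0; p = ix.nxt[p]) {
      // verify the full seed (index may cover only a prefix)
      bool full = true;
      if (ix.q < len[i]) {
        if (p + len[i] > L) continue;
        for (int j = ix.q; j < len[i]; ++j)
          if (t[p + j] != q[off[i] + j] || t[p + j] >= 4) { full = false; break; }
      }
      if (!full) continue;
      long c0 = p - off[i] - max_d, c1 = p - off[i] + max_d;
      for (long s = std::max(0L, c0); s <= std::min(L - 1, c1); ++s)
        cand.push_back(s);
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  int groups = 0;
  long last = -(long)max_d - 2;
  for (long s : cand) {
    int d = anchored_dist(q, t, s, max_d, nullptr);
    if (d <= max_d) {
      if (s - last > max_d) {
        ++groups;
        if (groups >= cap) return groups;
      }
      last = s;
    }
  }
  return groups;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'C': c = 'G'; break;
    case 'G': c = 'C'; break; case 'T': c = 'A'; break;
    case 'a': c = 't'; break; case 'c': c = 'g'; break;
    case 'g': c = 'c'; break; case 't': c = 'a'; break;
    default: c = 'N';
    }
  }
  return r;
}

// exact-engine collapsed counting: per-start minima over the whole text
static int count_collapsed_exact(const std::vector<int>& q, const std::vector<int>& t,
                                 int max_d, int cap) {
  std::vector<int> dists;
  per_start_minima(q, t, max_d, dists);
  int groups = 0;
  long last = -(long)max_d - 2;
  for (long s = 0; s < (long)dists.size(); ++s) {
    if (dists[s] <= max_d) {
      if (s - last > max_d) {
        ++groups;
        if (groups >= cap) return groups;
      }
      last = s;
    }
  }
  return groups;
}

// [[Rcpp::export]]
IntegerVector cpp_count_collapsed_batch(CharacterVector queries, std::string text,
                                        int max_d, bool both_strands,
                                        IntegerVector caps, bool exact_engine) {
  std::vector<int> t = encode(text);
  int nq = queries.size();
  IntegerVector out(nq, 0);
  if (nq == 0) return out;
  int k = LENGTH(STRING_ELT(queries, 0));
  std::vector<int> off, len;
  seed_layout(k, max_d, off, len);
  std::vector<QGramIndex> idx(off.size());
  if (!exact_engine) {
    for (size_t i = 0; i < off.size(); ++i)
      idx[i].build(t, std::min(len[i], 10));
  }
  for (int i = 0; i < nq; ++i) {
    int cap = caps[i];
    if (cap <= 0) { out[i] = NA_INTEGER; continue; }
    std::string qs = as<std::string>(queries[i]);
    std::vector<int> q = encode(qs);
    int n = exact_engine ? count_collapsed_exact(q, t, max_d, cap)
                         : count_collapsed_one(q, t, max_d, cap, idx, off, len);
    if (n < cap && both_strands) {
      std::vector<int> qr = encode(revcomp_str(qs));
      n += exact_engine
             ? count_collapsed_exact(qr, t, max_d, cap - n)
             : count_collapsed_one(qr, t, max_d, cap - n, idx, off, len);
    }
    out[i] = std::min(n, cap);
  }
  return out;
}

// ---- Hamming mappability ---------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_hamming_count_batch(CharacterVector queries, std::string text,
                                      int max_mm, int cap) {
  std::vector<int> t = encode(text);
  long L = (long)t.size();
  int nq = queries.size();
  IntegerVector out(nq, 0);
  for (int i = 0; i < nq; ++i) {
    std::string qs = as<std::string>(queries[i]);
    std::vector<int> q = encode(qs);
    int k = (int)q.size();
    int cnt = 0;
    for (long s = 0; s + k <= L; ++s) {
      int mm = 0;
      for (int j = 0; j < k; ++j) {
        if (t[s + j] != q[j] || t[s + j] >= 4) {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) {
        if (++cnt >= cap) break;
      }
    }
    out[i] = cnt;
  }
  return out;
}
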