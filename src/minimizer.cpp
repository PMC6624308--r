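#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// 64-bit mixer (splitmix64). Output is masked to 53 bits so the hash is
// exactly representable as an R double.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static const uint64_t HASH_MASK = (1ULL << 53) - 1;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct Kmer {
  double hash;
  int pos;     // 0-based start of the k-mer
  int strand;  // +1 if forward code <= reverse-complement code (ties -> +1)
};

// Enumerate canonical k-mer hashes of a sequence; k-mers containing a
// non-ACGT base are skipped. Returns one entry per valid k-mer start.
static void kmer_hashes(const std::string& seq, int k, uint64_t seed,
                        std::vector<Kmer>& out) {
  const int n = (int)seq.size();
  out.clear();
  if (n < k) return;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t fwd = 0, rc = 0;
  int valid = 0;  // number of consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    ++valid;
    if (valid >= k) {
      uint64_t canon = (fwd <= rc) ? fwd : rc;
      int strand = (fwd <= rc) ? 1 : -1;
      uint64_t h = mix64(canon ^ seed) & HASH_MASK;
      out.push_back({ (double)h, i - k + 1, strand });
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_kmer_hashes(std::string seq, int k, double seed) {
  std::vector<Kmer> km;
  kmer_hashes(seq, k, (uint64_t)seed, km);
  int n = (int)km.size();
  NumericVector hash(n); IntegerVector pos(n), strand(n);
  for (int i = 0; i < n; ++i) {
    hash[i] = km[i].hash; pos[i] = km[i].pos; strand[i] = km[i].strand;
  }
  return DataFrame::create(_["hash"] = hash, _["pos"] = pos,
                           _["strand"] = strand);
}

// Winnowing: within every window of w consecutive valid k-mers, keep the
// minimum-hash k-mer (leftmost on ties); each selected position reported
// once. Runs of fewer than w valid k-mers (short sequences or gaps between
// ambiguous bases) contribute the minimum of the run so that short contigs
// are still represented.
// [[Rcpp::export]]
DataFrame cpp_winnow(std::string seq, int k, int w, double seed) {
  std::vector<Kmer> km;
  kmer_hashes(seq, k, (uint64_t)seed, km);
  std::vector<Kmer> out;
  const int n = (int)km.size();
  int run_start = 0;
  auto flush_run = [&](int s, int e) {  // [s, e): consecutive k-mers
    int len = e - s;
    if (len <= 0) return;
    int last_emitted = -1;
    if (len < w) {  // truncated window: single minimum of the run
      int best = s;
      for (int i = s + 1; i < e; ++i)
        if (km[i].hash < km[best].hash) best = i;
      out.push_back(km[best]);
      return;
    }
    std::deque<int> dq;  // indices, hashes increasing; front = window min
    for (int i = s; i < e; ++i) {
      while (!dq.empty() && km[dq.back()].hash > km[i].hash) dq.pop_back();
      dq.push_back(i);
      if (dq.front() <= i - w) dq.pop_front();
      if (i - s >= w - 1) {
        int m = dq.front();
        if (m != last_emitted) { out.push_back(km[m]); last_emitted = m; }
      }
    }
  };
  for (int i = 1; i <= n; ++i) {
    if (i == n || km[i].pos != km[i - 1].pos + 1) {
      flush_run(run_start, i);
      run_start = i;
    }
  }
  int m = (int)out.size();
  NumericVector hash(m); IntegerVector pos(m), strand(m);
  for (int i = 0; i < m; ++i) {
    hash[i] = out[i].hash; pos[i] = out[i].pos; strand[i] = out[i].strand;
  }
  return DataFrame::create(_["hash"] = hash, _["pos"] = pos,
                           _["strand"] = strand);
}

// Candidate window scan. Input rows are minimizer matches between one read
// and one contig, sorted by group (= read x contig) and reference position.
// For each anchor row i, the window [pos_i, pos_i + L) is scored by the
// number of distinct read minimizers (hid) it contains; windows with
// >= m_min distinct matches are kept and overlapping windows are merged,
// retaining the (leftmost) maximal-count anchor per merged cluster.
//
// grp: 0-based group id per row (non-decreasing); L: window extent per group.
// Returns one row per candidate: grp, row_lo/row_hi (1-based, half-open row
// range of the winning window), start (anchor position), count.
// [[Rcpp::export]]
DataFrame cpp_scan_candidates(IntegerVector grp, IntegerVector pos,
                              IntegerVector hid, IntegerVector L_grp,
                              int m_min) {
  const int n = grp.size();
  std::vector<int> o_grp, o_lo, o_hi, o_start, o_count;
  int s = 0;
  while (s < n) {
    int e = s;
    while (e < n && grp[e] == grp[s]) ++e;
    const int L = L_grp[grp[s]];
    // distinct-count two-pointer over [i, j)
    std::unordered_map<int, int> cnt;
    int distinct = 0, j = s;
    std::vector<int> wcount(e - s), wend(e - s);
    for (int i = s; i < e; ++i) {
      while (j < e && pos[j] < pos[i] + L) {
        if (++cnt[hid[j]] == 1) ++distinct;
        ++j;
      }
      wcount[i - s] = distinct;
      wend[i - s] = j;
      if (--cnt[hid[i]] == 0) --distinct;
    }
    // select + merge overlapping windows, keep leftmost argmax per cluster
    int i = s;
    while (i < e) {
      if (wcount[i - s] < m_min) { ++i; continue; }
      int best = i, last = i, t = i + 1;
      while (t < e && wcount[t - s] >= m_min && pos[t] <= pos[last] + L - 1) {
        if (wcount[t - s] > wcount[best - s]) best = t;
        last = t; ++t;
      }
      o_grp.push_back(grp[s]);
      o_lo.push_back(best + 1);
      o_hi.push_back(wend[best - s] + 1);
      o_start.push_back(pos[best]);
      o_count.push_back(wcount[best - s]);
      i = t;
    }
    s = e;
  }
  return DataFrame::create(_["grp"] = wrap(o_grp), _["row_lo"] = wrap(o_lo),
                           _["row_hi"] = wrap(o_hi),
                           _["start"] = wrap(o_start),
                           _["count"] = wrap(o_count));
}

// Winnowed-minhash sketch statistics: a and b are sorted, distinct hash
// vectors; the union sketch is the `cap` smallest values of union(a, b).
// Returns (n_union = |sketch|, n_shared = |sketch ∩ a ∩ b|).
// [[Rcpp::export]]
IntegerVector cpp_sketch_stats(NumericVector a, NumericVector b, int cap) {
  const int na = a.size(), nb = b.size();
  int ia = 0, ib = 0, taken = 0, shared = 0;
  while (taken < cap && (ia < na || ib < nb)) {
    bool inA = false, inB = false;
    if (ib >= nb || (ia < na && a[ia] < b[ib])) { inA = true; }
    else if (ia >= na || b[ib] < a[ia]) { inB = true; }
    else { inA = true; inB = true; }
    if (inA) ++ia;
    if (inB) ++ib;
    ++taken;
    if (inA && inB) ++shared;
  }
  return IntegerVector::create(taken, shared);
}
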