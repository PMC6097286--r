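#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// 2-bit nucleotide code; -1 for anything that is not A/C/G/T
static inline int nt_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct Hit { int q; int t; };

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

// index all valid k-mers of s; positions capped at max_occ + 1
static void build_index(const char *s, int n, int k, int max_occ,
                        KmerIndex &index) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  index.reserve((size_t)n);
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = nt_code(s[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      std::vector<int> &v = index[h];
      if ((int)v.size() <= max_occ) v.push_back(i - k + 1);
    }
  }
  for (auto it = index.begin(); it != index.end();) {
    if ((int)it->second.size() > max_occ) it = index.erase(it);
    else ++it;
  }
}

// scan s against the index, collecting hits (hit.q = scanned side)
static void scan_hits(const char *s, int n, int k, const KmerIndex &index,
                      std::vector<Hit> &hits,
                      std::unordered_map<uint64_t, int> *scan_count) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = nt_code(s[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      KmerIndex::const_iterator it = index.find(h);
      if (it != index.end()) {
        if (scan_count) ++(*scan_count)[h];
        int p = i - k + 1;
        for (int hp : it->second) {
          Hit hh; hh.q = p; hh.t = hp;
          hits.push_back(hh);
        }
      }
    }
  }
}

// merge hits (q = query pos, t = target pos, both 0-based) along
// diagonals into maximal exact matches; returns 1-based matrix
static IntegerMatrix merge_hits(std::vector<Hit> &hits, int k) {
  if (hits.empty()) {
    IntegerMatrix out(0, 3);
    colnames(out) = CharacterVector::create("qstart", "tstart", "len");
    return out;
  }
  std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
    long long da = (long long)a.t - a.q, db = (long long)b.t - b.q;
    if (da != db) return da < db;
    return a.q < b.q;
  });
  std::vector<int> qs, ts, len;
  int cq = hits[0].q, ct = hits[0].t, clen = k;
  for (size_t i = 1; i < hits.size(); ++i) {
    long long dprev = (long long)ct - cq;
    long long dcur = (long long)hits[i].t - hits[i].q;
    if (dcur == dprev && hits[i].q == cq + clen - k + 1) {
      clen = hits[i].q + k - cq;
    } else if (dcur == dprev && hits[i].q <= cq + clen - k) {
      // duplicate within the current run; skip
    } else {
      qs.push_back(cq); ts.push_back(ct); len.push_back(clen);
      cq = hits[i].q; ct = hits[i].t; clen = k;
    }
  }
  qs.push_back(cq); ts.push_back(ct); len.push_back(clen);
  IntegerMatrix out((int)qs.size(), 3);
  for (int i = 0; i < (int)qs.size(); ++i) {
    out(i, 0) = qs[i] + 1;
    out(i, 1) = ts[i] + 1;
    out(i, 2) = len[i];
  }
  colnames(out) = CharacterVector::create("qstart", "tstart", "len");
  return out;
}

// Exact k-mer matches between query and target (forward strands),
// merged along diagonals into maximal exact matches. k in [2, 31].
// K-mers containing non-ACGT are skipped; k-mers occurring more than
// max_occ times in either sequence are skipped (repeat masking).
// [[Rcpp::export(name = ".kmerMatchesCpp")]]
IntegerMatrix kmer_matches_cpp(CharacterVector query,
                               CharacterVector target,
                               int k, int max_occ) {
  const char *q = CHAR(STRING_ELT(query, 0));
  const char *t = CHAR(STRING_ELT(target, 0));
  const int nq = (int)std::strlen(q), nt = (int)std::strlen(t);
  if (k < 2 || k > 31 || nq < k || nt < k) {
    IntegerMatrix out(0, 3);
    colnames(out) = CharacterVector::create("qstart", "tstart", "len");
    return out;
  }
  const bool hash_query = nq <= nt;
  const char *hs = hash_query ? q : t;
  const char *sc = hash_query ? t : q;
  const int nh = hash_query ? nq : nt, ns = hash_query ? nt : nq;

  KmerIndex index;
  build_index(hs, nh, k, max_occ, index);
  std::vector<Hit> hits;
  std::unordered_map<uint64_t, int> scan_count;
  scan_hits(sc, ns, k, index, hits, &scan_count);

  // symmetric max_occ filter: drop hits whose k-mer is over-represented
  // on the scanned side (replay the scan to recover each hit's key)
  bool need_filter = false;
  for (auto &kv : scan_count)
    if (kv.second > max_occ) { need_filter = true; break; }
  if (need_filter) {
    std::vector<Hit> kept;
    kept.reserve(hits.size());
    const uint64_t mask = (1ULL << (2 * k)) - 1;
    uint64_t h = 0; int run = 0; size_t hi = 0;
    for (int i = 0; i < ns && hi < hits.size(); ++i) {
      int c = nt_code(sc[i]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        KmerIndex::const_iterator it = index.find(h);
        if (it != index.end()) {
          bool ok = scan_count[h] <= max_occ;
          for (size_t j = 0; j < it->second.size(); ++j, ++hi)
            if (ok) kept.push_back(hits[hi]);
        }
      }
    }
    hits.swap(kept);
  }
  // orient hits so .q is always the query side
  if (!hash_query) {
    // hits.q = scanned = query side already
  } else {
    for (auto &hh : hits) std::swap(hh.q, hh.t);
  }
  return merge_hits(hits, k);
}

// Batched variant: the target is indexed once and every query (e.g.
// sampled scaffold segments, both strands) is scanned against it.
// Returns a list of match matrices, one per query.
// [[Rcpp::export(name = ".kmerMatchesBatchCpp")]]
List kmer_matches_batch_cpp(CharacterVector queries,
                            CharacterVector target,
                            int k, int max_occ) {
  const char *t = CHAR(STRING_ELT(target, 0));
  const int nt = (int)std::strlen(t);
  List out(queries.size());
  if (k < 2 || k > 31 || nt < k) {
    for (int i = 0; i < queries.size(); ++i) {
      IntegerMatrix m(0, 3);
      colnames(m) = CharacterVector::create("qstart", "tstart", "len");
      out[i] = m;
    }
    return out;
  }
  KmerIndex index;
  build_index(t, nt, k, max_occ, index);
  for (int i = 0; i < queries.size(); ++i) {
    const char *q = CHAR(STRING_ELT(queries, i));
    const int nq = (int)std::strlen(q);
    std::vector<Hit> hits;
    if (nq >= k) scan_hits(q, nq, k, index, hits, NULL);
    out[i] = merge_hits(hits, k);
  }
  return out;
}

// Offsets (1-based, relative to the given 1-based starts) at which
// a[a_start + i] differs from b[b_start + i], i in 0..len-1.
// [[Rcpp::export(name = ".mismatchOffsetsCpp")]]
IntegerVector mismatch_offsets_cpp(CharacterVector a, CharacterVector b,
                                   int a_start, int b_start, int len) {
  const char *pa = CHAR(STRING_ELT(a, 0));
  const char *pb = CHAR(STRING_ELT(b, 0));
  const int na = (int)std::strlen(pa), nb = (int)std::strlen(pb);
  std::vector<int> out;
  for (int i = 0; i < len; ++i) {
    int ia = a_start - 1 + i, ib = b_start - 1 + i;
    if (ia >= na || ib >= nb) break;
    if (pa[ia] != pb[ib]) out.push_back(i + 1);
  }
  return wrap(out);
}

// Runs of non-ACGT characters (N gaps); 1-based start/end columns.
// [[Rcpp::export(name = ".nRunsCpp")]]
IntegerMatrix n_runs_cpp(CharacterVector seq) {
  const char *s = CHAR(STRING_ELT(seq, 0));
  const int n = (int)std::strlen(s);
  std::vector<int> st, en;
  int i = 0;
  while (i < n) {
    if (nt_code(s[i]) < 0) {
      int j = i;
      while (j < n && nt_code(s[j]) < 0) ++j;
      st.push_back(i + 1); en.push_back(j);
      i = j;
    } else ++i;
  }
  IntegerMatrix out((int)st.size(), 2);
  for (int i2 = 0; i2 < (int)st.size(); ++i2) {
    out(i2, 0) = st[i2]; out(i2, 1) = en[i2];
  }
  colnames(out) = CharacterVector::create("start", "end");
  return out;
}
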