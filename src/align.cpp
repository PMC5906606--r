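#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Global alignment with free end gaps ("overlap" alignment). Identity and
// coverage are computed on the aligned region only: terminal overhangs are
// excluded from the column count, mirroring BLAST-style local reporting.
// Traceback prefers diagonal, then up, then left, so results are
// deterministic for tied optima.

struct AlnStats {
  double score;
  int matches;
  int columns;
  int longest_run;
  int short_res_aligned; // residues of the shorter sequence inside the aligned region
};

static AlnStats align_core(const std::string& a, const std::string& b,
                           double match, double mismatch, double gap) {
  const int la = (int) a.size(), lb = (int) b.size();
  // H has (la+1) x (lb+1) cells; free leading gaps -> borders are 0.
  std::vector<double> H((size_t)(la + 1) * (lb + 1), 0.0);
  auto at = [&](int i, int j) -> double& { return H[(size_t)i * (lb + 1) + j]; };
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double best = at(i - 1, j - 1) + s;
      double up = at(i - 1, j) + gap;
      double lf = at(i, j - 1) + gap;
      if (up > best) best = up;
      if (lf > best) best = lf;
      at(i, j) = best;
    }
  }
  // Free trailing gaps: best cell over last row and last column.
  int bi = la, bj = lb;
  double best = at(la, lb);
  for (int j = 0; j <= lb; ++j)
    if (at(la, j) > best) { best = at(la, j); bi = la; bj = j; }
  for (int i = 0; i <= la; ++i)
    if (at(i, lb) > best) { best = at(i, lb); bi = i; bj = lb; }

  AlnStats st; st.score = best; st.matches = 0; st.columns = 0;
  st.longest_run = 0; st.short_res_aligned = 0;
  int i = bi, j = bj, run = 0;
  int a_res = 0, b_res = 0;
  const double eps = 1e-9;
  while (i > 0 && j > 0) {
    double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
    if (std::abs(at(i, j) - (at(i - 1, j - 1) + s)) < eps) {
      ++st.columns; ++a_res; ++b_res;
      if (a[i - 1] == b[j - 1]) { ++st.matches; ++run; if (run > st.longest_run) st.longest_run = run; }
      else run = 0;
      --i; --j;
    } else if (std::abs(at(i, j) - (at(i - 1, j) + gap)) < eps) {
      ++st.columns; ++a_res; run = 0; --i;
    } else {
      ++st.columns; ++b_res; run = 0; --j;
    }
  }
  st.short_res_aligned = (la <= lb) ? a_res : b_res;
  return st;
}

static List stats_to_list(const AlnStats& st, int la, int lb) {
  int shorter = la <= lb ? la : lb;
  double identity = st.columns > 0 ? (double) st.matches / st.columns : 0.0;
  double coverage = shorter > 0 ? (double) st.short_res_aligned / shorter : 0.0;
  return List::create(
    _["identity"] = identity,
    _["coverage"] = coverage,
    _["longest_perfect_run"] = st.longest_run,
    _["score"] = st.score,
    _["matches"] = st.matches,
    _["columns"] = st.columns);
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, double match, double mismatch, double gap) {
  AlnStats st = align_core(a, b, match, mismatch, gap);
  return stats_to_list(st, (int) a.size(), (int) b.size());
}

// [[Rcpp::export]]
NumericMatrix cpp_align_many(std::string q, CharacterVector refs,
                             double match, double mismatch, double gap) {
  int n = refs.size();
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("identity", "coverage",
           "longest_perfect_run", "score", "matches", "columns");
  for (int r = 0; r < n; ++r) {
    std::string b = as<std::string>(refs[r]);
    AlnStats st = align_core(q, b, match, mismatch, gap);
    int shorter = (int) std::min(q.size(), b.size());
    out(r, 0) = st.columns > 0 ? (double) st.matches / st.columns : 0.0;
    out(r, 1) = shorter > 0 ? (double) st.short_res_aligned / shorter : 0.0;
    out(r, 2) = st.longest_run;
    out(r, 3) = st.score;
    out(r, 4) = st.matches;
    out(r, 5) = st.columns;
  }
  return out;
}

// Identity for clustering / best-reference decisions: matches over the
// aligned columns plus the unaligned extent of the shorter sequence. This
// "global" normalization prevents short perfect overlaps between unrelated
// sequences from scoring as high identity.
static inline double global_identity(const AlnStats& st, int la, int lb) {
  int shorter = la <= lb ? la : lb;
  int denom = st.columns + (shorter - st.short_res_aligned);
  return denom > 0 ? (double) st.matches / denom : 0.0;
}

static inline uint64_t fnv1a(const char* s, int len) {
  uint64_t h = 1469598103934665603ULL;
  for (int i = 0; i < len; ++i) { h ^= (uint64_t)(unsigned char) s[i]; h *= 1099511628211ULL; }
  return h;
}

// Hamming distance with early exit once `limit` is exceeded; returns limit+1 then.
static inline int hamming_capped(const char* a, const char* b, int len, int limit) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (a[i] != b[i]) { if (++mm > limit) return mm; }
  }
  return mm;
}

// Greedy centroid clustering. `seqs` must already be ordered (decreasing
// abundance, ties lexicographic); each sequence joins the first existing
// centroid whose identity is >= threshold, else founds a new centroid.
// When all sequences share one length and `use_hamming` is true, membership
// is decided by ungapped mismatch count (identical to the gapped optimum for
// high thresholds under substitution-only divergence), accelerated by a
// blocked exact-substring prefilter: with <= max_mm mismatches at least
// nb - max_mm of nb fixed-position blocks are intact.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold,
                                 double match, double mismatch, double gap,
                                 bool use_hamming) {
  int n = seqs.size();
  IntegerVector otu(n);
  if (n == 0) return otu;
  std::vector<const char*> ptr(n);
  std::vector<int> len(n);
  bool same_len = true;
  for (int i = 0; i < n; ++i) {
    ptr[i] = CHAR(STRING_ELT(seqs, i));
    len[i] = (int) LENGTH(STRING_ELT(seqs, i));
    if (len[i] != len[0]) same_len = false;
  }
  std::vector<int> centroid; // indices into seqs, in founding order

  if (use_hamming && same_len && len[0] >= 32) {
    const int L = len[0];
    const int max_mm = (int) std::floor((1.0 - threshold) * L + 1e-9);
    const int nb = 16;
    std::vector<int> b0(nb), blen(nb);
    for (int k = 0; k < nb; ++k) {
      b0[k] = (int) ((long long) k * L / nb);
      blen[k] = (int) ((long long)(k + 1) * L / nb) - b0[k];
    }
    const int min_votes = nb - max_mm > 1 ? nb - max_mm : 1;
    std::vector<std::unordered_map<uint64_t, std::vector<int>>> maps(nb);
    std::vector<int> votes; votes.reserve(1024);
    std::vector<int> touched; touched.reserve(256);
    std::vector<int> cand; cand.reserve(64);
    for (int i = 0; i < n; ++i) {
      uint64_t h[16];
      for (int k = 0; k < nb; ++k) h[k] = fnv1a(ptr[i] + b0[k], blen[k]);
      // vote counting over candidate centroids
      votes.resize(centroid.size(), 0);
      touched.clear(); cand.clear();
      for (int k = 0; k < nb; ++k) {
        auto it = maps[k].find(h[k]);
        if (it == maps[k].end()) continue;
        for (int c : it->second) {
          if (votes[c] == 0) touched.push_back(c);
          if (++votes[c] == min_votes) cand.push_back(c);
        }
      }
      std::sort(cand.begin(), cand.end()); // first-centroid rule
      int hit = -1;
      for (int c : cand) {
        if (hamming_capped(ptr[i], ptr[centroid[c]], L, max_mm) <= max_mm) { hit = c; break; }
      }
      for (int c : touched) votes[c] = 0;
      if (hit < 0) {
        hit = (int) centroid.size();
        centroid.push_back(i);
        for (int k = 0; k < nb; ++k) maps[k][h[k]].push_back(hit);
      }
      otu[i] = hit + 1;
    }
  } else {
    // general path: gapped identity against each centroid in order
    for (int i = 0; i < n; ++i) {
      std::string a(ptr[i], (size_t) len[i]);
      int hit = -1;
      for (size_t c = 0; c < centroid.size(); ++c) {
        std::string b(ptr[centroid[c]], (size_t) len[centroid[c]]);
        AlnStats st = align_core(a, b, match, mismatch, gap);
        double ident = global_identity(st, (int) a.size(), (int) b.size());
        if (ident >= threshold - 1e-12) { hit = (int) c; break; }
      }
      if (hit < 0) { hit = (int) centroid.size(); centroid.push_back(i); }
      otu[i] = hit + 1;
    }
  }
  return otu;
}

// Best-reference assignment (closed-reference clustering / nearest neighbour).
// Returns, per read, the 1-based index of the highest-identity reference with
// identity >= threshold (ties -> lowest reference index) or 0, plus the best
// identity seen regardless of threshold.
// [[Rcpp::export]]
List cpp_assign_best(CharacterVector reads, CharacterVector refs, double threshold,
                     double match, double mismatch, double gap, bool use_hamming) {
  int n = reads.size(), m = refs.size();
  IntegerVector best_ref(n);
  NumericVector best_id(n);
  std::vector<const char*> rptr(m); std::vector<int> rlen(m);
  for (int r = 0; r < m; ++r) {
    rptr[r] = CHAR(STRING_ELT(refs, r));
    rlen[r] = (int) LENGTH(STRING_ELT(refs, r));
  }
  for (int i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(reads, i));
    int ql = (int) LENGTH(STRING_ELT(reads, i));
    double bid = -1.0; int bref = 0;
    for (int r = 0; r < m; ++r) {
      double ident;
      if (use_hamming && rlen[r] == ql) {
        int mm = hamming_capped(q, rptr[r], ql, ql);
        ident = 1.0 - (double) mm / ql;
      } else {
        AlnStats st = align_core(std::string(q, (size_t) ql),
                                 std::string(rptr[r], (size_t) rlen[r]),
                                 match, mismatch, gap);
        ident = global_identity(st, ql, rlen[r]);
      }
      if (ident > bid + 1e-12) { bid = ident; bref = r + 1; }
    }
    best_id[i] = bid;
    best_ref[i] = (bid >= threshold - 1e-12) ? bref : 0;
  }
  return List::create(_["ref"] = best_ref, _["identity"] = best_id);
}
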