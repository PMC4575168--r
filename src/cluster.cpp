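#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// identity between two sequences under a global alignment with match 1,
// mismatch 0, gap 0. Among equal-score optima the alignment with the
// fewest gaps (most aligned pairs) is chosen, so a same-length single
// substitution scores (n-1)/n rather than (n-1)/(n+1). The DP maximises
// the packed objective matches * BIG + aligned_pairs; identity =
// matches / (n1 + n2 - aligned_pairs).

#define PACK_SHIFT 20
#define PACK_MASK ((1 << PACK_SHIFT) - 1)

static long long align_pack(const std::string &a, const std::string &b,
                            std::vector<long long> &dp) {
  const int n = (int)a.size(), m = (int)b.size();
  dp.assign(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    long long diag = 0; // dp[i-1][j-1]
    for (int j = 1; j <= m; ++j) {
      long long tmp = dp[j];
      long long best = dp[j] > dp[j - 1] ? dp[j] : dp[j - 1];
      long long cand = diag + 1 +
        ((a[i - 1] == b[j - 1]) ? (1LL << PACK_SHIFT) : 0);
      if (cand > best) best = cand;
      dp[j] = best;
      diag = tmp;
    }
  }
  return dp[m];
}

static double identity_from_pack(long long v, int n1, int n2) {
  long long matches = v >> PACK_SHIFT;
  long long pairs = v & PACK_MASK;
  if (n1 + n2 == 0) return 1.0;
  return (double)matches / (double)(n1 + n2 - pairs);
}

// 32-bin histogram over 'A'..'Z' (and '*', which maps into an unused bin)
static void histo(const std::string &s, int *h) {
  std::memset(h, 0, 32 * sizeof(int));
  for (char c : s) h[(unsigned char)c & 31]++;
}

// [[Rcpp::export(name = ".pair_identity_cpp")]]
double pair_identity_cpp(std::string a, std::string b) {
  if (a.empty() && b.empty()) return 1.0;
  std::vector<long long> dp;
  return identity_from_pack(align_pack(a, b, dp), (int)a.size(),
                            (int)b.size());
}

// Greedy centroid clustering: sequences are visited in the given order
// (callers sort by descending count, lexicographic tie-break); a sequence
// joins the first centroid with identity >= threshold, else founds a new
// cluster. Returns 1-based cluster ids per sequence.
//
// A cheap upper bound prunes most centroid comparisons: matches are at most
// min(n1, n2) and at most the character-multiset intersection, while the
// alignment length is at least max(n1, n2), so identity <=
// bound / max(n1, n2) rules most pairs out without running the DP.
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double threshold) {
  const int n = seqs.size();
  IntegerVector out(n);
  std::vector<std::string> cent;
  std::vector<int> cent_h;  // 32 bins per centroid, contiguous
  std::vector<long long> dp;
  cent.reserve(1024);
  int h[32];
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    histo(s, h);
    int joined = -1;
    const int ns = (int)s.size();
    for (size_t c = 0; c < cent.size(); ++c) {
      const int nc = (int)cent[c].size();
      // identity <= matches / max(ns, nc): matches needed for >= t
      double need = threshold * (ns > nc ? ns : nc);
      int bound = ns < nc ? ns : nc;
      if ((double)bound < need) continue;
      const int *hc = cent_h.data() + 32 * c;
      int inter = 0;
      for (int k = 0; k < 32; ++k)
        inter += h[k] < hc[k] ? h[k] : hc[k];
      if ((double)inter < need) continue;
      double ident = identity_from_pack(align_pack(s, cent[c], dp), ns, nc);
      if (ident >= threshold) { joined = (int)c; break; }
    }
    if (joined < 0) {
      cent.push_back(s);
      cent_h.insert(cent_h.end(), h, h + 32);
      joined = (int)cent.size() - 1;
    }
    out[i] = joined + 1;
  }
  return out;
}
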