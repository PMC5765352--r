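#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Kruskal-Wallis LOD over all markers for one assignment of rank keys to
// strains. `key[i]` is the dense integer rank key (1..K) of the phenotype
// value currently held by strain i; tied values share a key. Midranks and
// the tie-corrected denominator follow from a counting pass over the keys,
// so no per-permutation sorting is needed.
struct MarkerIndex {
  std::vector<int> idx;   // strains with a call at this marker
  std::vector<int> grp;   // 1 or 2, parallel to idx
  int n1, n2;
};

static double kw_lod_marker(const MarkerIndex &mk, const int *key,
                            std::vector<int> &cnt1, std::vector<int> &cnt2,
                            int K) {
  const int n = (int)mk.idx.size();
  if (mk.n1 == 0 || mk.n2 == 0 || n < 2) return 0.0;
  for (size_t j = 0; j < mk.idx.size(); ++j) {
    int k = key[mk.idx[j]];
    if (mk.grp[j] == 1) cnt1[k]++; else cnt2[k]++;
  }
  double R1 = 0.0, ties = 0.0;
  int pos = 0;
  for (int k = 1; k <= K; ++k) {
    int t = cnt1[k] + cnt2[k];
    if (t == 0) continue;
    double mid = pos + (t + 1) / 2.0;
    R1 += cnt1[k] * mid;
    if (t > 1) ties += (double)t * t * t - t;
    pos += t;
    if (pos == n) break;
  }
  // reset touched buckets
  for (size_t j = 0; j < mk.idx.size(); ++j) {
    int k = key[mk.idx[j]];
    cnt1[k] = 0; cnt2[k] = 0;
  }
  const double n1 = mk.n1, n2 = mk.n2, N = n;
  double R2 = N * (N + 1) / 2.0 - R1;
  double mean = (N + 1) / 2.0;
  double H = 12.0 / (N * (N + 1)) *
    (n1 * (R1 / n1 - mean) * (R1 / n1 - mean) +
     n2 * (R2 / n2 - mean) * (R2 / n2 - mean));
  double C = 1.0 - ties / (N * N * N - N);
  if (C <= 0.0) return 0.0;
  return H / C / (2.0 * std::log(10.0));
}

static std::vector<MarkerIndex> build_index(const IntegerMatrix &geno) {
  const int n = geno.nrow(), m = geno.ncol();
  std::vector<MarkerIndex> out(m);
  for (int j = 0; j < m; ++j) {
    MarkerIndex mk;
    mk.n1 = mk.n2 = 0;
    for (int i = 0; i < n; ++i) {
      int g = geno(i, j);
      if (g == 1 || g == 2) {
        mk.idx.push_back(i);
        mk.grp.push_back(g);
        if (g == 1) mk.n1++; else mk.n2++;
      }
    }
    out[j] = mk;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector kw_scan_cpp(IntegerVector dense_rank, IntegerMatrix geno) {
  const int n = geno.nrow(), m = geno.ncol();
  if (dense_rank.size() != n) stop("rank/genotype size mismatch");
  std::vector<MarkerIndex> index = build_index(geno);
  int K = 0;
  for (int i = 0; i < n; ++i) K = std::max(K, dense_rank[i]);
  std::vector<int> cnt1(K + 1, 0), cnt2(K + 1, 0);
  std::vector<int> key(dense_rank.begin(), dense_rank.end());
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    out[j] = kw_lod_marker(index[j], key.data(), cnt1, cnt2, K);
  }
  return out;
}

// Genome-wide maximum LOD for each of n_perm random permutations of the
// phenotype against the strains. Uses R's RNG (reproducible via set.seed).
// [[Rcpp::export]]
NumericVector kw_perm_max_cpp(IntegerVector dense_rank, IntegerMatrix geno,
                              int n_perm) {
  const int n = geno.nrow(), m = geno.ncol();
  if (dense_rank.size() != n) stop("rank/genotype size mismatch");
  std::vector<MarkerIndex> index = build_index(geno);
  int K = 0;
  for (int i = 0; i < n; ++i) K = std::max(K, dense_rank[i]);
  std::vector<int> cnt1(K + 1, 0), cnt2(K + 1, 0);
  std::vector<int> key(dense_rank.begin(), dense_rank.end());
  NumericVector out(n_perm);
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle of the key assignment
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(key[i], key[j]);
    }
    double best = 0.0;
    for (int jm = 0; jm < m; ++jm) {
      double l = kw_lod_marker(index[jm], key.data(), cnt1, cnt2, K);
      if (l > best) best = l;
    }
    out[p] = best;
  }
  return out;
}
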