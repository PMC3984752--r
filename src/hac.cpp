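#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One-dimensional average-linkage agglomeration.
//
// Starts from singletons; repeatedly merges the active pair with the smallest
// average pairwise |x-y| distance (Lance-Williams update keeps the matrix
// exact for this linkage). Stops when the smallest inter-cluster distance
// exceeds eps AND no more than max_clusters clusters remain active.
// Deterministic tie-breaks: smallest distance, then lower centroid of the
// left (lower-index) cluster, then scan order. Returns a cluster id per
// input value (ids are arbitrary but stable).
// [[Rcpp::export(name = "hac_cpp")]]
IntegerVector hac_cpp(NumericVector values, double eps, int max_clusters) {
  const int n = values.size();
  if (n == 0) stop("empty input");
  if (max_clusters < 1) max_clusters = 1;

  std::vector<int> assign(n);
  std::vector<bool> active(n, true);
  std::vector<double> sum(n), dist((size_t)n * n, 0.0);
  std::vector<int> size(n, 1);
  for (int i = 0; i < n; ++i) { assign[i] = i; sum[i] = values[i]; }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      dist[(size_t)i * n + j] = std::fabs(values[i] - values[j]);

  int n_active = n;
  while (n_active > 1) {
    // locate the best merge candidate
    int bi = -1, bj = -1;
    double bd = 0.0, bcent = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      double cent_i = sum[i] / size[i];
      for (int j = i + 1; j < n; ++j) {
        if (!active[j]) continue;
        double d = dist[(size_t)i * n + j];
        if (bi < 0 || d < bd || (d == bd && cent_i < bcent)) {
          bi = i; bj = j; bd = d; bcent = cent_i;
        }
      }
    }
    if (bd > eps && n_active <= max_clusters) break;
    // merge bj into bi
    int ni = size[bi], nj = size[bj];
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi || k == bj) continue;
      double dk = (ni * dist[(size_t)k * n + bi] + nj * dist[(size_t)k * n + bj]) /
                  (double)(ni + nj);
      dist[(size_t)k * n + bi] = dk;
      dist[(size_t)bi * n + k] = dk;
    }
    size[bi] += size[bj];
    sum[bi] += sum[bj];
    active[bj] = false;
    for (int v = 0; v < n; ++v) if (assign[v] == bj) assign[v] = bi;
    --n_active;
  }

  IntegerVector out(n);
  for (int v = 0; v < n; ++v) out[v] = assign[v] + 1;
  return out;
}
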