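#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Neighbor statistics for the Kraskov-Stoegbauer-Grassberger mutual
// information estimator (algorithm 1).  For every point i: eps[i] is the
// Chebyshev (max-norm) distance to its k-th nearest neighbour in the joint
// (u, v) space; n_u[i] and n_v[i] count the points lying strictly closer
// than eps[i] along each marginal.  Brute-force O(n^2 k) joint search with
// a size-k max-heap; marginal counts by binary search on sorted copies.
// [[Rcpp::export]]
List ksg_neighbor_counts(NumericVector u, NumericVector v, int k) {
  const int n = u.size();
  if (v.size() != n) stop("u and v must have equal length");
  if (k < 1 || k >= n) stop("need 1 <= k < n");

  std::vector<double> su(u.begin(), u.end()), sv(v.begin(), v.end());
  std::sort(su.begin(), su.end());
  std::sort(sv.begin(), sv.end());

  IntegerVector nu(n), nv(n);
  NumericVector eps(n);
  std::vector<double> best(k);

  for (int i = 0; i < n; ++i) {
    int filled = 0;
    const double ui = u[i], vi = v[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double d = std::max(std::fabs(u[j] - ui), std::fabs(v[j] - vi));
      if (filled < k) {
        best[filled++] = d;
        if (filled == k) std::make_heap(best.begin(), best.end());
      } else if (d < best.front()) {
        std::pop_heap(best.begin(), best.end());
        best[k - 1] = d;
        std::push_heap(best.begin(), best.end());
      }
    }
    const double e = best.front();
    eps[i] = e;
    nu[i] = (int)(std::lower_bound(su.begin(), su.end(), ui + e) -
                  std::upper_bound(su.begin(), su.end(), ui - e)) - 1;
    nv[i] = (int)(std::lower_bound(sv.begin(), sv.end(), vi + e) -
                  std::upper_bound(sv.begin(), sv.end(), vi - e)) - 1;
  }
  return List::create(_["n_u"] = nu, _["n_v"] = nv, _["eps"] = eps);
}
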