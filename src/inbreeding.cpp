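#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Meuwissen & Luo (1992) recursion for inbreeding coefficients.
//
// Animals must be topologically sorted (parents before offspring) and coded
// 0-based; unknown parents are -1. For animal i the diagonal of the numerator
// relationship matrix is a_ii = sum_j L_ij^2 d_j over the ancestors j of i
// (including i itself), where L is the Cholesky-style descent matrix and
// d_j the Mendelian sampling variance scaling. F_i = a_ii - 1.
//
// d_i = 0.5 - 0.25 (F_s + F_d), with an unknown parent contributing F = -1,
// i.e. d = 1 for founders and 0.75 for animals with one known parent.

// [[Rcpp::export]]
List ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n), d(n);
  std::vector<double> L(n, 0.0);
  std::vector<int> touched;
  touched.reserve(64);

  for (int i = 0; i < n; ++i) {
    const int s = sire[i], m = dam[i];
    const double Fs = (s >= 0) ? F[s] : -1.0;
    const double Fm = (m >= 0) ? F[m] : -1.0;
    d[i] = 0.5 - 0.25 * (Fs + Fm);
    if (s < 0 && m < 0) { F[i] = 0.0; continue; }
    if (s >= i || m >= i)
      stop("pedigree is not topologically sorted at position %d", i + 1);

    // traverse ancestors of i in decreasing order of index
    std::priority_queue<int> q;
    double aii = 0.0;
    L[i] = 1.0;
    touched.push_back(i);
    q.push(i);
    while (!q.empty()) {
      const int j = q.top();
      q.pop();
      // skip duplicates: contributions were merged into L[j]
      while (!q.empty() && q.top() == j) q.pop();
      const double Lj = L[j];
      aii += Lj * Lj * d[j];
      const int sj = sire[j], mj = dam[j];
      if (sj >= 0) {
        if (L[sj] == 0.0) { touched.push_back(sj); q.push(sj); }
        L[sj] += 0.5 * Lj;
      }
      if (mj >= 0) {
        if (L[mj] == 0.0) { touched.push_back(mj); q.push(mj); }
        L[mj] += 0.5 * Lj;
      }
    }
    F[i] = aii - 1.0;
    for (size_t k = 0; k < touched.size(); ++k) L[touched[k]] = 0.0;
    touched.clear();
  }
  return List::create(_["f"] = F, _["d"] = d);
}
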