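// Dynamic-programming alignment of two nicking-site maps.
//
// Chains matched site pairs (monotone in both maps). A chunk joining
// consecutive matched pairs may skip up to max_skip sites on each map;
// its cost is a chi-square-like sizing term when the span difference is
// within the sizing gate max(3*sigma*sqrt(nskip+1), tol), or a flat
// indel penalty otherwise, so genuine insertions/deletions stay inside
// one chain instead of breaking it.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
List nickmap_dp_cpp(NumericVector q, NumericVector r, double sigma, int max_skip,
                    double tol, double match_bonus, double skip_pen,
                    double indel_pen) {
  const int n = q.size(), m = r.size();
  if (n == 0 || m == 0)
    return List::create(_["qi"] = IntegerVector(0), _["ri"] = IntegerVector(0),
                        _["score"] = 0.0);
  const double NEG = -1e18;
  std::vector<double> S((size_t)n * m, NEG);
  std::vector<int> bt((size_t)n * m, -1);

  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      // chain ends are free on both maps (local in both), which keeps the
      // score symmetric under query/ref exchange; skips inside the chain
      // are penalized
      double best = match_bonus;
      int from = -1;
      for (int pi = std::max(0, i - 1 - max_skip); pi <= i - 1; ++pi)
        for (int pj = std::max(0, j - 1 - max_skip); pj <= j - 1; ++pj) {
          double prev = S[(size_t)pi * m + pj];
          if (prev <= NEG / 2) continue;
          int nskip = (i - pi - 1) + (j - pj - 1);
          double delta = (q[i] - q[pi]) - (r[j] - r[pj]);
          double gate = std::max(3.0 * sigma * std::sqrt((double)nskip + 1.0), tol);
          double cost;
          if (std::fabs(delta) <= gate) {
            double z = delta / (sigma * std::sqrt((double)nskip + 1.0));
            cost = z * z;
          } else {
            cost = indel_pen;
          }
          double cand = prev + match_bonus - cost - skip_pen * nskip;
          if (cand > best) { best = cand; from = pi * m + pj; }
        }
      S[(size_t)i * m + j] = best;
      bt[(size_t)i * m + j] = from;
    }

  double best = NEG; int bi = -1;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double v = S[(size_t)i * m + j];
      if (v > best) { best = v; bi = i * m + j; }
    }

  std::vector<int> qi, ri;
  for (int cur = bi; cur >= 0; cur = bt[cur]) {
    qi.push_back(cur / m + 1);  // 1-based
    ri.push_back(cur % m + 1);
  }
  std::reverse(qi.begin(), qi.end());
  std::reverse(ri.begin(), ri.end());
  return List::create(_["qi"] = wrap(qi), _["ri"] = wrap(ri), _["score"] = best);
}
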