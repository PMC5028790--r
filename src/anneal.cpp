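#include <Rcpp.h>
using namespace Rcpp;

static double order_cost_internal(const NumericMatrix& dp,
                                  const std::vector<int>& ord) {
  int n = ord.size();
  double c = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = dp(ord[i], ord[j]);
      if (!ISNAN(d)) c += 1.0 - d;
    }
  return c;
}

// Simulated annealing over linear orders with adjacent-transposition
// proposals and geometric cooling, followed by a deterministic descent to
// the nearest adjacent-swap local optimum.  dp is the dominance probability
// matrix; start holds 0-based animal indices, best to worst.  Zero-delta
// swaps are never accepted, so fully ambiguous matrices return the start
// order unchanged.  Uses R's RNG (set.seed() controls it).
// [[Rcpp::export]]
List anneal_order_cpp(NumericMatrix dp, IntegerVector start, int n_iter,
                      double t0, double t1) {
  int n = start.size();
  std::vector<int> ord(start.begin(), start.end());
  double cur = order_cost_internal(dp, ord);
  std::vector<int> best_ord = ord;
  double best = cur;
  const double eps = 1e-12;
  double temp = t0;
  double cool = (n_iter > 1) ? std::pow(t1 / t0, 1.0 / (n_iter - 1)) : 1.0;

  for (int it = 0; it < n_iter; ++it) {
    int p = (int)(unif_rand() * (n - 1));
    if (p > n - 2) p = n - 2;
    int a = ord[p], b = ord[p + 1];
    double dab = dp(a, b), dba = dp(b, a);
    // current contribution (a above b): 1 - dp(a,b); after swap: 1 - dp(b,a)
    double delta = (ISNAN(dab) || ISNAN(dba)) ? 0.0 : (dab - dba);
    bool accept = false;
    if (delta < -eps) accept = true;
    else if (delta > eps && unif_rand() < std::exp(-delta / temp))
      accept = true;
    if (accept) {
      ord[p] = b; ord[p + 1] = a;
      cur += delta;
      if (cur < best - eps) { best = cur; best_ord = ord; }
    }
    temp *= cool;
  }

  // deterministic adjacent-swap descent from the best order seen
  bool improved = true;
  while (improved) {
    improved = false;
    for (int p = 0; p < n - 1; ++p) {
      int a = best_ord[p], b = best_ord[p + 1];
      double dab = dp(a, b), dba = dp(b, a);
      double delta = (ISNAN(dab) || ISNAN(dba)) ? 0.0 : (dab - dba);
      if (delta < -eps) {
        best_ord[p] = b; best_ord[p + 1] = a;
        improved = true;
      }
    }
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best_ord[i] + 1;  // 1-based
  return List::create(_["order"] = out,
                      _["cost"] = order_cost_internal(dp, best_ord));
}
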