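#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overflow-safe evaluation of the causal function
// f(z) = (1 - exp(-z)) / (1 + exp(-z)) with z = alpha * x.
// For z >= 0, exp(-z) <= 1 so the naive form is safe; for z < 0 the
// odd symmetry f(-z) = -f(z) avoids exp() of a large positive argument.
static inline double causal_f(double z) {
  if (z >= 0.0) {
    double e = std::exp(-z);
    return (1.0 - e) / (1.0 + e);
  } else {
    double e = std::exp(z);
    return -(1.0 - e) / (1.0 + e);
  }
}

// One synchronous update of all species from the frozen previous state.
// Influences are passed flattened: influence i targets tgt[i] (0-based),
// its sources are src[ptr[i] .. ptr[i+1]-1], with magnitude w[i] and sign
// sgn[i] (+1 / -1). Clamped species are copied unchanged.
static void step_once(const double* cur, double* nxt, int n,
                      const int* clamped, const double* cmax,
                      const double* alpha,
                      int m, const int* tgt, const int* ptr,
                      const int* src, const double* w, const int* sgn,
                      double* x) {
  for (int j = 0; j < n; ++j) x[j] = 0.0;
  for (int i = 0; i < m; ++i) {
    double term = w[i] * sgn[i];
    for (int p = ptr[i]; p < ptr[i + 1]; ++p) term *= cur[src[p]];
    x[tgt[i]] += term;
  }
  for (int j = 0; j < n; ++j) {
    if (clamped[j]) {
      nxt[j] = cur[j];
    } else {
      double f = causal_f(alpha[j] * x[j]);
      double lam = (f > 0.0) ? (cmax[j] - cur[j]) : cur[j];
      nxt[j] = cur[j] + lam * f;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate(NumericVector init, IntegerVector clamped,
                           NumericVector cmax, NumericVector alpha,
                           IntegerVector tgt, IntegerVector ptr,
                           IntegerVector src, NumericVector w,
                           IntegerVector sgn, int n_iter) {
  const int n = init.size();
  const int m = tgt.size();
  NumericMatrix out(n_iter + 1, n);
  std::vector<double> cur(init.begin(), init.end());
  std::vector<double> nxt(n), x(n);
  for (int j = 0; j < n; ++j) out(0, j) = cur[j];
  for (int t = 1; t <= n_iter; ++t) {
    step_once(cur.data(), nxt.data(), n, clamped.begin(), cmax.begin(),
              alpha.begin(), m, tgt.begin(), ptr.begin(), src.begin(),
              w.begin(), sgn.begin(), x.data());
    for (int j = 0; j < n; ++j) out(t, j) = nxt[j];
    std::swap(cur, nxt);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_to_steady(NumericVector init, IntegerVector clamped,
                       NumericVector cmax, NumericVector alpha,
                       IntegerVector tgt, IntegerVector ptr,
                       IntegerVector src, NumericVector w,
                       IntegerVector sgn, double tol, int max_iter) {
  const int n = init.size();
  const int m = tgt.size();
  std::vector<double> cur(init.begin(), init.end());
  std::vector<double> nxt(n), x(n);
  bool converged = false;
  int used = max_iter;
  for (int t = 1; t <= max_iter; ++t) {
    step_once(cur.data(), nxt.data(), n, clamped.begin(), cmax.begin(),
              alpha.begin(), m, tgt.begin(), ptr.begin(), src.begin(),
              w.begin(), sgn.begin(), x.data());
    double d = 0.0;
    for (int j = 0; j < n; ++j) {
      double dj = std::fabs(nxt[j] - cur[j]);
      if (dj > d) d = dj;
    }
    std::swap(cur, nxt);
    if (d < tol) { converged = true; used = t - 1; break; }
  }
  return List::create(_["state"] = NumericVector(cur.begin(), cur.end()),
                      _["converged"] = converged,
                      _["iterations"] = used);
}
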