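#include <Rcpp.h>
using namespace Rcpp;

// log(1 + exp(x)) without overflow
static inline double log1pexp_c(double x) {
  if (x > 33.0) return x;
  if (x > 18.0) return x + std::exp(-x);
  return std::log1p(std::exp(x));
}

static double unit_objective(const NumericMatrix &D, const NumericMatrix &S,
                             const NumericVector &Wm, double lambda,
                             const NumericMatrix &Bt,
                             const LogicalVector &penal, int j) {
  const int R = D.nrow(), P = D.ncol();
  double obj = 0.0;
  for (int m = 0; m < R; ++m) {
    double eta = 0.0;
    for (int k = 0; k < P; ++k) eta += D(m, k) * Bt(k, j);
    obj += S(m, j) * eta - Wm[m] * log1pexp_c(eta);
  }
  for (int k = 0; k < P; ++k)
    if (penal[k]) obj -= lambda * std::fabs(Bt(k, j));
  return obj;
}

// Penalized weighted logistic M-step for all units of a layer, by IRLS +
// cyclical coordinate descent with soft thresholding. D is the 2^K x P
// profile design (0/1 entries), S the per-profile success weights (R x M),
// Wm the per-profile trial weights. Bt (P x M) holds warm-start coefficients
// and is updated in place semantics (a copy is returned). mask (P x M)
// restricts the support when has_mask is true. A per-unit ascent guard
// backtracks toward the warm start if the penalized objective would drop.
// [[Rcpp::export]]
NumericMatrix cd_mstep(const NumericMatrix &D, const NumericMatrix &S,
                       const NumericVector &Wm, double lambda,
                       const NumericMatrix &Bt0, const LogicalMatrix &mask,
                       bool has_mask, const LogicalVector &penal, double tol,
                       int max_irls, int max_cycles) {
  const int R = D.nrow(), P = D.ncol(), M = S.ncol();
  NumericMatrix Bt = clone(Bt0);
  std::vector<double> eta(R), v(R), u(R);
  for (int j = 0; j < M; ++j) {
    double obj_old = unit_objective(D, S, Wm, lambda, Bt, penal, j);
    std::vector<double> b(P), b_start(P);
    for (int k = 0; k < P; ++k) b[k] = b_start[k] = Bt(k, j);
    for (int outer = 0; outer < max_irls; ++outer) {
      double outer_delta = 0.0;
      for (int m = 0; m < R; ++m) {
        double e = 0.0;
        for (int k = 0; k < P; ++k)
          if (b[k] != 0.0) e += D(m, k) * b[k];
        eta[m] = e;
        double p = 1.0 / (1.0 + std::exp(-e));
        double vv = Wm[m] * p * (1.0 - p);
        v[m] = vv < 1e-10 ? 1e-10 : vv;
        u[m] = S(m, j) - Wm[m] * p; // v * working residual
      }
      for (int cycle = 0; cycle < max_cycles; ++cycle) {
        double dmax = 0.0;
        for (int k = 0; k < P; ++k) {
          if (has_mask && !mask(k, j)) continue;
          double num = 0.0, denom = 0.0;
          for (int m = 0; m < R; ++m) {
            if (D(m, k) != 0.0) {
              num += u[m];
              denom += v[m];
            }
          }
          if (denom <= 1e-12) continue;
          num += denom * b[k];
          double bnew;
          if (penal[k]) {
            double a = std::fabs(num) - lambda;
            bnew = a > 0.0 ? (num > 0 ? a : -a) / denom : 0.0;
          } else {
            bnew = num / denom;
          }
          double d = bnew - b[k];
          if (d != 0.0) {
            for (int m = 0; m < R; ++m)
              if (D(m, k) != 0.0) u[m] -= v[m] * d;
            b[k] = bnew;
            double ad = std::fabs(d);
            if (ad > dmax) dmax = ad;
            if (ad > outer_delta) outer_delta = ad;
          }
        }
        if (dmax < tol) break;
      }
      if (outer_delta < tol) break;
    }
    for (int k = 0; k < P; ++k) Bt(k, j) = b[k];
    double obj_new = unit_objective(D, S, Wm, lambda, Bt, penal, j);
    int tries = 0;
    while (obj_new < obj_old - 1e-10 && tries < 30) {
      for (int k = 0; k < P; ++k) Bt(k, j) = 0.5 * (Bt(k, j) + b_start[k]);
      obj_new = unit_objective(D, S, Wm, lambda, Bt, penal, j);
      ++tries;
    }
    if (obj_new < obj_old)
      for (int k = 0; k < P; ++k) Bt(k, j) = b_start[k];
  }
  return Bt;
}
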