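#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Binary soft-margin SVM trained by sequential minimal optimization
// (Platt-style working-set selection, deterministic: no random choices).
// K is the precomputed kernel matrix, y in {-1, +1}.
// Returns the dual coefficients alpha and the threshold b so that
//   f(x) = sum_i alpha_i y_i K(x_i, x) - b     (Platt's sign convention).

static const double EPS = 1e-12;

struct SmoCtx {
  const double *K;
  int n;
  std::vector<double> y, alpha, E;
  double C, tol, b;
};

static inline double kij(const SmoCtx &c, int i, int j) {
  return c.K[(size_t)j * c.n + i];
}

static bool take_step(SmoCtx &c, int i1, int i2) {
  if (i1 == i2) return false;
  double a1 = c.alpha[i1], a2 = c.alpha[i2];
  double y1 = c.y[i1], y2 = c.y[i2];
  double E1 = c.E[i1], E2 = c.E[i2];
  double s = y1 * y2;
  double L, H;
  if (s < 0) {
    L = std::max(0.0, a2 - a1);
    H = std::min(c.C, c.C + a2 - a1);
  } else {
    L = std::max(0.0, a1 + a2 - c.C);
    H = std::min(c.C, a1 + a2);
  }
  if (H - L < EPS) return false;
  double k11 = kij(c, i1, i1), k12 = kij(c, i1, i2), k22 = kij(c, i2, i2);
  double eta = k11 + k22 - 2.0 * k12;
  double a2new;
  if (eta > EPS) {
    a2new = a2 + y2 * (E1 - E2) / eta;
    if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
  } else {
    // objective is flat or concave along the constraint: test both ends
    double f1 = y1 * (E1 + c.b) - a1 * k11 - s * a2 * k12;
    double f2 = y2 * (E2 + c.b) - s * a1 * k12 - a2 * k22;
    double L1 = a1 + s * (a2 - L), H1 = a1 + s * (a2 - H);
    double objL = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 + 0.5 * L * L * k22 +
                  s * L * L1 * k12;
    double objH = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 + 0.5 * H * H * k22 +
                  s * H * H1 * k12;
    if (objL < objH - EPS) a2new = L;
    else if (objH < objL - EPS) a2new = H;
    else return false;
  }
  if (std::fabs(a2new - a2) < EPS * (a2new + a2 + EPS)) return false;
  double a1new = a1 + s * (a2 - a2new);
  if (a1new < 0) { a2new += s * a1new; a1new = 0; }
  else if (a1new > c.C) { a2new += s * (a1new - c.C); a1new = c.C; }

  // bias update (Platt's b1/b2 rules)
  double b1 = E1 + y1 * (a1new - a1) * k11 + y2 * (a2new - a2) * k12 + c.b;
  double b2 = E2 + y1 * (a1new - a1) * k12 + y2 * (a2new - a2) * k22 + c.b;
  double bnew;
  if (a1new > EPS && a1new < c.C - EPS) bnew = b1;
  else if (a2new > EPS && a2new < c.C - EPS) bnew = b2;
  else bnew = 0.5 * (b1 + b2);
  double db = bnew - c.b;
  c.b = bnew;

  double d1 = y1 * (a1new - a1), d2 = y2 * (a2new - a2);
  for (int k = 0; k < c.n; ++k)
    c.E[k] += d1 * kij(c, i1, k) + d2 * kij(c, i2, k) - db;
  c.alpha[i1] = a1new;
  c.alpha[i2] = a2new;
  return true;
}

static bool examine(SmoCtx &c, int i2) {
  double y2 = c.y[i2], a2 = c.alpha[i2], E2 = c.E[i2];
  double r2 = E2 * y2;
  if (!((r2 < -c.tol && a2 < c.C - EPS) || (r2 > c.tol && a2 > EPS)))
    return false;
  // 1) second-choice heuristic: maximize |E1 - E2| over non-bound points
  int best = -1;
  double bestgap = -1.0;
  for (int i = 0; i < c.n; ++i) {
    if (c.alpha[i] > EPS && c.alpha[i] < c.C - EPS) {
      double gap = std::fabs(c.E[i] - E2);
      if (gap > bestgap) { bestgap = gap; best = i; }
    }
  }
  if (best >= 0 && take_step(c, best, i2)) return true;
  // 2) all non-bound, then 3) all points, in deterministic order
  for (int i = 0; i < c.n; ++i)
    if (c.alpha[i] > EPS && c.alpha[i] < c.C - EPS && take_step(c, i, i2))
      return true;
  for (int i = 0; i < c.n; ++i)
    if (take_step(c, i, i2)) return true;
  return false;
}

// [[Rcpp::export]]
List smo_train_cpp(NumericMatrix K, NumericVector y, double C, double tol,
                   int max_epochs) {
  int n = K.nrow();
  if (K.ncol() != n) stop("kernel matrix must be square");
  if (y.size() != n) stop("label length mismatch");
  SmoCtx c;
  c.K = REAL(K);
  c.n = n;
  c.C = C;
  c.tol = tol;
  c.b = 0.0;
  c.y.assign(y.begin(), y.end());
  c.alpha.assign(n, 0.0);
  c.E.resize(n);
  for (int i = 0; i < n; ++i) c.E[i] = -c.y[i];  // f = 0 initially

  bool examine_all = true;
  int epochs = 0;
  while (epochs < max_epochs) {
    int changed = 0;
    if (examine_all) {
      for (int i = 0; i < n; ++i) changed += examine(c, i) ? 1 : 0;
      ++epochs;
      if (changed == 0) break;
      examine_all = false;
    } else {
      for (int i = 0; i < n; ++i)
        if (c.alpha[i] > EPS && c.alpha[i] < C - EPS)
          changed += examine(c, i) ? 1 : 0;
      if (changed == 0) examine_all = true;
    }
  }
  return List::create(
      _["alpha"] = NumericVector(c.alpha.begin(), c.alpha.end()),
      _["b"] = c.b, _["epochs"] = epochs);
}
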