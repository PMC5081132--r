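#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// C-SVC with RBF kernel solved by sequential minimal optimisation (SMO),
// Platt-style with a maintained decision-value cache and deterministic
// second-choice heuristics (no randomised working-set selection), so the
// fitted machine is an exact function of the inputs.
//
// Labels enter as {-1, +1}. Decision function f(x) = sum_i alpha_i y_i
// K(x_i, x) + b; prediction is +1 iff f(x) > 0.

namespace {

const double TOL = 1e-3;   // KKT violation tolerance
const double EPS = 1e-12;

struct SMO {
  int n;
  double C, gamma, b;
  std::vector<double> alpha, F;  // F[i] = f(x_i) with current alpha, b
  std::vector<double> K;
  const IntegerVector& y;

  SMO(const NumericMatrix& X, const IntegerVector& y_, double C_, double g_)
      : n(X.nrow()), C(C_), gamma(g_), b(0.0), alpha(n, 0.0), F(n, 0.0),
        K((size_t)n * n), y(y_) {
    const int p = X.ncol();
    for (int i = 0; i < n; ++i) {
      K[(size_t)i * n + i] = 1.0;
      for (int j = i + 1; j < n; ++j) {
        double s = 0.0;
        for (int k = 0; k < p; ++k) {
          const double d = X(i, k) - X(j, k);
          s += d * d;
        }
        const double v = std::exp(-gamma * s);
        K[(size_t)i * n + j] = v;
        K[(size_t)j * n + i] = v;
      }
    }
  }

  inline double k(int i, int j) const { return K[(size_t)i * n + j]; }

  bool takeStep(int i1, int i2) {
    if (i1 == i2) return false;
    const double a1o = alpha[i1], a2o = alpha[i2];
    const int y1 = y[i1], y2 = y[i2];
    const double E1 = F[i1] - y1, E2 = F[i2] - y2;
    const double s = y1 * y2;
    double L, H;
    if (s > 0) {
      L = std::max(0.0, a1o + a2o - C);
      H = std::min(C, a1o + a2o);
    } else {
      L = std::max(0.0, a2o - a1o);
      H = std::min(C, C + a2o - a1o);
    }
    if (H - L < EPS) return false;
    const double k11 = k(i1, i1), k22 = k(i2, i2), k12 = k(i1, i2);
    const double eta = k11 + k22 - 2.0 * k12;
    double a2;
    if (eta > EPS) {
      a2 = a2o + y2 * (E1 - E2) / eta;
      if (a2 < L) a2 = L;
      else if (a2 > H) a2 = H;
    } else {
      // objective at the two clip ends (Platt's pseudocode)
      const double f1 = y1 * (E1 + b) - a1o * k11 - s * a2o * k12;
      const double f2 = y2 * (E2 + b) - a2o * k22 - s * a1o * k12;
      const double L1 = a1o + s * (a2o - L), H1 = a1o + s * (a2o - H);
      const double Lobj = L1 * f1 + L * f2 + 0.5 * L1 * L1 * k11 +
                          0.5 * L * L * k22 + s * L * L1 * k12;
      const double Hobj = H1 * f1 + H * f2 + 0.5 * H1 * H1 * k11 +
                          0.5 * H * H * k22 + s * H * H1 * k12;
      if (Lobj < Hobj - 1e-8) a2 = L;
      else if (Lobj > Hobj + 1e-8) a2 = H;
      else return false;
    }
    if (std::fabs(a2 - a2o) < EPS * (a2 + a2o + EPS)) return false;
    const double a1 = a1o + s * (a2o - a2);
    const double d1 = a1 - a1o, d2 = a2 - a2o;

    const double b1 = b - E1 - y1 * d1 * k11 - y2 * d2 * k12;
    const double b2 = b - E2 - y1 * d1 * k12 - y2 * d2 * k22;
    double bn;
    if (a1 > EPS && a1 < C - EPS) bn = b1;
    else if (a2 > EPS && a2 < C - EPS) bn = b2;
    else bn = 0.5 * (b1 + b2);
    const double db = bn - b;
    for (int i = 0; i < n; ++i)
      F[i] += y1 * d1 * k(i1, i) + y2 * d2 * k(i2, i) + db;
    b = bn;
    alpha[i1] = a1;
    alpha[i2] = a2;
    return true;
  }

  bool examine(int i2) {
    const int y2 = y[i2];
    const double a2 = alpha[i2];
    const double E2 = F[i2] - y2;
    const double r2 = E2 * y2;
    if (!((r2 < -TOL && a2 < C - EPS) || (r2 > TOL && a2 > EPS))) return false;

    // 1) second choice: maximal |E1 - E2| over non-bound points
    int best = -1;
    double bestGap = -1.0;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] > EPS && alpha[i] < C - EPS) {
        const double gap = std::fabs(F[i] - y[i] - E2);
        if (gap > bestGap) {
          bestGap = gap;
          best = i;
        }
      }
    }
    if (best >= 0 && takeStep(best, i2)) return true;
    // 2) all non-bound points in order
    for (int i = 0; i < n; ++i)
      if (alpha[i] > EPS && alpha[i] < C - EPS && takeStep(i, i2)) return true;
    // 3) the whole training set in order
    for (int i = 0; i < n; ++i)
      if (takeStep(i, i2)) return true;
    return false;
  }

  void solve() {
    int numChanged = 0;
    bool examineAll = true;
    long guard = 0;
    const long maxSweeps = 2000L + 200L * n;
    while ((numChanged > 0 || examineAll) && guard++ < maxSweeps) {
      numChanged = 0;
      if (examineAll) {
        for (int i = 0; i < n; ++i) numChanged += examine(i);
      } else {
        for (int i = 0; i < n; ++i)
          if (alpha[i] > EPS && alpha[i] < C - EPS) numChanged += examine(i);
      }
      if (examineAll) examineAll = false;
      else if (numChanged == 0) examineAll = true;
    }
    finalizeThreshold();
  }

  // recompute b from the KKT conditions at the solution: average y_i - G_i
  // over free support vectors; with none free, the midpoint of the interval
  // the bound constraints leave for b (the libsvm rule)
  void finalizeThreshold() {
    double sum = 0.0;
    int nFree = 0;
    double lo = -HUGE_VAL, hi = HUGE_VAL;
    for (int i = 0; i < n; ++i) {
      const double G = F[i] - b;  // decision value without threshold
      const double yg = y[i] - G;
      if (alpha[i] > EPS && alpha[i] < C - EPS) {
        sum += yg;
        ++nFree;
      } else if ((y[i] > 0 && alpha[i] <= EPS) ||
                 (y[i] < 0 && alpha[i] >= C - EPS)) {
        lo = std::max(lo, yg);  // b >= y_i - G_i
      } else {
        hi = std::min(hi, yg);  // b <= y_i - G_i
      }
    }
    double bn;
    if (nFree > 0) bn = sum / nFree;
    else if (std::isfinite(lo) && std::isfinite(hi)) bn = 0.5 * (lo + hi);
    else if (std::isfinite(lo)) bn = lo;
    else if (std::isfinite(hi)) bn = hi;
    else bn = b;
    const double db = bn - b;
    for (int i = 0; i < n; ++i) F[i] += db;
    b = bn;
  }
};

}  // namespace

// [[Rcpp::export(name = ".svm_fit_cpp")]]
List svm_fit_cpp(NumericMatrix X, IntegerVector y, double cost, double gamma) {
  if (cost <= 0) stop("cost must be > 0");
  if (gamma <= 0) stop("gamma must be > 0");
  SMO smo(X, y, cost, gamma);
  smo.solve();
  return List::create(_["alpha"] = NumericVector(smo.alpha.begin(), smo.alpha.end()),
                      _["b"] = smo.b,
                      _["fitted"] = NumericVector(smo.F.begin(), smo.F.end()));
}

// [[Rcpp::export(name = ".svm_train_predict_cpp")]]
IntegerVector svm_train_predict_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                    NumericMatrix Xte, double cost,
                                    double gamma) {
  if (cost <= 0) stop("cost must be > 0");
  if (gamma <= 0) stop("gamma must be > 0");
  SMO smo(Xtr, ytr, cost, gamma);
  smo.solve();
  const int n = Xtr.nrow(), m = Xte.nrow(), p = Xtr.ncol();
  IntegerVector out(m);
  for (int t = 0; t < m; ++t) {
    double f = smo.b;
    for (int i = 0; i < n; ++i) {
      if (smo.alpha[i] < EPS) continue;
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        const double d = Xtr(i, k) - Xte(t, k);
        s += d * d;
      }
      f += smo.alpha[i] * ytr[i] * std::exp(-gamma * s);
    }
    out[t] = f > 0 ? 1 : -1;
  }
  return out;
}
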