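#include <Rcpp.h>
using namespace Rcpp;

// Soft-thresholding operator: argmin_w (w - s)^2/stuff + lambda1 |w|
static inline double soft(double s, double thr) {
  if (s > thr) return s - thr;
  if (s < -thr) return s + thr;
  return 0.0;
}

// Full coordinate-descent sweeps over the component weight matrix W for the
// penalised concatenated least-squares problem
//   || Z - X W P^T ||^2 + lambda1 |W|_1 + lambda2 |W|_2^2.
// Each w_{jr} update is the exact univariate elastic-net minimiser
//   w+ = S(s, lambda1 / 2) / (lambda2 + ||p_r||^2 ||x_j||^2),
// with s the covariance of the partial residual with the rank-one direction.
// The residual is carried implicitly: per component we hold u = Resid * p_r
// and the score column t_r = X w_r, both updated in O(I) per coordinate.
// The residual matrix is recomputed from T at the start of every component
// cycle, which bounds floating-point drift.
//
// support: logical mask; entries with support == FALSE are clamped to zero
// (used by the fixed-support refit).  coord_order: 0-based sweep order over
// the predictor columns.
// [[Rcpp::export]]
List cd_sweeps(const NumericMatrix& X, const NumericMatrix& Z,
               const NumericMatrix& P, const NumericMatrix& W0,
               const LogicalMatrix& support, double lambda1, double lambda2,
               int n_sweeps, const IntegerVector& coord_order) {
  const int I = X.nrow(), Jx = X.ncol(), J2 = Z.ncol(), R = P.ncol();
  if (Z.nrow() != I || P.nrow() != J2 || W0.nrow() != Jx || W0.ncol() != R)
    stop("non-conformable arguments to cd_sweeps");

  NumericMatrix W = clone(W0);
  const double thr = lambda1 / 2.0;

  // column sums of squares of X
  std::vector<double> cx(Jx);
  for (int j = 0; j < Jx; ++j) {
    double a = 0.0;
    for (int i = 0; i < I; ++i) a += X(i, j) * X(i, j);
    cx[j] = a;
  }

  // T = X W
  std::vector<double> T(static_cast<size_t>(I) * R, 0.0);
  for (int r = 0; r < R; ++r)
    for (int j = 0; j < Jx; ++j) {
      double w = W(j, r);
      if (w != 0.0)
        for (int i = 0; i < I; ++i) T[i + static_cast<size_t>(I) * r] += X(i, j) * w;
    }

  std::vector<double> u(I);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int r = 0; r < R; ++r) {
      double cp = 0.0;
      for (int k = 0; k < J2; ++k) cp += P(k, r) * P(k, r);
      // u = (Z - T P^T) p_r, recomputed from scratch for this component
      for (int i = 0; i < I; ++i) {
        double a = 0.0;
        for (int k = 0; k < J2; ++k) {
          double resid = Z(i, k);
          for (int s = 0; s < R; ++s) resid -= T[i + static_cast<size_t>(I) * s] * P(k, s);
          a += resid * P(k, r);
        }
        u[i] = a;
      }
      double* tr = &T[static_cast<size_t>(I) * r];
      for (int jj = 0; jj < Jx; ++jj) {
        int j = coord_order[jj];
        double wold = W(j, r);
        double wnew;
        if (!support(j, r)) {
          wnew = 0.0;
          if (wold == 0.0) continue;
        } else {
          double s = 0.0;
          for (int i = 0; i < I; ++i) s += X(i, j) * u[i];
          s += wold * cp * cx[j];
          if (!std::isfinite(s))
            stop("non-finite inner product in coordinate update; check that the inputs are centred and scaled");
          double d = lambda2 + cp * cx[j];
          if (d <= 0.0) {
            wnew = (lambda1 > 0.0) ? 0.0 : wold;
          } else {
            wnew = soft(s, thr) / d;
          }
        }
        double delta = wnew - wold;
        if (delta != 0.0) {
          W(j, r) = wnew;
          for (int i = 0; i < I; ++i) {
            u[i] -= cp * delta * X(i, j);
            tr[i] += delta * X(i, j);
          }
        }
      }
    }
  }

  NumericMatrix Tout(I, R);
  for (int r = 0; r < R; ++r)
    for (int i = 0; i < I; ++i) Tout(i, r) = T[i + static_cast<size_t>(I) * r];
  return List::create(_["W"] = W, _["T"] = Tout);
}
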