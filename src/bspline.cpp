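// Cubic B-spline free-form deformation kernels.
//
// A field has a c_1 x ... x c_n control mesh (flattened column-major into a
// nctrl x n matrix of displacement vectors), uniform spacing delta and a
// physical support origin (position of control index 0).  Displacement at x
// uses the 4^n controls around the containing knot span; outside the support
// the transformation is the identity.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static const int MAX_DIM = 3;

static inline void basis4(double u, double* b) {
  double u2 = u * u, u3 = u2 * u, v = 1.0 - u;
  b[0] = v * v * v / 6.0;
  b[1] = (3.0 * u3 - 6.0 * u2 + 4.0) / 6.0;
  b[2] = (-3.0 * u3 + 3.0 * u2 + 3.0 * u + 1.0) / 6.0;
  b[3] = u3 / 6.0;
}

static inline void basis4_deriv(double u, double* b) {
  double v = 1.0 - u;
  b[0] = -v * v / 2.0;
  b[1] = (3.0 * u * u - 4.0 * u) / 2.0;
  b[2] = (-3.0 * u * u + 2.0 * u + 1.0) / 2.0;
  b[3] = u * u / 2.0;
}

// [[Rcpp::export]]
NumericVector cpp_basis_weights(double u) {
  NumericVector b(4);
  basis4(u, REAL(b));
  return b;
}

// locate the knot span of x: t = (x - origin)/delta must lie in [1, c-2]
// (the support); the span index zi is clamped to [1, c-3] so the top support
// boundary uses the last span with u = 1.
static inline bool locate(const double* x, const double* origin,
                          const double* delta, const int* cc, int n,
                          int* zi, double* u) {
  // tolerance so the support boundary itself stays inside despite
  // floating-point round-off of t = (x - origin) / delta
  const double tol = 1e-9;
  for (int k = 0; k < n; ++k) {
    double t = (x[k] - origin[k]) / delta[k];
    if (t < 1.0 - tol || t > cc[k] - 2.0 + tol) return false;
    int z = (int)std::floor(t);
    if (z > cc[k] - 3) z = cc[k] - 3;
    if (z < 1) z = 1;
    zi[k] = z;
    u[k] = t - z;
  }
  return true;
}

// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericMatrix pts, NumericMatrix phi,
                               IntegerVector cc, NumericVector delta,
                               NumericVector origin) {
  int n = cc.size();
  int npts = pts.nrow();
  NumericMatrix out(npts, n);
  int zi[MAX_DIM];
  double u[MAX_DIM], x[MAX_DIM], bw[MAX_DIM][4];
  R_xlen_t stride[MAX_DIM];
  stride[0] = 1;
  for (int k = 1; k < n; ++k) stride[k] = stride[k - 1] * cc[k - 1];
  for (int ip = 0; ip < npts; ++ip) {
    for (int k = 0; k < n; ++k) x[k] = pts(ip, k);
    if (!locate(x, REAL(origin), REAL(delta), INTEGER(cc), n, zi, u)) continue;
    for (int k = 0; k < n; ++k) basis4(u[k], bw[k]);
    int nsup = 1;
    for (int k = 0; k < n; ++k) nsup *= 4;
    for (int j = 0; j < nsup; ++j) {
      double w = 1.0;
      R_xlen_t idx = 0;
      int jj = j;
      for (int k = 0; k < n; ++k) {
        int o = jj & 3;
        jj >>= 2;
        w *= bw[k][o];
        idx += (R_xlen_t)(zi[k] - 1 + o) * stride[k];
      }
      for (int k = 0; k < n; ++k) out(ip, k) += w * phi(idx, k);
    }
  }
  return out;
}

// Analytic spatial Jacobian of the displacement: out[p, a, k] =
// d disp_a / d x_k, from tensor products with the derivative basis along
// axis k.  Zero outside the support (identity transformation there).
// [[Rcpp::export]]
NumericVector cpp_bspline_jacobian(NumericMatrix pts, NumericMatrix phi,
                                   IntegerVector cc, NumericVector delta,
                                   NumericVector origin) {
  int n = cc.size();
  int npts = pts.nrow();
  NumericVector out(Dimension(npts, n, n));
  int zi[MAX_DIM];
  double u[MAX_DIM], x[MAX_DIM], bw[MAX_DIM][4], dbw[MAX_DIM][4];
  R_xlen_t stride[MAX_DIM];
  stride[0] = 1;
  for (int k = 1; k < n; ++k) stride[k] = stride[k - 1] * cc[k - 1];
  int nsup = 1;
  for (int k = 0; k < n; ++k) nsup *= 4;
  for (int ip = 0; ip < npts; ++ip) {
    for (int k = 0; k < n; ++k) x[k] = pts(ip, k);
    if (!locate(x, REAL(origin), REAL(delta), INTEGER(cc), n, zi, u)) continue;
    for (int k = 0; k < n; ++k) {
      basis4(u[k], bw[k]);
      basis4_deriv(u[k], dbw[k]);
    }
    for (int j = 0; j < nsup; ++j) {
      R_xlen_t idx = 0;
      int jj = j, offs[MAX_DIM];
      for (int k = 0; k < n; ++k) {
        offs[k] = jj & 3;
        jj >>= 2;
        idx += (R_xlen_t)(zi[k] - 1 + offs[k]) * stride[k];
      }
      for (int kd = 0; kd < n; ++kd) {  // derivative axis
        double w = 1.0;
        for (int k = 0; k < n; ++k)
          w *= (k == kd) ? dbw[k][offs[k]] / delta[k] : bw[k][offs[k]];
        for (int a = 0; a < n; ++a)
          out[ip + (R_xlen_t)npts * a + (R_xlen_t)npts * n * kd] +=
              w * phi(idx, a);
      }
    }
  }
  return out;
}

// Tensor-product basis weights per point: idx (1-based flat control index,
// 0 when the point is outside the support) and the matching weights.
// [[Rcpp::export]]
List cpp_bspline_weights(NumericMatrix pts, IntegerVector cc,
                         NumericVector delta, NumericVector origin) {
  int n = cc.size();
  int npts = pts.nrow();
  int nsup = 1;
  for (int k = 0; k < n; ++k) nsup *= 4;
  IntegerMatrix idx(npts, nsup);
  NumericMatrix w(npts, nsup);
  LogicalVector inside(npts);
  int zi[MAX_DIM];
  double u[MAX_DIM], x[MAX_DIM], bw[MAX_DIM][4];
  R_xlen_t stride[MAX_DIM];
  stride[0] = 1;
  for (int k = 1; k < n; ++k) stride[k] = stride[k - 1] * cc[k - 1];
  for (int ip = 0; ip < npts; ++ip) {
    for (int k = 0; k < n; ++k) x[k] = pts(ip, k);
    if (!locate(x, REAL(origin), REAL(delta), INTEGER(cc), n, zi, u)) continue;
    inside[ip] = true;
    for (int k = 0; k < n; ++k) basis4(u[k], bw[k]);
    for (int j = 0; j < nsup; ++j) {
      double ww = 1.0;
      R_xlen_t ii = 0;
      int jj = j;
      for (int k = 0; k < n; ++k) {
        int o = jj & 3;
        jj >>= 2;
        ww *= bw[k][o];
        ii += (R_xlen_t)(zi[k] - 1 + o) * stride[k];
      }
      idx(ip, j) = (int)ii + 1;
      w(ip, j) = ww;
    }
  }
  return List::create(_["idx"] = idx, _["w"] = w, _["inside"] = inside);
}

// Scatter-accumulate per-point vector values into the control mesh:
// out[ctrl, comp] = sum_p bw[p, j] * vals[p, comp] over supports j with
// idx[p, j] == ctrl.  Shared by gradient assembly and derivative scaling.
// [[Rcpp::export]]
NumericMatrix cpp_accum_ctrl(IntegerMatrix idx, NumericMatrix bw,
                             NumericMatrix vals, int nctrl) {
  int npts = idx.nrow(), nsup = idx.ncol(), nc = vals.ncol();
  NumericMatrix out(nctrl, nc);
  for (int p = 0; p < npts; ++p)
    for (int j = 0; j < nsup; ++j) {
      int ii = idx(p, j);
      if (ii == 0) continue;
      double w = bw(p, j);
      for (int c = 0; c < nc; ++c) out(ii - 1, c) += w * vals(p, c);
    }
  return out;
}
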