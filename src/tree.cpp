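// Augmented max KD-tree over a rectangular image grid and the Monte-Carlo
// alpha-cut distance estimator built on it.
//
// The tree is stored implicitly in a flat array: root at index 1, children of
// node i at 2i and 2i+1.  Each node covers an integer sub-rectangle (y, R) of
// the grid and stores the maximum membership inside it, which allows pruning
// of sub-trees that are empty after alpha-cutting.  Spel centers live at
// physical position index * spacing (0-based indices).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int MAX_DIM = 3;
static const int MAX_DEPTH = 64;

// split along argmax_k s_k * (R_k - 1); ties broken by lowest dimension
// index; the "left" half gets ceil(R_k / 2) spels (build and search must
// agree on this).
static int split_axis(const int* R, const double* s, int n) {
  int axis = 0;
  double best = -1.0;
  for (int k = 0; k < n; ++k) {
    double v = s[k] * (double)(R[k] - 1);
    if (v > best) { best = v; axis = k; }
  }
  return axis;
}

static inline R_xlen_t flat_index(const int* y, const int* N, int n) {
  R_xlen_t idx = 0, stride = 1;
  for (int k = 0; k < n; ++k) { idx += (R_xlen_t)y[k] * stride; stride *= N[k]; }
  return idx;
}

static void build_rec(double* tau, R_xlen_t i, int* y, int* R,
                      const double* mu, const int* N, const double* s,
                      int n, bool complement) {
  R_xlen_t prod = 1;
  for (int k = 0; k < n; ++k) prod *= R[k];
  if (prod == 1) {
    double v = mu[flat_index(y, N, n)];
    tau[i] = complement ? 1.0 - v : v;
    return;
  }
  int k = split_axis(R, s, n);
  int left = (R[k] + 1) / 2;
  int Rk = R[k], yk = y[k];
  R[k] = left;
  build_rec(tau, 2 * i, y, R, mu, N, s, n, complement);
  y[k] = yk + left; R[k] = Rk - left;
  build_rec(tau, 2 * i + 1, y, R, mu, N, s, n, complement);
  y[k] = yk; R[k] = Rk;
  tau[i] = std::max(tau[2 * i], tau[2 * i + 1]);
}

// [[Rcpp::export]]
NumericVector cpp_build_tree(NumericVector mu, IntegerVector N,
                             NumericVector s, bool complement) {
  int n = N.size();
  if (n < 1 || n > MAX_DIM) stop("dimension must be 1..3");
  int depth_bits = 0;
  for (int k = 0; k < n; ++k) {
    int b = 0;
    while ((1 << b) < N[k]) ++b;
    depth_bits += b;
  }
  R_xlen_t len = ((R_xlen_t)1) << (1 + depth_bits);
  NumericVector tree(len, -1.0);
  int y[MAX_DIM] = {0, 0, 0};
  int R[MAX_DIM];
  for (int k = 0; k < n; ++k) R[k] = N[k];
  build_rec(REAL(tree), 1, y, R, REAL(mu), INTEGER(N), REAL(s), n, complement);
  return tree;
}

// [[Rcpp::export]]
List cpp_split_rect(IntegerVector y, IntegerVector R, NumericVector s) {
  int n = y.size();
  R_xlen_t prod = 1;
  for (int k = 0; k < n; ++k) prod *= R[k];
  if (prod <= 1) stop("cannot split a leaf rectangle");
  int k = split_axis(INTEGER(R), REAL(s), n);
  int left = (R[k] + 1) / 2;
  IntegerVector y1 = clone(y), y2 = clone(y), R1 = clone(R), R2 = clone(R);
  R1[k] = left;
  y2[k] = y[k] + left;
  R2[k] = R[k] - left;
  return List::create(_["y1"] = y1, _["R1"] = R1,
                      _["y2"] = y2, _["R2"] = R2, _["axis"] = k + 1);
}

// Euclidean distance from physical point p to the nearest spel center of the
// rectangle (y, R): per-axis clamped excess, combined in quadrature.
static double rect_bound(const double* p, const int* y, const int* R,
                         const double* s, int n) {
  double acc = 0.0;
  for (int k = 0; k < n; ++k) {
    double lo = y[k] * s[k];
    double hi = (y[k] + R[k] - 1) * s[k];
    double e = std::max(0.0, std::max(lo - p[k], p[k] - hi));
    acc += e * e;
  }
  return std::sqrt(acc);
}

static inline double relax_bound(double b, double d_t, double beta) {
  return b > d_t ? d_t + beta * (b - d_t) : b;
}

// [[Rcpp::export]]
double cpp_rect_lower_bound(NumericVector p, IntegerVector y, IntegerVector R,
                            NumericVector s) {
  return rect_bound(REAL(p), INTEGER(y), INTEGER(R), REAL(s), p.size());
}

// [[Rcpp::export]]
double cpp_relaxed_bound(double bound, double d_t, double beta) {
  return relax_bound(bound, d_t, beta);
}

// ----------------------------------------------------------------------
// Joint multi-alpha branch-and-bound search.
//
// D is an nalpha x ncorner matrix of current best distances (column-major).
// Rows correspond to alpha levels sorted ascending.  A row stays active in a
// sub-tree only if its alpha-cut is non-empty there (alpha <= tau_i) and at
// least one of its corner distances still exceeds the (relaxed) lower bound.
// Filtering rows independently makes the joint traversal return exactly the
// same distances as one single-alpha search per row, including under bound
// relaxation (beta > 1).

struct SearchCtx {
  const double* tau;
  const int* N;
  const double* s;
  int n, ncorner, nalpha;
  const double* P;       // ncorner x n, column-major, physical coords
  const double* alphas;  // ascending
  double* D;             // nalpha x ncorner, column-major
  double d_t, beta;
  std::vector<int> actbuf;  // per-depth active-row scratch
};

static void search_rec(SearchCtx& C, R_xlen_t i, int* y, int* R,
                       const int* act, int nact, int depth) {
  // alpha pruning: rows are ascending so the ones still satisfying
  // alpha <= tau_i form a prefix of act
  double tau_i = C.tau[i];
  int na = 0;
  while (na < nact && C.alphas[act[na]] <= tau_i) ++na;
  if (na == 0) return;

  // distance-bound pruning per corner / per row
  double bnd[8];
  for (int j = 0; j < C.ncorner; ++j) {
    double p[MAX_DIM];
    for (int k = 0; k < C.n; ++k) p[k] = C.P[j + C.ncorner * k];
    bnd[j] = relax_bound(rect_bound(p, y, R, C.s, C.n), C.d_t, C.beta);
  }
  int* keep = &C.actbuf[(size_t)depth * C.nalpha];
  int nkeep = 0;
  for (int a = 0; a < na; ++a) {
    int row = act[a];
    bool any = false;
    for (int j = 0; j < C.ncorner && !any; ++j)
      any = C.D[row + (R_xlen_t)C.nalpha * j] > bnd[j];
    if (any) keep[nkeep++] = row;
  }
  if (nkeep == 0) return;

  R_xlen_t prod = 1;
  for (int k = 0; k < C.n; ++k) prod *= R[k];
  if (prod == 1) {
    for (int j = 0; j < C.ncorner; ++j) {
      double acc = 0.0;
      for (int k = 0; k < C.n; ++k) {
        double d = C.P[j + C.ncorner * k] - y[k] * C.s[k];
        acc += d * d;
      }
      double d = std::sqrt(acc);
      for (int a = 0; a < nkeep; ++a) {
        R_xlen_t idx = keep[a] + (R_xlen_t)C.nalpha * j;
        if (d < C.D[idx]) C.D[idx] = d;
      }
    }
    return;
  }

  int k = split_axis(R, C.s, C.n);
  int left = (R[k] + 1) / 2;
  int Rk = R[k], yk = y[k];
  // visit the child containing (or nearer to) the first corner point first
  bool left_first = C.P[0 + C.ncorner * k] <= (yk + left) * C.s[k];
  for (int pass = 0; pass < 2; ++pass) {
    bool go_left = (pass == 0) == left_first;
    if (go_left) {
      R[k] = left;
      search_rec(C, 2 * i, y, R, keep, nkeep, depth + 1);
      R[k] = Rk;
    } else {
      y[k] = yk + left; R[k] = Rk - left;
      search_rec(C, 2 * i + 1, y, R, keep, nkeep, depth + 1);
      y[k] = yk; R[k] = Rk;
    }
  }
}

static void run_search(const double* tree, const int* N, const double* s,
                       int n, const double* P, int ncorner,
                       const double* alphas, int nalpha, double* D,
                       double d_t, double beta, bool joint) {
  SearchCtx C;
  C.tau = tree; C.N = N; C.s = s; C.n = n; C.ncorner = ncorner;
  C.P = P; C.d_t = d_t; C.beta = beta;
  int y[MAX_DIM] = {0, 0, 0};
  int R[MAX_DIM];
  if (joint) {
    C.nalpha = nalpha;
    C.alphas = alphas;
    C.D = D;
    C.actbuf.resize((size_t)MAX_DEPTH * nalpha);
    std::vector<int> act(nalpha);
    for (int a = 0; a < nalpha; ++a) act[a] = a;
    for (int k = 0; k < n; ++k) R[k] = N[k];
    search_rec(C, 1, y, R, act.data(), nalpha, 0);
  } else {
    // reference path: one full traversal per alpha level
    std::vector<double> Drow(ncorner);
    C.nalpha = 1;
    C.actbuf.resize(MAX_DEPTH);
    int act0 = 0;
    for (int a = 0; a < nalpha; ++a) {
      for (int j = 0; j < ncorner; ++j) Drow[j] = D[a + (R_xlen_t)nalpha * j];
      C.alphas = &alphas[a];
      C.D = Drow.data();
      for (int k = 0; k < n; ++k) R[k] = N[k];
      search_rec(C, 1, y, R, &act0, 1, 0);
      for (int j = 0; j < ncorner; ++j) D[a + (R_xlen_t)nalpha * j] = Drow[j];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_alpha_search(NumericMatrix P, NumericVector alphas,
                               NumericVector tree, IntegerVector N,
                               NumericVector s, NumericMatrix d_init,
                               double d_t, double beta, bool joint) {
  int n = N.size();
  int ncorner = P.nrow();
  int nalpha = alphas.size();
  if (ncorner > 8) stop("at most 8 corner points supported");
  // rows must be sorted ascending for the joint prefix pruning
  for (int a = 1; a < nalpha; ++a)
    if (alphas[a] < alphas[a - 1]) stop("alphas must be sorted ascending");
  NumericMatrix D = clone(d_init);
  run_search(REAL(tree), INTEGER(N), REAL(s), n, REAL(P), ncorner,
             REAL(alphas), nalpha, REAL(D), d_t, beta, joint);
  return D;
}

// ----------------------------------------------------------------------
// Monte-Carlo distance estimate at fuzzy points.
//
// For each point p with height h: for every alpha sample, search the object
// tree at level alpha when alpha <= h, else the complement tree at level
// 1 - alpha; distances start at d_max so empty cuts saturate there.  Corner
// averages are interpolated multilinearly at p; the gradient is returned both
// as the mid-point stencil (robust against saddle points of the
// interpolation surface) and as the derivative of the interpolation surface
// at p itself (exact, used for finite-difference verification).

// [[Rcpp::export]]
List cpp_mc_distance(NumericMatrix pts, NumericVector heights,
                     NumericVector treeS, NumericVector treeSc,
                     IntegerVector N, NumericVector s, NumericVector alphas,
                     double d_max, double d_t, double beta, bool joint) {
  int n = N.size();
  int npts = pts.nrow();
  int nalpha = alphas.size();
  int ncorner = 1 << n;
  NumericVector value(npts, NA_REAL);
  NumericMatrix grad_mid(npts, n), grad_exact(npts, n), corner(npts, ncorner);
  LogicalVector indomain(npts);
  std::fill(grad_mid.begin(), grad_mid.end(), NA_REAL);
  std::fill(grad_exact.begin(), grad_exact.end(), NA_REAL);
  std::fill(corner.begin(), corner.end(), NA_REAL);

  // pre-sort alphas ascending once, remember permutation and the object /
  // complement split per point (depends on h)
  std::vector<int> ord(nalpha);
  for (int a = 0; a < nalpha; ++a) ord[a] = a;
  std::sort(ord.begin(), ord.end(),
            [&](int i, int j) { return alphas[i] < alphas[j]; });
  std::vector<double> asort(nalpha);
  for (int a = 0; a < nalpha; ++a) asort[a] = alphas[ord[a]];

  std::vector<double> P(ncorner * n), D, lv;
  std::vector<double> Dbar(ncorner);

  for (int ip = 0; ip < npts; ++ip) {
    // base cell (clamped so the top grid point maps into the last cell)
    int base[MAX_DIM];
    double u[MAX_DIM];
    bool ok = true;
    for (int k = 0; k < n; ++k) {
      double t = pts(ip, k) / s[k];
      int b = (int)std::floor(t);
      // grid-hull boundary stays in-domain despite round-off
      if (b >= N[k] - 1 && t <= (double)(N[k] - 1) + 1e-9) b = N[k] - 2;
      if (b == -1 && t >= -1e-9) b = 0;
      if (b < 0 || b + 1 > N[k] - 1) { ok = false; break; }
      base[k] = b;
      u[k] = t - b;
    }
    indomain[ip] = ok;
    if (!ok) continue;
    for (int j = 0; j < ncorner; ++j)
      for (int k = 0; k < n; ++k)
        P[j + ncorner * k] = (base[k] + ((j >> k) & 1)) * s[k];

    double h = heights[ip];
    std::fill(Dbar.begin(), Dbar.end(), 0.0);
    // two passes: object levels (alpha <= h) then complement levels
    for (int pass = 0; pass < 2; ++pass) {
      lv.clear();
      if (pass == 0) {
        for (int a = 0; a < nalpha; ++a)
          if (asort[a] <= h) lv.push_back(asort[a]);
      } else {
        for (int a = nalpha - 1; a >= 0; --a)  // 1 - alpha ascending
          if (asort[a] > h) lv.push_back(1.0 - asort[a]);
      }
      int nl = (int)lv.size();
      if (nl == 0) continue;
      D.assign((size_t)nl * ncorner, d_max);
      run_search(pass == 0 ? REAL(treeS) : REAL(treeSc), INTEGER(N), REAL(s),
                 n, P.data(), ncorner, lv.data(), nl, D.data(), d_t, beta,
                 joint);
      for (int j = 0; j < ncorner; ++j)
        for (int a = 0; a < nl; ++a) Dbar[j] += D[a + (size_t)nl * j];
    }
    for (int j = 0; j < ncorner; ++j) {
      Dbar[j] /= nalpha;
      corner(ip, j) = Dbar[j];
    }

    // multilinear interpolation at p
    double val = 0.0;
    for (int j = 0; j < ncorner; ++j) {
      double w = 1.0;
      for (int k = 0; k < n; ++k) w *= ((j >> k) & 1) ? u[k] : 1.0 - u[k];
      val += w * Dbar[j];
    }
    value[ip] = val;

    // gradients: difference along axis k of corner pairs, weighted by the
    // interpolation weights of the remaining axes (exact) or by the cell
    // mid-point weights (mid-point stencil)
    for (int k = 0; k < n; ++k) {
      double ge = 0.0, gm = 0.0;
      for (int j = 0; j < ncorner; ++j) {
        if ((j >> k) & 1) continue;
        int j1 = j | (1 << k);
        double we = 1.0, wm = 1.0;
        for (int kk = 0; kk < n; ++kk) {
          if (kk == k) continue;
          we *= ((j >> kk) & 1) ? u[kk] : 1.0 - u[kk];
          wm *= 0.5;
        }
        double diff = Dbar[j1] - Dbar[j];
        ge += we * diff;
        gm += wm * diff;
      }
      grad_exact(ip, k) = ge / s[k];
      grad_mid(ip, k) = gm / s[k];
    }
  }
  return List::create(_["value"] = value, _["grad_mid"] = grad_mid,
                      _["grad_exact"] = grad_exact, _["corner"] = corner,
                      _["indomain"] = indomain);
}
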