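// Separable image filters: Gaussian smoothing / first derivative with
// reflected boundaries, block-mean downsampling, and grayscale ball
// morphology for rolling-ball background removal.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int MAX_DIM = 3;

// 1-D convolution along one axis of an n-D array, reflect boundary (abc|cba)
static void conv_axis(const double* in, double* out, const int* N, int n,
                      int axis, const std::vector<double>& kern, int radius) {
  R_xlen_t stride = 1, total = 1;
  for (int k = 0; k < axis; ++k) stride *= N[k];
  for (int k = 0; k < n; ++k) total *= N[k];
  int len = N[axis];
  R_xlen_t outer = total / len;
  for (R_xlen_t o = 0; o < outer; ++o) {
    // decode o into the coordinates of this line (axis coordinate = 0)
    R_xlen_t coords[MAX_DIM];
    R_xlen_t rem = o, base;
    for (int k = 0; k < n; ++k) {
      if (k == axis) continue;
      coords[k] = rem % N[k];
      rem /= N[k];
    }
    coords[axis] = 0;
    base = 0;
    R_xlen_t str = 1;
    for (int k = 0; k < n; ++k) { base += coords[k] * str; str *= N[k]; }
    for (int i = 0; i < len; ++i) {
      double acc = 0.0;
      for (int t = -radius; t <= radius; ++t) {
        int j = i + t;
        if (j < 0) j = -j - 1;
        if (j >= len) j = 2 * len - 1 - j;
        acc += kern[t + radius] * in[base + (R_xlen_t)j * stride];
      }
      out[base + (R_xlen_t)i * stride] = acc;
    }
  }
}

static std::vector<double> gauss_kernel(double sigma, int radius, bool deriv) {
  std::vector<double> k(2 * radius + 1);
  double sum = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    double g = std::exp(-0.5 * t * t / (sigma * sigma));
    k[t + radius] = g;
    sum += g;
  }
  for (double& v : k) v /= sum;
  if (deriv)
    for (int t = -radius; t <= radius; ++t)
      k[t + radius] *= -t / (sigma * sigma);
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_filter(NumericVector img, IntegerVector N,
                               double sigma, int deriv_axis) {
  int n = N.size();
  if (sigma <= 0 && deriv_axis < 0) return clone(img);
  int radius = std::max(1, (int)std::ceil(4.0 * sigma));
  NumericVector cur = clone(img), tmp(img.size());
  for (int k = 0; k < n; ++k) {
    std::vector<double> kern =
        gauss_kernel(sigma, radius, k == deriv_axis - 1);
    conv_axis(REAL(cur), REAL(tmp), INTEGER(N), n, k, kern, radius);
    std::swap(cur, tmp);
  }
  return cur;
}

// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector img, IntegerVector N, int factor) {
  int n = N.size();
  if (factor == 1) return clone(img);
  int M[MAX_DIM];
  R_xlen_t total = 1;
  for (int k = 0; k < n; ++k) { M[k] = N[k] / factor; total *= M[k]; }
  NumericVector out(total);
  R_xlen_t nblock = 1;
  for (int k = 0; k < n; ++k) nblock *= factor;
  R_xlen_t coords[MAX_DIM], off[MAX_DIM];
  for (R_xlen_t i = 0; i < total; ++i) {
    R_xlen_t rem = i;
    for (int k = 0; k < n; ++k) { coords[k] = rem % M[k]; rem /= M[k]; }
    double acc = 0.0;
    for (R_xlen_t b = 0; b < nblock; ++b) {
      R_xlen_t rb = b;
      for (int k = 0; k < n; ++k) { off[k] = rb % factor; rb /= factor; }
      R_xlen_t idx = 0, str = 1;
      for (int k = 0; k < n; ++k) {
        idx += (coords[k] * factor + off[k]) * str;
        str *= N[k];
      }
      acc += img[idx];
    }
    out[i] = acc / nblock;
  }
  IntegerVector dims(n);
  for (int k = 0; k < n; ++k) dims[k] = M[k];
  out.attr("dim") = dims;
  return out;
}

// Grayscale erosion (erode = true) or dilation with a ball structuring
// function of the given radius: height profile -sqrt(r^2 - d^2) over the
// disk d <= r (2-D only; used by rolling-ball background estimation).
// [[Rcpp::export]]
NumericMatrix cpp_grey_ball_morph(NumericMatrix img, double radius,
                                  bool erode) {
  int nr = img.nrow(), ncl = img.ncol();
  int r = (int)std::floor(radius);
  NumericMatrix out(nr, ncl);
  // precompute ball heights
  std::vector<double> hgt((2 * r + 1) * (2 * r + 1));
  std::vector<bool> inb((2 * r + 1) * (2 * r + 1));
  for (int dy = -r; dy <= r; ++dy)
    for (int dx = -r; dx <= r; ++dx) {
      double d2 = (double)dx * dx + (double)dy * dy;
      size_t ii = (dy + r) * (2 * r + 1) + (dx + r);
      inb[ii] = d2 <= radius * radius;
      hgt[ii] = inb[ii] ? radius - std::sqrt(radius * radius - d2) : 0.0;
    }
  for (int y = 0; y < ncl; ++y)
    for (int x = 0; x < nr; ++x) {
      double best = erode ? R_PosInf : R_NegInf;
      for (int dy = -r; dy <= r; ++dy) {
        int yy = y + dy;
        if (yy < 0 || yy >= ncl) continue;
        for (int dx = -r; dx <= r; ++dx) {
          int xx = x + dx;
          if (xx < 0 || xx >= nr) continue;
          size_t ii = (dy + r) * (2 * r + 1) + (dx + r);
          if (!inb[ii]) continue;
          double v = erode ? img(xx, yy) + hgt[ii] : img(xx, yy) - hgt[ii];
          if (erode ? v < best : v > best) best = v;
        }
      }
      out(x, y) = best;
    }
  return out;
}
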