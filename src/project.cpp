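#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear sample of an image at physical point (x, y), zero outside.
// Pixel (i, j) (0-based row, col) has its center at
//   x = (j + 0.5 - n/2) * d,  y = (n/2 - i - 0.5) * d
// so the image is centered on the origin with rows running top to bottom.
static inline double sample_bilinear(const double *img, int n, double d,
                                     double x, double y) {
  double cj = x / d + 0.5 * n - 0.5;
  double ci = 0.5 * n - 0.5 - y / d;
  int j0 = (int)std::floor(cj);
  int i0 = (int)std::floor(ci);
  double fj = cj - j0, fi = ci - i0;
  double v = 0.0;
  for (int di = 0; di <= 1; ++di) {
    int i = i0 + di;
    if (i < 0 || i >= n) continue;
    double wi = di ? fi : 1.0 - fi;
    for (int dj = 0; dj <= 1; ++dj) {
      int j = j0 + dj;
      if (j < 0 || j >= n) continue;
      double wj = dj ? fj : 1.0 - fj;
      v += wi * wj * img[i + (R_xlen_t)n * j];
    }
  }
  return v;
}

// Parallel-beam line integrals of a square image.
// angles in radians; detector bins are spaced d (the pixel size) apart and
// centered on the origin; ray for angle t runs along (-sin t, cos t) through
// the detector axis (cos t, sin t).  Integration step is d / oversample.
// [[Rcpp::export(name = ".cpp_forward_project")]]
NumericMatrix cpp_forward_project(NumericMatrix image, NumericVector angles,
                                  int n_det, double d, int oversample) {
  int n = image.nrow();
  int n_ang = angles.size();
  double h = d / oversample;
  double half = 0.5 * n * d * std::sqrt(2.0) + d;
  int n_s = (int)std::ceil(2.0 * half / h) + 1;
  NumericMatrix sino(n_ang, n_det);
  const double *img = image.begin();
  for (int a = 0; a < n_ang; ++a) {
    double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int k = 0; k < n_det; ++k) {
      double t = (k - 0.5 * (n_det - 1)) * d;
      double bx = t * ct, by = t * st;
      double acc = 0.0;
      for (int s = 0; s < n_s; ++s) {
        double u = -half + s * h;
        acc += sample_bilinear(img, n, d, bx - u * st, by + u * ct);
      }
      sino(a, k) = acc * h;
    }
  }
  return sino;
}

// Pixel-driven backprojection of filtered projections (n_ang x n_det),
// linear interpolation between detector bins, scaled by pi / n_ang.
// [[Rcpp::export(name = ".cpp_backproject")]]
NumericMatrix cpp_backproject(NumericMatrix filt, NumericVector angles,
                              int side, double d) {
  int n_ang = filt.nrow(), n_det = filt.ncol();
  NumericMatrix out(side, side);
  double scale = M_PI / n_ang;
  for (int a = 0; a < n_ang; ++a) {
    double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < side; ++j) {
      double x = (j + 0.5 - 0.5 * side) * d;
      for (int i = 0; i < side; ++i) {
        double y = (0.5 * side - i - 0.5) * d;
        double t = x * ct + y * st;
        double k = t / d + 0.5 * (n_det - 1);
        int k0 = (int)std::floor(k);
        double f = k - k0;
        double v = 0.0;
        if (k0 >= 0 && k0 < n_det) v += (1.0 - f) * filt(a, k0);
        if (k0 + 1 >= 0 && k0 + 1 < n_det) v += f * filt(a, k0 + 1);
        out(i, j) += scale * v;
      }
    }
  }
  return out;
}
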