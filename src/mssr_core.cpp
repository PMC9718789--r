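#include <Rcpp.h>
using namespace Rcpp;

// Reflect an out-of-range index into [0, n) without repeating the edge sample
// (half-sample-symmetric mirroring, "abcba" style).
static inline int reflect(int k, int n) {
  if (n == 1) return 0;
  while (k < 0 || k >= n) {
    if (k < 0) k = -k;
    if (k >= n) k = 2 * n - 2 - k;
  }
  return k;
}

// Mean-shift field of a 2D intensity raster.
//
// For every pixel x the kernel-weighted mean of the circular neighborhood of
// radius hs (center included) is computed with Gaussian range weights
// w_r(d) = exp(-d^2 / (2 hr^2)) and either uniform or Gaussian spatial
// weights, and the center value is subtracted:
//
//   MS(x) = sum_y w_s w_r I(y) / sum_y w_s w_r  -  I(x)
//
// hr <= 0 disables range weighting (w_r = 1). boundary: 0 = mirror padding,
// 1 = constant (zero) padding.
// [[Rcpp::export(name = ".ms_field_cpp")]]
NumericMatrix ms_field_cpp(NumericMatrix img, int hs, double hr,
                           int boundary = 0, bool gaussian_spatial = false,
                           bool include_center = true) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> offi, offj;
  std::vector<double> wsp;
  const double sd_sp = hs / 2.0;
  for (int di = -hs; di <= hs; ++di)
    for (int dj = -hs; dj <= hs; ++dj) {
      if (di * di + dj * dj > hs * hs) continue;
      if (!include_center && di == 0 && dj == 0) continue;
      // single-row/column input: the disk degenerates to a 1D segment
      if (nr == 1 && di != 0) continue;
      if (nc == 1 && dj != 0) continue;
      offi.push_back(di);
      offj.push_back(dj);
      wsp.push_back(gaussian_spatial
                      ? std::exp(-(di * di + dj * dj) / (2.0 * sd_sp * sd_sp))
                      : 1.0);
    }
  // padded working copy
  const int pr = nr + 2 * hs, pc = nc + 2 * hs;
  std::vector<double> P((size_t)pr * pc, 0.0);
  for (int j = 0; j < pc; ++j)
    for (int i = 0; i < pr; ++i) {
      const int ii = i - hs, jj = j - hs;
      if (ii >= 0 && ii < nr && jj >= 0 && jj < nc)
        P[(size_t)j * pr + i] = img(ii, jj);
      else if (boundary == 0)
        P[(size_t)j * pr + i] = img(reflect(ii, nr), reflect(jj, nc));
      // boundary == 1: already zero
    }
  const bool use_range = hr > 0.0;
  const double inv2hr2 = use_range ? 1.0 / (2.0 * hr * hr) : 0.0;
  const size_t K = offi.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double c = img(i, j);
      double num = 0.0, den = 0.0;
      for (size_t k = 0; k < K; ++k) {
        const double v = P[(size_t)(j + hs + offj[k]) * pr + (i + hs + offi[k])];
        double w = wsp[k];
        if (use_range) {
          const double d = v - c;
          w *= std::exp(-d * d * inv2hr2);
        }
        num += w * v;
        den += w;
      }
      out(i, j) = num / den - c;
    }
  }
  return out;
}

// Catmull-Rom cubic interpolation kernel (the standard "bicubic" kernel with
// a = -1/2); exact on constants and on the original samples.
static inline double cubic_w(double t) {
  t = std::fabs(t);
  if (t <= 1.0) return ((1.5 * t - 2.5) * t) * t + 1.0;
  if (t < 2.0) return (((-0.5 * t + 2.5) * t) - 4.0) * t + 2.0;
  return 0.0;
}

// Separable bicubic (Catmull-Rom) magnification by an integer factor.
// Output pixel k samples input coordinate k / amp (0-based); indices beyond
// the frame are clamped to the edge sample.
// [[Rcpp::export(name = ".bicubic_zoom_cpp")]]
NumericMatrix bicubic_zoom_cpp(NumericMatrix img, int amp) {
  const int nr = img.nrow(), nc = img.ncol();
  const int NR = nr * amp, NC = nc * amp;
  auto clampi = [](int k, int n) { return k < 0 ? 0 : (k >= n ? n - 1 : k); };

  // rows first: (nr x nc) -> (NR x nc)
  NumericMatrix tmp(NR, nc);
  for (int j = 0; j < nc; ++j)
    for (int I = 0; I < NR; ++I) {
      const double y = (double)I / amp;
      const int i0 = (int)std::floor(y);
      const double f = y - i0;
      double acc = 0.0;
      for (int m = -1; m <= 2; ++m)
        acc += cubic_w(f - m) * img(clampi(i0 + m, nr), j);
      tmp(I, j) = acc;
    }
  NumericMatrix out(NR, NC);
  for (int J = 0; J < NC; ++J) {
    const double x = (double)J / amp;
    const int j0 = (int)std::floor(x);
    const double f = x - j0;
    double w[4];
    int jj[4];
    for (int m = -1; m <= 2; ++m) {
      w[m + 1] = cubic_w(f - m);
      jj[m + 1] = clampi(j0 + m, nc);
    }
    for (int I = 0; I < NR; ++I)
      out(I, J) = w[0] * tmp(I, jj[0]) + w[1] * tmp(I, jj[1]) +
                  w[2] * tmp(I, jj[2]) + w[3] * tmp(I, jj[3]);
  }
  return out;
}

// 3x3 median filter with mirrored edges; used by the optional
// mesh-minimization smoothing pass.
// [[Rcpp::export(name = ".median3x3_cpp")]]
NumericMatrix median3x3_cpp(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double v[9];
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di)
          v[k++] = img(reflect(i + di, nr), reflect(j + dj, nc));
      std::nth_element(v, v + 4, v + 9);
      out(i, j) = v[4];
    }
  return out;
}
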