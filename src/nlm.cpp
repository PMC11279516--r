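#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Non-local means via the offset decomposition: for every displacement t in
// the search window, the per-pixel patch distance to the pixel at p + t is a
// box filter (running sums along rows then columns) of the squared shifted
// difference image. This turns the naive O(N * S^2 * P^2) cost into
// O(N * S^2), independent of patch size. Borders are handled by index
// clamping (edge replication).
//
// Weights follow the standard noise-compensated kernel
//   w = exp(-max(d2 - 2*sigma^2, 0) / h^2)
// where d2 is the mean squared patch difference.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// [[Rcpp::export(name = ".nlm_cpp")]]
NumericMatrix nlm_cpp(NumericMatrix img, int patch, int search,
                      double h, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  const int f = patch / 2;      // patch radius
  const int r = search / 2;     // search radius
  const double patchArea = (2.0 * f + 1.0) * (2.0 * f + 1.0);
  const double h2 = h * h;
  const double twoSigma2 = 2.0 * sigma * sigma;

  NumericMatrix num(nr, nc), den(nr, nc);
  NumericMatrix diff2(nr, nc), rowsum(nr, nc), boxsum(nr, nc);

  for (int dr = -r; dr <= r; ++dr) {
    for (int dc = -r; dc <= r; ++dc) {
      // squared difference against the image shifted by (dr, dc)
      for (int j = 0; j < nc; ++j) {
        int js = clampi(j + dc, 0, nc - 1);
        for (int i = 0; i < nr; ++i) {
          int is = clampi(i + dr, 0, nr - 1);
          double d = img(i, j) - img(is, js);
          diff2(i, j) = d * d;
        }
      }
      // box filter over the patch: rows then columns, clamped windows
      for (int j = 0; j < nc; ++j) {
        double acc = 0.0;
        for (int i = 0; i <= f && i < nr; ++i) acc += diff2(i, j);
        for (int i = 0; i < nr; ++i) {
          if (i - f - 1 >= 0) acc -= diff2(i - f - 1, j);
          if (i + f < nr && i > 0) acc += diff2(i + f, j);
          rowsum(i, j) = acc;
        }
      }
      for (int i = 0; i < nr; ++i) {
        double acc = 0.0;
        for (int j = 0; j <= f && j < nc; ++j) acc += rowsum(i, j);
        for (int j = 0; j < nc; ++j) {
          if (j - f - 1 >= 0) acc -= rowsum(i, j - f - 1);
          if (j + f < nc && j > 0) acc += rowsum(i, j + f);
          boxsum(i, j) = acc;
        }
      }
      // accumulate weighted shifted values
      for (int j = 0; j < nc; ++j) {
        int js = clampi(j + dc, 0, nc - 1);
        for (int i = 0; i < nr; ++i) {
          int is = clampi(i + dr, 0, nr - 1);
          double d2 = boxsum(i, j) / patchArea - twoSigma2;
          if (d2 < 0.0) d2 = 0.0;
          double w = std::exp(-d2 / h2);
          num(i, j) += w * img(is, js);
          den(i, j) += w;
        }
      }
    }
  }

  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = num(i, j) / den(i, j);
  return out;
}
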