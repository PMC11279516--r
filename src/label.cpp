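#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connectivity connected-component labeling by iterative flood fill.
// Labels are assigned in raster-scan order of each component's first pixel,
// so the labeling is deterministic.

// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (mask(i0, j0) == 0 || lab(i0, j0) != 0) continue;
      ++next;
      lab(i0, j0) = next;
      stack.push_back(i0 + j0 * nr);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int i = p % nr, j = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= nc) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nr || (di == 0 && dj == 0)) continue;
            if (mask(ii, jj) != 0 && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
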