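#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a 0/1 matrix by iterative flood fill.
// Labels are assigned 1..k in raster-scan order of each component's first
// pixel.  Returns an integer matrix; background stays 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix bin) {
  const int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (bin(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int idx = stack.back(); stack.pop_back();
        const int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          const int c2 = cc + dc;
          if (c2 < 0 || c2 >= nc) continue;
          for (int dr = -1; dr <= 1; ++dr) {
            const int r2 = rr + dr;
            if (r2 < 0 || r2 >= nr || (dr == 0 && dc == 0)) continue;
            if (bin(r2, c2) != 0 && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
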