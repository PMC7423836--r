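#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask. Labels are assigned in
// raster-scan order (rows, then columns) of each component's first pixel,
// i.e. its topmost-leftmost pixel, starting at 1. Connectivity 8 or 4.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nd = connectivity == 8 ? 8 : 4;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc2 = idx / nr;
        for (int d = 0; d < nd; ++d) {
          int r2 = cr + dr[d], c2 = cc2 + dc[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
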