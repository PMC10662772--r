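#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling of a binary mask ("region filling").
// Labels are assigned 1..k in raster-scan order (row-major, i.e. by image
// row y then column x) of each region's first-encountered pixel, so the
// labeling is deterministic for a given mask and connectivity.
// [[Rcpp::export]]
IntegerMatrix cc_label(const LogicalMatrix& fg, int connectivity) {
  const int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  const int ndir = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  std::vector<int> stack_r, stack_c;
  stack_r.reserve(256);
  stack_c.reserve(256);
  int next_label = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!fg(r, c) || lab(r, c) != 0) continue;
      ++next_label;
      lab(r, c) = next_label;
      stack_r.clear();
      stack_c.clear();
      stack_r.push_back(r);
      stack_c.push_back(c);
      while (!stack_r.empty()) {
        const int cr = stack_r.back(), cc = stack_c.back();
        stack_r.pop_back();
        stack_c.pop_back();
        for (int k = 0; k < ndir; ++k) {
          const int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc &&
              fg(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next_label;
            stack_r.push_back(r2);
            stack_c.push_back(c2);
          }
        }
      }
    }
  }
  return lab;
}
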