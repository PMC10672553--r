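#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected components of equal-level masked pixels.
// Returns a k x 2 integer matrix: column 1 the zone's gray level,
// column 2 its size in pixels.
// [[Rcpp::export]]
IntegerMatrix cpp_zone_sizes(IntegerMatrix levels, LogicalMatrix mask) {
  int nr = levels.nrow(), nc = levels.ncol();
  std::vector<char> seen(nr * nc, 0);
  std::vector<int> zl, zs;
  std::vector<int> stack;
  const int drs[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dcs[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = c * nr + r;
      if (!mask[idx] || seen[idx]) continue;
      int lev = levels[idx];
      int size = 0;
      stack.clear();
      stack.push_back(idx);
      seen[idx] = 1;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        ++size;
        int cr = cur % nr, cc = cur / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = cr + drs[k], c2 = cc + dcs[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          int i2 = c2 * nr + r2;
          if (!mask[i2] || seen[i2] || levels[i2] != lev) continue;
          seen[i2] = 1;
          stack.push_back(i2);
        }
      }
      zl.push_back(lev);
      zs.push_back(size);
    }
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t i = 0; i < zl.size(); ++i) {
    out(i, 0) = zl[i];
    out(i, 1) = zs[i];
  }
  return out;
}
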