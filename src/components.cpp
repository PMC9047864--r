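// 26-connected component labelling of equal-valued voxels (flood fill).
// Used for size-zone construction (zones of equal gray level) and for
// reducing simulated delineations to their largest connected component.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Label 26-connected components of equal positive value in `lev`
// (0 = background). Returns labels 1..n (0 outside).
// [[Rcpp::export]]
IntegerVector label_zones_cpp(IntegerVector lev, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (lev[s] == 0 || lab[s] != 0) continue;
    const int v = lev[s];
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % nx), y = (int)((cur / nx) % ny),
          z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                zz < 0 || zz >= nz) continue;
            R_xlen_t q = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
            if (lab[q] == 0 && lev[q] == v) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}
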