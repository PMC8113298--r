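#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling by breadth-first search.
// Labels are assigned in first-seen (increasing linear index) order;
// deterministic reordering (by volume, then minimum linear index) is done
// on the R side. connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export(name = ".labelComponents")]]
IntegerVector labelComponents(LogicalVector mask, IntegerVector dims,
                              int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(n, 0);

  // neighbour offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  const int nnb = (int)dxs.size();

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next;
    labels[start] = next;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int k = 0; k < nnb; ++k) {
        int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t nb = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return labels;
}
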