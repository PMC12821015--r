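#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labeling of a 3D logical array (dim = nz,ny,nx,
// column-major with z fastest, as stored by R). Iterative BFS; labels
// are 1-based in first-encounter order of the linear scan.
// [[Rcpp::export]]
IntegerVector cpp_label_components_26(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  labels.attr("dim") = dims;

  std::vector<R_xlen_t> queue;
  int next_label = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      R_xlen_t idx = queue.back();
      queue.pop_back();
      int z = idx % nz;
      int y = (idx / nz) % ny;
      int x = idx / ((R_xlen_t)nz * ny);
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx;
        if (xx < 0 || xx >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int zz = z + dz;
            if (zz < 0 || zz >= nz) continue;
            R_xlen_t nidx = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (mask[nidx] && labels[nidx] == 0) {
              labels[nidx] = next_label;
              queue.push_back(nidx);
            }
          }
        }
      }
    }
  }
  return labels;
}
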