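#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Connected-component labelling used for 3D region growing (26-connectivity)
// and 2D high-density-area detection (8-connectivity). Labels are assigned in
// scan order, so output is deterministic for a given mask.

// [[Rcpp::export]]
IntegerVector cc_label_3d26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    lab[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            if (!dx && !dy && !dz) continue;
            R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
          }
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// [[Rcpp::export]]
IntegerMatrix cc_label_2d8(LogicalMatrix mask) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
    if (!mask(i, j) || lab(i, j)) continue;
    lab(i, j) = ++next;
    q.push(i + nx * j);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      int x = v % nx, y = v / nx;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy; if (yy < 0 || yy >= ny) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx; if (xx < 0 || xx >= nx) continue;
          if (!dx && !dy) continue;
          if (mask(xx, yy) && !lab(xx, yy)) { lab(xx, yy) = next; q.push(xx + nx * yy); }
        }
      }
    }
  }
  return lab;
}
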