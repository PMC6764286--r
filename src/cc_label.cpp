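#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 3D connected-component labelling of a logical mask by breadth-first
// search. Connectivity 6 (faces) or 26 (faces + edges + corners).
// Returns an integer array of the same dimension; background is 0 and
// components are numbered 1..k in scan order.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims,
                          int connectivity = 26) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  IntegerVector lab(n, 0);
  lab.attr("dim") = dims;

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  const int nn = dx.size();

  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = v % nx;
      int y = (v / nx) % ny;
      int z = v / ((R_xlen_t)nx * ny);
      for (int j = 0; j < nn; ++j) {
        int x2 = x + dx[j], y2 = y + dy[j], z2 = z + dz[j];
        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
          continue;
        R_xlen_t w = x2 + (R_xlen_t)nx * (y2 + (R_xlen_t)ny * z2);
        if (mask[w] && lab[w] == 0) { lab[w] = next; q.push(w); }
      }
    }
  }
  return lab;
}
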