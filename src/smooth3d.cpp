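#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable 3D Gaussian smoothing, per-axis sigma in voxels, replicate
// boundary. One in-place buffer swap per axis.
// [[Rcpp::export(name = ".gauss_smooth_3d")]]
NumericVector gauss_smooth_3d_cpp(NumericVector a, IntegerVector dims,
                                  NumericVector sigma) {
  if (dims.size() != 3 || sigma.size() != 3) stop("dims/sigma must be length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (a.size() != n) stop("array length does not match dims");

  std::vector<double> src(a.begin(), a.end()), dst(n);
  const int nd[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int hw = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * hw + 1);
    double ksum = 0;
    for (int j = -hw; j <= hw; ++j) {
      k[j + hw] = std::exp(-0.5 * j * j / (s * s));
      ksum += k[j + hw];
    }
    for (double& v : k) v /= ksum;

    const int len = nd[ax];
    const R_xlen_t st = stride[ax];
    // iterate over all lines along axis `ax`
    for (int z = 0; z < (ax == 2 ? 1 : nz); ++z) {
      for (int y = 0; y < (ax == 1 ? 1 : ny); ++y) {
        for (int x = 0; x < (ax == 0 ? 1 : nx); ++x) {
          R_xlen_t base = x + (R_xlen_t)nx * y + (R_xlen_t)nx * ny * z;
          for (int i = 0; i < len; ++i) {
            double acc = 0;
            for (int j = -hw; j <= hw; ++j) {
              int ii = i + j;
              if (ii < 0) ii = 0; else if (ii >= len) ii = len - 1;
              acc += k[j + hw] * src[base + (R_xlen_t)ii * st];
            }
            dst[base + (R_xlen_t)i * st] = acc;
          }
        }
      }
    }
    std::swap(src, dst);
  }
  NumericVector out(src.begin(), src.end());
  out.attr("dim") = dims;
  return out;
}
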