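#include <Rcpp.h>
using namespace Rcpp;

// Separable 3D Gaussian smoothing, sigma in voxel units, kernel truncated at
// 3 sigma and renormalized; nearest (clamp) boundary handling.
static void blur_axis(std::vector<double>& buf, std::vector<double>& tmp,
                      int nx, int ny, int nz, int axis,
                      const std::vector<double>& ker) {
  int r = (int)ker.size() / 2;
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  R_xlen_t st = stride[axis];
  int len = n[axis];
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int idx3[3] = {i, j, k};
        if (idx3[axis] != 0) continue;  // iterate lines once
        R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        for (int t = 0; t < len; ++t) {
          double acc = 0.0;
          for (int q = -r; q <= r; ++q) {
            int tt = t + q;
            if (tt < 0) tt = 0;
            if (tt >= len) tt = len - 1;
            acc += ker[q + r] * buf[base + (R_xlen_t)tt * st];
          }
          tmp[base + (R_xlen_t)t * st] = acc;
        }
      }
  buf.swap(tmp);
}

// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector src, IntegerVector dim, double sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) return clone(src);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int q = -r; q <= r; ++q) { ker[q + r] = std::exp(-(double)q * q / s2); sum += ker[q + r]; }
  for (double& v : ker) v /= sum;
  std::vector<double> buf(REAL(src), REAL(src) + n), tmp(n);
  blur_axis(buf, tmp, nx, ny, nz, 0, ker);
  blur_axis(buf, tmp, nx, ny, nz, 1, ker);
  blur_axis(buf, tmp, nx, ny, nz, 2, ker);
  NumericVector out(n);
  std::copy(buf.begin(), buf.end(), REAL(out));
  return out;
}
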