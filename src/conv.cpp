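#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

// Feature maps are ((nx+2)(ny+2)(nz+2) x C) matrices holding an interior
// volume of dims (nx, ny, nz) surrounded by a one-voxel zero halo, voxel
// linear index i + (nx+2)*(j + (ny+2)*k) (i fastest, halo included).
// With this layout a zero-padded 3x3x3 convolution is 27 shifted dense
// GEMM accumulations on contiguous row ranges, which BLAS executes far
// faster than explicit loops. The halo absorbs all boundary wrap-around:
// garbage written into halo rows is re-zeroed after each pass.
// Weights use layout W[(c_in * 27 + o), c_out], o enumerating (di, dj, dk)
// offsets in di-fastest order.

static void zero_halo(double* xp, int nx, int ny, int nz, int C) {
  int px = nx + 2, py = ny + 2, pz = nz + 2;
  R_xlen_t np = (R_xlen_t)px * py * pz;
  for (int c = 0; c < C; ++c) {
    double* col = xp + (R_xlen_t)c * np;
    for (int k = 0; k < pz; ++k)
      for (int j = 0; j < py; ++j) {
        double* row = col + (R_xlen_t)px * ((R_xlen_t)j + (R_xlen_t)py * k);
        if (k == 0 || k == pz - 1 || j == 0 || j == py - 1) {
          std::fill(row, row + px, 0.0);
        } else {
          row[0] = 0.0;
          row[px - 1] = 0.0;
        }
      }
  }
}

// [[Rcpp::export]]
void cpp_zero_halo(NumericMatrix x, IntegerVector dim) {
  zero_halo(REAL(x), dim[0], dim[1], dim[2], x.ncol());
}

// [[Rcpp::export]]
NumericMatrix cpp_pad_mat(NumericMatrix x, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2], C = x.ncol();
  int px = nx + 2, py = ny + 2;
  R_xlen_t np = (R_xlen_t)px * py * (nz + 2);
  NumericMatrix out(np, C);
  const double* s = REAL(x);
  double* d = REAL(out);
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const double* srow = s + (R_xlen_t)c * n +
          (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        double* drow = d + (R_xlen_t)c * np + 1 +
          (R_xlen_t)px * ((R_xlen_t)(j + 1) + (R_xlen_t)py * (k + 1));
        std::copy(srow, srow + nx, drow);
      }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_unpad_mat(NumericMatrix x, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2], C = x.ncol();
  int px = nx + 2, py = ny + 2;
  R_xlen_t np = (R_xlen_t)px * py * (nz + 2);
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericMatrix out(n, C);
  const double* s = REAL(x);
  double* d = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const double* srow = s + (R_xlen_t)c * np + 1 +
          (R_xlen_t)px * ((R_xlen_t)(j + 1) + (R_xlen_t)py * (k + 1));
        double* drow = d + (R_xlen_t)c * n +
          (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
        std::copy(srow, srow + nx, drow);
      }
  return out;
}

static void wslice(const double* wp, int Cin, int Cout, int o,
                   std::vector<double>& buf) {
  R_xlen_t ldw = 27 * (R_xlen_t)Cin;
  for (int co = 0; co < Cout; ++co)
    for (int c = 0; c < Cin; ++c)
      buf[(size_t)co * Cin + c] = wp[(R_xlen_t)c * 27 + o + co * ldw];
}

// [[Rcpp::export]]
NumericMatrix cpp_conv3_fwd(NumericMatrix x, IntegerVector dim,
                            NumericMatrix W, NumericVector b) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int px = nx + 2, py = ny + 2, pz = nz + 2;
  R_xlen_t np = (R_xlen_t)px * py * pz;
  int Cin = x.ncol(), Cout = W.ncol();
  NumericMatrix y(np, Cout);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int co = 0; co < Cout; ++co)
    std::fill(yp + (R_xlen_t)co * np, yp + (R_xlen_t)co * np + np, b[co]);
  std::vector<double> wbuf((size_t)Cin * Cout);
  const double one = 1.0;
  int inp = (int)np;
  int o = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++o) {
        R_xlen_t off = di + (R_xlen_t)px * (dj + (R_xlen_t)py * dk);
        R_xlen_t p0 = off < 0 ? -off : 0;
        int m = (int)(np - (off < 0 ? -off : off));
        wslice(REAL(W), Cin, Cout, o, wbuf);
        F77_CALL(dgemm)("N", "N", &m, &Cout, &Cin, &one,
                        xp + p0 + off, &inp, wbuf.data(), &Cin, &one,
                        yp + p0, &inp FCONE FCONE);
      }
  zero_halo(yp, nx, ny, nz, Cout);
  return y;
}

// Fused backward: dx (padded, halo-zeroed) and dW from upstream dy (padded,
// halo must be zero so halo rows contribute nothing).
// [[Rcpp::export]]
List cpp_conv3_bwd(NumericMatrix x, IntegerVector dim, NumericMatrix W,
                   NumericMatrix dy) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int px = nx + 2, py = ny + 2, pz = nz + 2;
  R_xlen_t np = (R_xlen_t)px * py * pz;
  int Cin = x.ncol(), Cout = W.ncol();
  NumericMatrix dx(np, Cin), dW(27 * Cin, Cout);
  const double* xp = REAL(x);
  const double* wp = REAL(W);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  double* dWp = REAL(dW);
  std::vector<double> wbuf((size_t)Cin * Cout), gbuf((size_t)Cin * Cout);
  const double one = 1.0, zero = 0.0;
  int inp = (int)np;
  R_xlen_t ldw = 27 * (R_xlen_t)Cin;
  int o = 0;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di, ++o) {
        R_xlen_t off = di + (R_xlen_t)px * (dj + (R_xlen_t)py * dk);
        R_xlen_t p0 = off < 0 ? -off : 0;
        int m = (int)(np - (off < 0 ? -off : off));
        // dW_o = x_shifted^T dy
        F77_CALL(dgemm)("T", "N", &Cin, &Cout, &m, &one,
                        xp + p0 + off, &inp, dyp + p0, &inp, &zero,
                        gbuf.data(), &Cin FCONE FCONE);
        for (int co = 0; co < Cout; ++co)
          for (int c = 0; c < Cin; ++c)
            dWp[(R_xlen_t)c * 27 + o + co * ldw] = gbuf[(size_t)co * Cin + c];
        // dx_shifted += dy W_o^T
        wslice(wp, Cin, Cout, o, wbuf);
        F77_CALL(dgemm)("N", "T", &m, &Cin, &Cout, &one,
                        dyp + p0, &inp, wbuf.data(), &Cin, &one,
                        dxp + p0 + off, &inp FCONE FCONE);
      }
  zero_halo(dxp, nx, ny, nz, Cin);
  return List::create(_["dx"] = dx, _["dW"] = dW);
}

// 2x average pooling on padded layout (interior dims must be even); the
// output is padded with a zero halo. Adjoints mirror the forward maps.
// [[Rcpp::export]]
NumericMatrix cpp_avgpool2(NumericMatrix x, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2], C = x.ncol();
  int px = nx + 2, py = ny + 2;
  R_xlen_t np = (R_xlen_t)px * py * (nz + 2);
  int hx = nx / 2, hy = ny / 2, hz = nz / 2;
  int qx = hx + 2, qy = hy + 2;
  R_xlen_t nq = (R_xlen_t)qx * qy * (hz + 2);
  NumericMatrix out(nq, C);
  const double* s = REAL(x);
  double* d = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < hz; ++k)
      for (int j = 0; j < hy; ++j)
        for (int i = 0; i < hx; ++i) {
          double acc = 0.0;
          for (int dk2 = 0; dk2 < 2; ++dk2)
            for (int dj2 = 0; dj2 < 2; ++dj2)
              for (int di2 = 0; di2 < 2; ++di2)
                acc += s[(R_xlen_t)c * np + (2 * i + di2 + 1) +
                         (R_xlen_t)px * ((2 * j + dj2 + 1) +
                                         (R_xlen_t)py * (2 * k + dk2 + 1))];
          d[(R_xlen_t)c * nq + (i + 1) +
            (R_xlen_t)qx * ((j + 1) + (R_xlen_t)qy * (k + 1))] = acc / 8.0;
        }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_avgpool2_bwd(NumericMatrix dy, IntegerVector dim_full) {
  int nx = dim_full[0], ny = dim_full[1], nz = dim_full[2], C = dy.ncol();
  int px = nx + 2, py = ny + 2;
  R_xlen_t np = (R_xlen_t)px * py * (nz + 2);
  int hx = nx / 2, hy = ny / 2;
  int qx = hx + 2, qy = hy + 2;
  R_xlen_t nq = (R_xlen_t)qx * qy * (nz / 2 + 2);
  NumericMatrix out(np, C);
  const double* s = REAL(dy);
  double* d = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          d[(R_xlen_t)c * np + (i + 1) +
            (R_xlen_t)px * ((j + 1) + (R_xlen_t)py * (k + 1))] =
            s[(R_xlen_t)c * nq + (i / 2 + 1) +
              (R_xlen_t)qx * ((j / 2 + 1) + (R_xlen_t)qy * (k / 2 + 1))] / 8.0;
  return out;
}

// Nearest-neighbour 2x upsampling on padded layout, and its adjoint.
// [[Rcpp::export]]
NumericMatrix cpp_upsample2(NumericMatrix x, IntegerVector dim_small) {
  int hx = dim_small[0], hy = dim_small[1], hz = dim_small[2], C = x.ncol();
  int qx = hx + 2, qy = hy + 2;
  R_xlen_t nq = (R_xlen_t)qx * qy * (hz + 2);
  int nx = 2 * hx, ny = 2 * hy, nz = 2 * hz;
  int px = nx + 2, py = ny + 2;
  R_xlen_t np = (R_xlen_t)px * py * (nz + 2);
  NumericMatrix out(np, C);
  const double* s = REAL(x);
  double* d = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          d[(R_xlen_t)c * np + (i + 1) +
            (R_xlen_t)px * ((j + 1) + (R_xlen_t)py * (k + 1))] =
            s[(R_xlen_t)c * nq + (i / 2 + 1) +
              (R_xlen_t)qx * ((j / 2 + 1) + (R_xlen_t)qy * (k / 2 + 1))];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_upsample2_bwd(NumericMatrix dy, IntegerVector dim_small) {
  int hx = dim_small[0], hy = dim_small[1], hz = dim_small[2], C = dy.ncol();
  int qx = hx + 2, qy = hy + 2;
  R_xlen_t nq = (R_xlen_t)qx * qy * (hz + 2);
  int nx = 2 * hx, ny = 2 * hy, nz = 2 * hz;
  int px = nx + 2, py = ny + 2;
  R_xlen_t np = (R_xlen_t)px * py * (nz + 2);
  NumericMatrix out(nq, C);
  const double* s = REAL(dy);
  double* d = REAL(out);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          d[(R_xlen_t)c * nq + (i / 2 + 1) +
            (R_xlen_t)qx * ((j / 2 + 1) + (R_xlen_t)qy * (k / 2 + 1))] +=
            s[(R_xlen_t)c * np + (i + 1) +
              (R_xlen_t)px * ((j + 1) + (R_xlen_t)py * (k + 1))];
  return out;
}
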