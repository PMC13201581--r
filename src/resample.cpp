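#include <Rcpp.h>
using namespace Rcpp;

// Linear index helpers: voxel (i,j,k) 0-based, i fastest (NIfTI order).
static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

static inline double sample_trilinear(const double* src, int nx, int ny, int nz,
                                      double x, double y, double z, double fill) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    int zz = z0 + dz; if (zz < 0) zz = 0; if (zz >= nz) zz = nz - 1;
    double wz = dz ? fz : 1.0 - fz;
    for (int dy = 0; dy <= 1; ++dy) {
      int yy = y0 + dy; if (yy < 0) yy = 0; if (yy >= ny) yy = ny - 1;
      double wy = dy ? fy : 1.0 - fy;
      for (int dx = 0; dx <= 1; ++dx) {
        int xx = x0 + dx; if (xx < 0) xx = 0; if (xx >= nx) xx = nx - 1;
        double wx = dx ? fx : 1.0 - fx;
        out += wx * wy * wz * src[vidx(xx, yy, zz, nx, ny)];
      }
    }
  }
  return out;
}

static inline double sample_nearest(const double* src, int nx, int ny, int nz,
                                    double x, double y, double z, double fill) {
  int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5), k = (int)std::floor(z + 0.5);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
  return src[vidx(i, j, k, nx, ny)];
}

// Resample src (dims sdim) onto a grid of dims odim; M is the 4x4 matrix
// mapping 0-based output voxel indices to 0-based source voxel coordinates.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector sdim,
                                  IntegerVector odim, NumericMatrix M,
                                  bool nearest, double fill) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* s = REAL(src);
  double* o = REAL(out);
  double m00=M(0,0),m01=M(0,1),m02=M(0,2),m03=M(0,3);
  double m10=M(1,0),m11=M(1,1),m12=M(1,2),m13=M(1,3);
  double m20=M(2,0),m21=M(2,1),m22=M(2,2),m23=M(2,3);
  R_xlen_t p = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++p) {
        double x = m00*i + m01*j + m02*k + m03;
        double y = m10*i + m11*j + m12*k + m13;
        double z = m20*i + m21*j + m22*k + m23;
        o[p] = nearest ? sample_nearest(s, nx, ny, nz, x, y, z, fill)
                       : sample_trilinear(s, nx, ny, nz, x, y, z, fill);
      }
  return out;
}

// Warp: out(v) = src(v + d(v)), displacement in voxel units on the output grid.
// [[Rcpp::export]]
NumericVector cpp_warp_field(NumericVector src, IntegerVector sdim,
                             NumericVector dx, NumericVector dy, NumericVector dz,
                             IntegerVector odim, bool nearest, double fill) {
  int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  int ox = odim[0], oy = odim[1], oz = odim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double* s = REAL(src);
  const double *ux = REAL(dx), *uy = REAL(dy), *uz = REAL(dz);
  double* o = REAL(out);
  R_xlen_t p = 0;
  for (int k = 0; k < oz; ++k)
    for (int j = 0; j < oy; ++j)
      for (int i = 0; i < ox; ++i, ++p) {
        double x = i + ux[p], y = j + uy[p], z = k + uz[p];
        o[p] = nearest ? sample_nearest(s, nx, ny, nz, x, y, z, fill)
                       : sample_trilinear(s, nx, ny, nz, x, y, z, fill);
      }
  return out;
}

// Central-difference spatial gradient, clamped at edges.
// [[Rcpp::export]]
List cpp_gradient3(NumericVector src, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector gx(n), gy(n), gz(n);
  const double* s = REAL(src);
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++p) {
        int ip = i + 1 < nx ? i + 1 : i, im = i > 0 ? i - 1 : i;
        int jp = j + 1 < ny ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        int kp = k + 1 < nz ? k + 1 : k, km = k > 0 ? k - 1 : k;
        gx[p] = (s[vidx(ip,j,k,nx,ny)] - s[vidx(im,j,k,nx,ny)]) / (ip - im > 0 ? ip - im : 1);
        gy[p] = (s[vidx(i,jp,k,nx,ny)] - s[vidx(i,jm,k,nx,ny)]) / (jp - jm > 0 ? jp - jm : 1);
        gz[p] = (s[vidx(i,j,kp,nx,ny)] - s[vidx(i,j,km,nx,ny)]) / (kp - km > 0 ? kp - km : 1);
      }
  return List::create(_["x"] = gx, _["y"] = gy, _["z"] = gz);
}
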