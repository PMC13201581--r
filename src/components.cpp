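#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Connected-component labelling on a binary mask with 6- or 26-connectivity.
// Components are numbered 1..ncomp in scan (discovery) order; background 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> off;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m != 1) continue;
        off.push_back(di); off.push_back(dj); off.push_back(dk);
      }
  int ncomp = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t p0 = 0; p0 < n; ++p0) {
    if (!mask[p0] || lab[p0] != 0) continue;
    ++ncomp;
    stack.clear();
    stack.push_back(p0);
    lab[p0] = ncomp;
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((R_xlen_t)nx * ny));
      for (size_t q = 0; q < off.size(); q += 3) {
        int ii = i + off[q], jj = j + off[q + 1], kk = k + off[q + 2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t pp = (R_xlen_t)ii + (R_xlen_t)nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk);
        if (mask[pp] && lab[pp] == 0) { lab[pp] = ncomp; stack.push_back(pp); }
      }
    }
  }
  return lab;
}

// Multi-source BFS (6-connected): assign to each voxel in fill_mask the label
// of its nearest labelled voxel. Deterministic: seeds enqueued in scan order.
// [[Rcpp::export]]
IntegerVector cpp_nearest_label_fill(IntegerVector labels, IntegerVector dim,
                                     LogicalVector fill_mask) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out = clone(labels);
  std::queue<R_xlen_t> q;
  std::vector<int> reach(n, 0);
  for (R_xlen_t p = 0; p < n; ++p)
    if (out[p] > 0) { q.push(p); reach[p] = 1; }
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  while (!q.empty()) {
    R_xlen_t p = q.front(); q.pop();
    int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((R_xlen_t)nx * ny));
    for (int t = 0; t < 6; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
      R_xlen_t pp = (R_xlen_t)ii + (R_xlen_t)nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk);
      if (reach[pp]) continue;
      reach[pp] = 1;
      out[pp] = out[p];
      q.push(pp);
    }
  }
  for (R_xlen_t p = 0; p < n; ++p)
    if (!fill_mask[p]) out[p] = labels[p];
  return out;
}

// Boundary voxels: mask voxels with at least one 6-neighbour outside the mask
// (out-of-grid counts as outside).
// [[Rcpp::export]]
LogicalVector cpp_boundary6(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++p) {
        if (!mask[p]) continue;
        for (int t = 0; t < 6; ++t) {
          int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          bool outside = ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz;
          if (!outside) {
            R_xlen_t pp = (R_xlen_t)ii + (R_xlen_t)nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk);
            outside = !mask[pp];
          }
          if (outside) { out[p] = true; break; }
        }
      }
  return out;
}

// Directed average surface distance: mean over rows of A of the minimum
// Euclidean distance to any row of B (coordinates already in mm).
// [[Rcpp::export]]
double cpp_directed_avg_dist(NumericMatrix A, NumericMatrix B) {
  R_xlen_t na = A.nrow(), nb = B.nrow();
  double total = 0.0;
  for (R_xlen_t a = 0; a < na; ++a) {
    double ax = A(a, 0), ay = A(a, 1), az = A(a, 2);
    double best = R_PosInf;
    for (R_xlen_t b = 0; b < nb; ++b) {
      double dx = ax - B(b, 0), dy = ay - B(b, 1), dz = az - B(b, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total / (double)na;
}
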