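// 3-D binary morphology on voxel masks: boundary-connected background
// flood fill (6-connectivity), connected-component labelling of the
// foreground (26-connectivity), and dilation/erosion with a digital ball.
// The 6/26 complementary pair is the standard choice that avoids
// foreground/background topology paradoxes.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>

using namespace Rcpp;

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
}

// Background voxels 6-connected to the grid boundary. Returns logical
// "reached" array (true = background connected to outside).
// [[Rcpp::export(name = ".cpp_background_reach")]]
LogicalVector cpp_background_reach(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int* m = LOGICAL(mask);
  LogicalVector reached((R_xlen_t)nx * ny * nz);
  int* r = LOGICAL(reached);
  std::fill(r, r + (R_xlen_t)nx * ny * nz, FALSE);
  std::queue<R_xlen_t> q;
  std::vector<int> qi, qj, qk;
  // seed with all boundary background voxels
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        R_xlen_t id = lin(i, j, k, nx, ny);
        if (!m[id] && !r[id]) { r[id] = TRUE; q.push(id); }
      }
  const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    R_xlen_t id = q.front(); q.pop();
    int k = (int)(id / ((R_xlen_t)nx * ny));
    int rem = (int)(id - (R_xlen_t)k * nx * ny);
    int j = rem / nx, i = rem % nx;
    for (int d = 0; d < 6; ++d) {
      int ii = i + d6[d][0], jj = j + d6[d][1], kk = k + d6[d][2];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
        continue;
      R_xlen_t nid = lin(ii, jj, kk, nx, ny);
      if (!m[nid] && !r[nid]) { r[nid] = TRUE; q.push(nid); }
    }
  }
  return reached;
}

// Largest 26-connected foreground component; ties broken by the lowest
// linear index of the first voxel encountered (scan order = linear order,
// so the component seeded earliest wins ties).
// [[Rcpp::export(name = ".cpp_largest_component")]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int* m = LOGICAL(mask);
  std::vector<int> label(n, 0);
  int nlab = 0;
  R_xlen_t best_size = 0;
  int best_lab = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!m[s] || label[s]) continue;
    ++nlab;
    R_xlen_t size = 0;
    label[s] = nlab;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t id = q.front(); q.pop();
      ++size;
      int k = (int)(id / ((R_xlen_t)nx * ny));
      int rem = (int)(id - (R_xlen_t)k * nx * ny);
      int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny ||
                kk < 0 || kk >= nz)
              continue;
            R_xlen_t nid = lin(ii, jj, kk, nx, ny);
            if (m[nid] && !label[nid]) { label[nid] = nlab; q.push(nid); }
          }
    }
    if (size > best_size) { best_size = size; best_lab = nlab; }
    // ties: first-seeded component has the lower seed index and is kept
  }
  LogicalVector out(n);
  int* o = LOGICAL(out);
  for (R_xlen_t i = 0; i < n; ++i) o[i] = (label[i] == best_lab);
  return out;
}

// Dilation (grow=true) or erosion (grow=false) with a digital ball of the
// given radius in voxels.
// [[Rcpp::export(name = ".cpp_ball_morph")]]
LogicalVector cpp_ball_morph(LogicalVector mask, IntegerVector dims,
                             int radius, bool grow) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int* m = LOGICAL(mask);
  std::vector<int> off;
  for (int dk = -radius; dk <= radius; ++dk)
    for (int dj = -radius; dj <= radius; ++dj)
      for (int di = -radius; di <= radius; ++di)
        if (di * di + dj * dj + dk * dk <= radius * radius) {
          off.push_back(di); off.push_back(dj); off.push_back(dk);
        }
  int no = (int)(off.size() / 3);
  LogicalVector out(n);
  int* o = LOGICAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool acc = !grow;  // erosion starts true (AND), dilation false (OR)
        for (int t = 0; t < no; ++t) {
          int ii = i + off[3 * t], jj = j + off[3 * t + 1],
              kk = k + off[3 * t + 2];
          bool v;
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            v = false;  // outside grid = background
          else
            v = m[lin(ii, jj, kk, nx, ny)];
          if (grow) { if (v) { acc = true; break; } }
          else      { if (!v) { acc = false; break; } }
        }
        o[lin(i, j, k, nx, ny)] = acc;
      }
  return out;
}

// Separable Gaussian blur of a 3-D scalar field, reflecting boundaries.
// sigma is given per-axis in voxel units; kernel truncated at 3 sigma.
// [[Rcpp::export(name = ".cpp_gauss_blur3")]]
NumericVector cpp_gauss_blur3(NumericVector field, IntegerVector dims,
                              NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(REAL(field), REAL(field) + n), b(n);
  int dimv[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma_vox[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * r + 1);
    double sum = 0;
    for (int t = -r; t <= r; ++t) {
      kern[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += kern[t + r];
    }
    for (int t = 0; t <= 2 * r; ++t) kern[t] /= sum;
    int len = dimv[ax];
    R_xlen_t st = stride[ax];
    // iterate over all lines along axis ax
    int d1 = (ax == 0) ? 1 : 0;
    int d2 = (ax == 2) ? 1 : 2;
    for (int u = 0; u < dimv[d2]; ++u) {
      for (int v = 0; v < dimv[d1]; ++v) {
        R_xlen_t base = (R_xlen_t)u * stride[d2] + (R_xlen_t)v * stride[d1];
        for (int p = 0; p < len; ++p) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int q = p + t;
            if (q < 0) q = -q - 1;            // reflect
            if (q >= len) q = 2 * len - q - 1;
            acc += kern[t + r] * a[base + (R_xlen_t)q * st];
          }
          b[base + (R_xlen_t)p * st] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  NumericVector out(n);
  std::copy(a.begin(), a.end(), REAL(out));
  return out;
}
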