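// Isosurface extraction by marching tetrahedra: each grid cube is split
// into six tetrahedra sharing the main diagonal (Kuhn decomposition,
// identical in every cube, so faces and diagonals match across cube
// boundaries and the extracted surface is watertight whenever the
// isosurface does not touch the grid border). Surface vertices lie on
// tetrahedron edges at the linear-interpolation crossing and are welded
// through an edge-keyed map, so shared vertices are exact, not tolerance
// based. Triangles are oriented with outward normals assuming the
// region with values > level is the interior.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_map>

using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };

inline uint64_t edge_key(uint32_t a, uint32_t b) {
  if (a > b) std::swap(a, b);
  return ((uint64_t)a << 32) | (uint64_t)b;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_march_tet")]]
List cpp_march_tet(NumericVector field, IntegerVector dims, double level,
                   NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double* f = REAL(field);

  // cube corner offsets, labeled 0..7
  static const int co[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
  };
  // six tetrahedra around the 0-6 diagonal
  static const int tets[6][4] = {
    {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
    {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
  };

  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> VX, VY, VZ;
  std::vector<int> TI;  // 0-based triples

  auto gidx = [&](int i, int j, int k) -> uint32_t {
    return (uint32_t)(i + nx * (j + (int64_t)ny * k));
  };

  auto vert_on_edge = [&](uint32_t ga, uint32_t gb, double va, double vb,
                          const double pa[3], const double pb[3]) -> int {
    uint64_t key = edge_key(ga, gb);
    std::unordered_map<uint64_t, int>::iterator it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (level - va) / (vb - va);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    int id = (int)VX.size();
    VX.push_back(pa[0] + t * (pb[0] - pa[0]));
    VY.push_back(pa[1] + t * (pb[1] - pa[1]));
    VZ.push_back(pa[2] + t * (pb[2] - pa[2]));
    vmap[key] = id;
    return id;
  };

  auto emit = [&](int v0, int v1, int v2, const double out_dir[3]) {
    if (v0 == v1 || v1 == v2 || v0 == v2) return;  // clamped crossing
    // orient so the geometric normal points along out_dir (toward the
    // below-level, i.e. outside, region)
    double ax = VX[v1] - VX[v0], ay = VY[v1] - VY[v0], az = VZ[v1] - VZ[v0];
    double bx = VX[v2] - VX[v0], by = VY[v2] - VY[v0], bz = VZ[v2] - VZ[v0];
    double nxn = ay * bz - az * by;
    double nyn = az * bx - ax * bz;
    double nzn = ax * by - ay * bx;
    double d = nxn * out_dir[0] + nyn * out_dir[1] + nzn * out_dir[2];
    if (d >= 0) { TI.push_back(v0); TI.push_back(v1); TI.push_back(v2); }
    else        { TI.push_back(v0); TI.push_back(v2); TI.push_back(v1); }
  };

  double pv[8][3];
  double fv[8];
  uint32_t gv[8];

  for (int k = 0; k + 1 < nz; ++k) {
    for (int j = 0; j + 1 < ny; ++j) {
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_above = false, any_below = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + co[c][0], jj = j + co[c][1], kk = k + co[c][2];
          double val = f[ii + nx * (jj + (int64_t)ny * kk)];
          fv[c] = val;
          gv[c] = gidx(ii, jj, kk);
          pv[c][0] = ox + ii * sx;
          pv[c][1] = oy + jj * sy;
          pv[c][2] = oz + kk * sz;
          if (val > level) any_above = true; else any_below = true;
        }
        if (!any_above || !any_below) continue;
        for (int tt = 0; tt < 6; ++tt) {
          const int* T = tets[tt];
          int above[4], below[4];
          int na = 0, nb = 0;
          for (int m = 0; m < 4; ++m) {
            if (fv[T[m]] > level) above[na++] = T[m];
            else below[nb++] = T[m];
          }
          if (na == 0 || na == 4) continue;
          // outward reference: from centroid of above corners toward
          // centroid of below corners
          double ca[3] = {0, 0, 0}, cb[3] = {0, 0, 0};
          for (int m = 0; m < na; ++m)
            for (int a = 0; a < 3; ++a) ca[a] += pv[above[m]][a] / na;
          for (int m = 0; m < nb; ++m)
            for (int a = 0; a < 3; ++a) cb[a] += pv[below[m]][a] / nb;
          double outd[3] = {cb[0] - ca[0], cb[1] - ca[1], cb[2] - ca[2]};
          if (na == 1 || na == 3) {
            int lone = (na == 1) ? above[0] : below[0];
            const int* oth = (na == 1) ? below : above;
            int v0 = vert_on_edge(gv[lone], gv[oth[0]], fv[lone], fv[oth[0]],
                                  pv[lone], pv[oth[0]]);
            int v1 = vert_on_edge(gv[lone], gv[oth[1]], fv[lone], fv[oth[1]],
                                  pv[lone], pv[oth[1]]);
            int v2 = vert_on_edge(gv[lone], gv[oth[2]], fv[lone], fv[oth[2]],
                                  pv[lone], pv[oth[2]]);
            emit(v0, v1, v2, outd);
          } else {
            // 2 above / 2 below: quad split into two triangles
            int a0 = above[0], a1 = above[1], b0 = below[0], b1 = below[1];
            int p1 = vert_on_edge(gv[a0], gv[b0], fv[a0], fv[b0], pv[a0], pv[b0]);
            int p2 = vert_on_edge(gv[a0], gv[b1], fv[a0], fv[b1], pv[a0], pv[b1]);
            int p3 = vert_on_edge(gv[a1], gv[b1], fv[a1], fv[b1], pv[a1], pv[b1]);
            int p4 = vert_on_edge(gv[a1], gv[b0], fv[a1], fv[b0], pv[a1], pv[b0]);
            emit(p1, p2, p3, outd);
            emit(p1, p3, p4, outd);
          }
        }
      }
    }
  }

  int nv = (int)VX.size();
  NumericMatrix Vm(nv, 3);
  for (int i = 0; i < nv; ++i) {
    Vm(i, 0) = VX[i]; Vm(i, 1) = VY[i]; Vm(i, 2) = VZ[i];
  }
  int nt = (int)(TI.size() / 3);
  IntegerMatrix Fm(nt, 3);
  for (int t = 0; t < nt; ++t) {
    Fm(t, 0) = TI[3 * t] + 1;
    Fm(t, 1) = TI[3 * t + 1] + 1;
    Fm(t, 2) = TI[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = Vm, _["triangles"] = Fm);
}
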