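// Isosurface extraction by marching tetrahedra: each grid cell between
// eight neighboring voxel centers is split into six tetrahedra sharing the
// main diagonal; surface-edge crossings are interpolated linearly.
// Vertices are welded on shared edges so closed foregrounds give closed
// (watertight) triangle meshes.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  std::unordered_map<uint64_t, int> edge_vertex;
};

inline int edge_point(MeshAcc &m, uint64_t gi, uint64_t gj,
                      const double *pi, const double *pj,
                      double vi, double vj, double iso) {
  uint64_t a = gi, b = gj;
  const double *pa = pi, *pb = pj;
  double va = vi, vb = vj;
  if (a > b) { std::swap(a, b); std::swap(pa, pb); std::swap(va, vb); }
  uint64_t key = a * 0x100000000ULL ^ b;
  auto it = m.edge_vertex.find(key);
  if (it != m.edge_vertex.end()) return it->second;
  double t = (iso - va) / (vb - va);
  if (t < 0) t = 0;
  if (t > 1) t = 1;
  m.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  m.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  m.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  int id = (int)m.vx.size() - 1;
  m.edge_vertex[key] = id;
  return id;
}

inline void add_tri(MeshAcc &m, int a, int b, int c,
                    const double *dir_from, const double *dir_to) {
  // orient so the normal points from the inside region toward outside
  double ax = m.vx[a], ay = m.vy[a], az = m.vz[a];
  double e1x = m.vx[b] - ax, e1y = m.vy[b] - ay, e1z = m.vz[b] - az;
  double e2x = m.vx[c] - ax, e2y = m.vy[c] - ay, e2z = m.vz[c] - az;
  double nxv = e1y * e2z - e1z * e2y;
  double nyv = e1z * e2x - e1x * e2z;
  double nzv = e1x * e2y - e1y * e2x;
  double dx = dir_to[0] - dir_from[0];
  double dy = dir_to[1] - dir_from[1];
  double dz = dir_to[2] - dir_from[2];
  if (nxv * dx + nyv * dy + nzv * dz >= 0) {
    m.f0.push_back(a); m.f1.push_back(b); m.f2.push_back(c);
  } else {
    m.f0.push_back(a); m.f1.push_back(c); m.f2.push_back(b);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector vol, int nx, int ny, int nz,
                             double iso) {
  MeshAcc m;
  // corner offsets of the unit cube
  static const int CO[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  static const int TETS[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        double val[8];
        double pos[8][3];
        uint64_t gid[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + CO[c][0], cy = y + CO[c][1], cz = z + CO[c][2];
          R_xlen_t li = cx + (R_xlen_t)nx * (cy + (R_xlen_t)ny * cz);
          val[c] = vol[li];
          pos[c][0] = cx; pos[c][1] = cy; pos[c][2] = cz;
          gid[c] = (uint64_t)li;
          if (val[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int it = 0; it < 6; ++it) {
          int ci[4] = {TETS[it][0], TETS[it][1], TETS[it][2], TETS[it][3]};
          int ins[4], outs[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (val[ci[k]] > iso) ins[ni++] = ci[k];
            else outs[no++] = ci[k];
          }
          if (ni == 0 || ni == 4) continue;
          if (ni == 1) {
            int a = ins[0];
            int p1 = edge_point(m, gid[a], gid[outs[0]], pos[a], pos[outs[0]],
                                val[a], val[outs[0]], iso);
            int p2 = edge_point(m, gid[a], gid[outs[1]], pos[a], pos[outs[1]],
                                val[a], val[outs[1]], iso);
            int p3 = edge_point(m, gid[a], gid[outs[2]], pos[a], pos[outs[2]],
                                val[a], val[outs[2]], iso);
            double cen[3] = {(pos[outs[0]][0]+pos[outs[1]][0]+pos[outs[2]][0])/3.0,
                             (pos[outs[0]][1]+pos[outs[1]][1]+pos[outs[2]][1])/3.0,
                             (pos[outs[0]][2]+pos[outs[1]][2]+pos[outs[2]][2])/3.0};
            add_tri(m, p1, p2, p3, pos[a], cen);
          } else if (ni == 3) {
            int a = outs[0];
            int p1 = edge_point(m, gid[a], gid[ins[0]], pos[a], pos[ins[0]],
                                val[a], val[ins[0]], iso);
            int p2 = edge_point(m, gid[a], gid[ins[1]], pos[a], pos[ins[1]],
                                val[a], val[ins[1]], iso);
            int p3 = edge_point(m, gid[a], gid[ins[2]], pos[a], pos[ins[2]],
                                val[a], val[ins[2]], iso);
            double cen[3] = {(pos[ins[0]][0]+pos[ins[1]][0]+pos[ins[2]][0])/3.0,
                             (pos[ins[0]][1]+pos[ins[1]][1]+pos[ins[2]][1])/3.0,
                             (pos[ins[0]][2]+pos[ins[1]][2]+pos[ins[2]][2])/3.0};
            add_tri(m, p1, p2, p3, cen, pos[a]);
          } else { // ni == 2
            int a = ins[0], b = ins[1], c = outs[0], d = outs[1];
            int pac = edge_point(m, gid[a], gid[c], pos[a], pos[c],
                                 val[a], val[c], iso);
            int pad = edge_point(m, gid[a], gid[d], pos[a], pos[d],
                                 val[a], val[d], iso);
            int pbc = edge_point(m, gid[b], gid[c], pos[b], pos[c],
                                 val[b], val[c], iso);
            int pbd = edge_point(m, gid[b], gid[d], pos[b], pos[d],
                                 val[b], val[d], iso);
            double min_[3] = {(pos[a][0]+pos[b][0])/2.0,
                              (pos[a][1]+pos[b][1])/2.0,
                              (pos[a][2]+pos[b][2])/2.0};
            double mout[3] = {(pos[c][0]+pos[d][0])/2.0,
                              (pos[c][1]+pos[d][1])/2.0,
                              (pos[c][2]+pos[d][2])/2.0};
            add_tri(m, pac, pad, pbd, min_, mout);
            add_tri(m, pac, pbd, pbc, min_, mout);
          }
        }
      }

  int nv = (int)m.vx.size(), nf = (int)m.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = m.vx[i]; V(i, 1) = m.vy[i]; V(i, 2) = m.vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = m.f0[i] + 1; F(i, 1) = m.f1[i] + 1; F(i, 2) = m.f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
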