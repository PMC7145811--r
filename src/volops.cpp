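// Voxel-volume primitives: 3D median filtering, connected-component
// labeling (6/26 connectivity), and binary morphology with a spherical
// structuring element. Volumes are column-major numeric/integer arrays.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
}

// reflect index into [0, n)
inline int refl(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector vol, int nx, int ny, int nz,
                           int radius) {
  NumericVector out(vol.size());
  int k = 2 * radius + 1;
  std::vector<double> buf(k * k * k);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int m = 0;
        for (int dz = -radius; dz <= radius; ++dz)
          for (int dy = -radius; dy <= radius; ++dy)
            for (int dx = -radius; dx <= radius; ++dx)
              buf[m++] = vol[idx3(refl(x + dx, nx), refl(y + dy, ny),
                                  refl(z + dz, nz), nx, ny)];
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[idx3(x, y, z, nx, ny)] = buf[m / 2];
      }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int nx, int ny, int nz,
                          int connectivity) {
  IntegerVector lab(mask.size(), 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::queue<std::array<int, 3>> q;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        if (!mask[i] || lab[i]) continue;
        lab[i] = ++cur;
        q.push({x, y, z});
        while (!q.empty()) {
          auto p = q.front(); q.pop();
          for (auto &o : offs) {
            int ax = p[0] + o[0], ay = p[1] + o[1], az = p[2] + o[2];
            if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
              continue;
            R_xlen_t j = idx3(ax, ay, az, nx, ny);
            if (mask[j] && !lab[j]) { lab[j] = cur; q.push({ax, ay, az}); }
          }
        }
      }
  lab.attr("n_labels") = cur;
  return lab;
}

// Binary dilation (or erosion when erode = true) with a digital ball of the
// given radius in voxels.
// [[Rcpp::export]]
LogicalVector cpp_morph3d(LogicalVector mask, int nx, int ny, int nz,
                          int radius, bool erode) {
  std::vector<std::array<int, 3>> offs;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius)
          offs.push_back({dx, dy, dz});
  LogicalVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool acc = erode;
        for (auto &o : offs) {
          int ax = x + o[0], ay = y + o[1], az = z + o[2];
          bool v;
          if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
            v = false; // outside treated as background
          else
            v = mask[idx3(ax, ay, az, nx, ny)];
          if (erode) { if (!v) { acc = false; break; } }
          else       { if (v)  { acc = true;  break; } }
        }
        out[idx3(x, y, z, nx, ny)] = acc;
      }
  return out;
}

// 3x3x3 box mean with reflecting edges; used to soften binary volumes
// before isosurface extraction.
// [[Rcpp::export]]
NumericVector cpp_boxmean3d(NumericVector vol, int nx, int ny, int nz) {
  NumericVector out(vol.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double s = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx)
              s += vol[idx3(refl(x + dx, nx), refl(y + dy, ny),
                            refl(z + dz, nz), nx, ny)];
        out[idx3(x, y, z, nx, ny)] = s / 27.0;
      }
  return out;
}
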