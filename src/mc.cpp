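// Monte Carlo photon transport in layered and voxelized turbid media.
// Weight-based absorption (albedo method), Henyey-Greenstein scattering,
// unpolarized Fresnel refraction/reflection at index mismatches,
// time-of-flight accumulated as n*s/c per step.
//
// All lengths in mm, time in ns. Uses R's RNG so set.seed() governs runs.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double C_MM_NS = 299.792458; // speed of light, mm/ns
static const double W_MIN = 1e-4;         // Russian-roulette threshold
static const double ROULETTE_P = 0.1;     // survival probability

// ---- small helpers ---------------------------------------------------------

inline double hg_cos_sample(double g) {
  double u = unif_rand();
  if (std::fabs(g) < 1e-8) return 2.0 * u - 1.0;
  double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - t * t) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

inline void spin(double &ux, double &uy, double &uz, double ct) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = (uz >= 0.0 ? ct : -ct);
  } else {
    double d = std::sqrt(1.0 - uz * uz);
    double nux = st * (ux * uz * cp - uy * sp) / d + ux * ct;
    double nuy = st * (uy * uz * cp + ux * sp) / d + uy * ct;
    double nuz = -d * st * cp + uz * ct;
    ux = nux; uy = nuy; uz = nuz;
  }
  // renormalize to fight drift
  double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= nrm; uy /= nrm; uz /= nrm;
}

// Unpolarized Fresnel reflectance for incidence cosine ci (>=0); on return
// ct holds the transmission cosine (0 under total internal reflection).
inline double fresnel_R(double n1, double n2, double ci, double &ct) {
  if (n1 == n2) { ct = ci; return 0.0; }
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n1 / n2 * si;
  if (st >= 1.0) { ct = 0.0; return 1.0; } // total internal reflection
  ct = std::sqrt(1.0 - st * st);
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// time bin index for edges (strictly increasing, starting at 0); the last
// slot is an overflow bin so the partition over time is exact.
inline int time_bin(double t, const std::vector<double> &edges) {
  int nt = (int)edges.size() - 1;
  if (t >= edges[nt]) return nt; // overflow
  int lo = 0, hi = nt;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (t >= edges[mid]) lo = mid; else hi = mid;
  }
  return lo;
}

// signed 1-degree angular bin: theta in [0,90) deg, sign from x-direction.
inline int ang_bin(double ux, double uz_abs) {
  double th = std::acos(std::min(1.0, uz_abs)) * 180.0 / M_PI;
  if (th >= 89.9999) th = 89.9999;
  int b = (int)std::floor(th);            // 0..89
  return (ux >= 0.0) ? (90 + b) : (89 - b); // signed bins -90..-1, 0..89
}

// [[Rcpp::export]]
double cpp_fresnel_unpolarized(double n1, double n2, double cos_i) {
  double ct;
  return fresnel_R(n1, n2, cos_i, ct);
}

// [[Rcpp::export]]
NumericVector cpp_hg_sample(double g, int n) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cos_sample(g);
  return out;
}

// ---- layered slab kernel ---------------------------------------------------

// Layers ordered along +z. Photons launched at z = 0 moving +z from ambient
// with index n_top; ambient below the last layer has index n_bot.
// Fluence is tallied by track length into nz depth bins x time bins
// (laterally integrated, i.e. per unit incident power per mm of depth).
// [[Rcpp::export]]
List cpp_mc_layered(NumericVector mua, NumericVector mus, NumericVector g,
                    NumericVector n, NumericVector thickness,
                    double n_top, double n_bot,
                    int n_photons, int nz, NumericVector time_edges,
                    double theta_in = 0.0) {
  int nl = mua.size();
  std::vector<double> zb(nl + 1);
  zb[0] = 0.0;
  for (int i = 0; i < nl; ++i) zb[i + 1] = zb[i] + thickness[i];
  double L = zb[nl];
  double dz = L / nz;

  std::vector<double> te(time_edges.begin(), time_edges.end());
  int nt = (int)te.size(); // nt-1 regular bins + 1 overflow slot

  NumericMatrix fluence(nz, nt);
  NumericVector ang_w(180);
  IntegerVector ang_n(180);
  double T_sum = 0, R_sum = 0, A_sum = 0;
  double closure_sumsq = 0; // per-photon (t + r + a)^2 for SE of closure
  double T_sumsq = 0;
  int n_trans = 0;

  double ci0 = std::cos(theta_in);
  double si0 = std::sin(theta_in);

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = 0, y = 0, z = 0;
    double ux = si0, uy = 0, uz = ci0;
    double w = 1.0, t = 0.0;
    double pt = 0, pr = 0, pa = 0; // this photon's tallies
    int lay = 0;
    bool alive = true;

    // entry interface ambient -> layer 0
    {
      double ct;
      double R = fresnel_R(n_top, n[0], uz, ct);
      if (unif_rand() < R) {
        pr = w; alive = false;
      } else {
        ux *= n_top / n[0]; uy *= n_top / n[0]; uz = ct;
        double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
        ux /= nrm; uy /= nrm; uz /= nrm;
      }
    }

    long steps = 0;
    while (alive) {
      if (++steps > 50000000L) { pa += w; break; } // pathological guard
      double mt = mua[lay] + mus[lay];
      double s = (mt > 0.0) ? -std::log(unif_rand()) / mt : R_PosInf;
      double db;
      if (uz > 1e-12) db = (zb[lay + 1] - z) / uz;
      else if (uz < -1e-12) db = (zb[lay] - z) / uz;
      else db = R_PosInf;

      if (!R_finite(s) && !R_finite(db)) { pa += w; break; } // stuck sideways

      double seg = std::min(s, db);
      // deposit track length across depth bins along the segment
      double z_end = z + seg * uz;
      if (std::fabs(uz) > 1e-12) {
        double zlo = std::min(z, z_end), zhi = std::max(z, z_end);
        int b0 = std::max(0, (int)std::floor(zlo / dz));
        int b1 = std::min(nz - 1, (int)std::floor((zhi - 1e-12) / dz));
        double tpermm = n[lay] / C_MM_NS;
        for (int b = b0; b <= b1; ++b) {
          double lo = std::max(zlo, b * dz), hi = std::min(zhi, (b + 1) * dz);
          if (hi > lo) {
            // time at the midpoint of this sub-segment, preserving causality
            double zmid = 0.5 * (lo + hi);
            double along = (zmid - z) / uz; // distance from segment start
            int tb = time_bin(t + along * tpermm, te);
            fluence(b, tb) += w * (hi - lo) / std::fabs(uz);
          }
        }
      } else {
        int b = std::min(nz - 1, std::max(0, (int)std::floor(z / dz)));
        int tb = time_bin(t, te);
        fluence(b, tb) += w * seg;
      }
      x += seg * ux; y += seg * uy; z = z_end;
      t += seg * n[lay] / C_MM_NS;

      if (s < db) {
        // collision: absorb part of the weight, then scatter
        double alb = (mt > 0.0) ? mus[lay] / mt : 1.0;
        pa += w * (1.0 - alb);
        w *= alb;
        if (w <= 0.0) break;
        spin(ux, uy, uz, hg_cos_sample(g[lay]));
        if (w < W_MIN) {
          if (unif_rand() < ROULETTE_P) w /= ROULETTE_P; else break;
        }
      } else {
        // boundary: Fresnel against neighbor layer or ambient
        bool down = uz > 0.0;
        z = down ? zb[lay + 1] : zb[lay];
        int nxt = down ? lay + 1 : lay - 1;
        double n2 = (nxt < 0) ? n_top : (nxt >= nl ? n_bot : n[nxt]);
        double ct;
        double R = fresnel_R(n[lay], n2, std::fabs(uz), ct);
        if (unif_rand() < R) {
          uz = -uz; // reflected back into the layer
        } else {
          double scale = n[lay] / n2;
          ux *= scale; uy *= scale;
          uz = down ? ct : -ct;
          double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
          ux /= nrm; uy /= nrm; uz /= nrm;
          if (nxt < 0) { pr = w; break; }
          if (nxt >= nl) {
            pt = w; n_trans++;
            int b = ang_bin(ux, std::fabs(uz));
            ang_w[b] += w; ang_n[b]++;
            break;
          }
          lay = nxt;
        }
      }
    }
    T_sum += pt; R_sum += pr; A_sum += pa;
    double cl = pt + pr + pa;
    closure_sumsq += cl * cl;
    T_sumsq += pt * pt;
  }

  return List::create(
    _["T_sum"] = T_sum, _["R_sum"] = R_sum, _["A_sum"] = A_sum,
    _["S_sum"] = 0.0,
    _["closure_sumsq"] = closure_sumsq, _["T_sumsq"] = T_sumsq,
    _["fluence"] = fluence, _["ang_w"] = ang_w, _["ang_n"] = ang_n,
    _["n_transmitted"] = n_trans, _["dz"] = dz, _["L"] = L);
}

// ---- voxel grid kernel -----------------------------------------------------

// labels: 1-based material labels over an nx x ny x nz grid (column-major,
// x fastest). Ambient (index n_amb, non-scattering) surrounds the grid.
// Source enters the top face (z = 0) moving +z: pencil at (x0, y0), or
// plane wave (uniform random position over the top face) when plane = true.
// [[Rcpp::export]]
List cpp_mc_voxel(IntegerVector labels, int nx, int ny, int nz,
                  double dx, double dy, double dzv,
                  NumericVector mua, NumericVector mus, NumericVector g,
                  NumericVector n, double n_amb,
                  int n_photons, NumericVector time_edges,
                  bool plane, double x0, double y0) {
  std::vector<double> te(time_edges.begin(), time_edges.end());
  int nt = (int)te.size();

  NumericVector flu(nx * ny * nz); // track-length per voxel
  NumericMatrix depth_time(nz, nt);
  NumericVector ang_w(180);
  IntegerVector ang_n(180);
  double T_sum = 0, R_sum = 0, A_sum = 0, S_sum = 0;
  double closure_sumsq = 0, T_sumsq = 0;
  int n_trans = 0;

  double X = nx * dx, Y = ny * dy;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x = plane ? unif_rand() * X : x0;
    double y = plane ? unif_rand() * Y : y0;
    double z = 0.0;
    double ux = 0, uy = 0, uz = 1;
    double w = 1.0, t = 0.0;
    double pt = 0, pr = 0, pa = 0, ps = 0;
    int ix = std::min(nx - 1, (int)std::floor(x / dx));
    int iy = std::min(ny - 1, (int)std::floor(y / dy));
    int iz = 0;
    bool alive = true;

    int lab = labels[ix + nx * (iy + (R_xlen_t)ny * iz)] - 1;
    {
      double ct;
      double R = fresnel_R(n_amb, n[lab], 1.0, ct);
      if (unif_rand() < R) { pr = w; alive = false; }
    }

    double tau = alive ? -std::log(unif_rand()) : 0.0;
    long steps = 0;
    while (alive) {
      if (++steps > 50000000L) { pa += w; break; }
      lab = labels[ix + nx * (iy + (R_xlen_t)ny * iz)] - 1;
      double mt = mua[lab] + mus[lab];
      // distances to the three exit faces of the current voxel
      double tx = (ux > 1e-12) ? ((ix + 1) * dx - x) / ux
                : (ux < -1e-12) ? (ix * dx - x) / ux : R_PosInf;
      double ty = (uy > 1e-12) ? ((iy + 1) * dy - y) / uy
                : (uy < -1e-12) ? (iy * dy - y) / uy : R_PosInf;
      double tz = (uz > 1e-12) ? ((iz + 1) * dzv - z) / uz
                : (uz < -1e-12) ? (iz * dzv - z) / uz : R_PosInf;
      double dface = std::min(tx, std::min(ty, tz));
      if (dface < 0) dface = 0;
      double dcol = (mt > 0.0) ? tau / mt : R_PosInf;

      if (!R_finite(dcol) && !R_finite(dface)) { pa += w; break; }

      double seg = std::min(dcol, dface);
      flu[ix + nx * (iy + (R_xlen_t)ny * iz)] += w * seg;
      {
        double tmid = t + 0.5 * seg * n[lab] / C_MM_NS;
        depth_time(iz, time_bin(tmid, te)) += w * seg;
      }
      x += seg * ux; y += seg * uy; z += seg * uz;
      t += seg * n[lab] / C_MM_NS;

      if (dcol <= dface) {
        // collision
        double alb = mus[lab] / mt;
        pa += w * (1.0 - alb);
        w *= alb;
        if (w <= 0.0) break;
        spin(ux, uy, uz, hg_cos_sample(g[lab]));
        if (w < W_MIN) {
          if (unif_rand() < ROULETTE_P) w /= ROULETTE_P; else break;
        }
        tau = -std::log(unif_rand());
      } else {
        tau -= mt * seg;
        if (tau < 0) tau = 0;
        // which face: 0=x,1=y,2=z
        int axis = (dface == tx) ? 0 : (dface == ty ? 1 : 2);
        int sgn = (axis == 0 ? (ux > 0) : axis == 1 ? (uy > 0) : (uz > 0))
                      ? 1 : -1;
        // snap to face plane
        if (axis == 0) x = (sgn > 0 ? (ix + 1) : ix) * dx;
        else if (axis == 1) y = (sgn > 0 ? (iy + 1) : iy) * dy;
        else z = (sgn > 0 ? (iz + 1) : iz) * dzv;

        int jx = ix + (axis == 0 ? sgn : 0);
        int jy = iy + (axis == 1 ? sgn : 0);
        int jz = iz + (axis == 2 ? sgn : 0);
        bool outside = (jx < 0 || jx >= nx || jy < 0 || jy >= ny ||
                        jz < 0 || jz >= nz);
        double n2 = outside ? n_amb
                            : n[labels[jx + nx * (jy + (R_xlen_t)ny * jz)] - 1];
        double n1 = n[lab];
        double un = (axis == 0 ? ux : axis == 1 ? uy : uz);
        double ct;
        double R = fresnel_R(n1, n2, std::fabs(un), ct);
        if (unif_rand() < R) {
          if (axis == 0) ux = -ux; else if (axis == 1) uy = -uy; else uz = -uz;
        } else {
          if (n1 != n2) {
            double scale = n1 / n2;
            ux *= scale; uy *= scale; uz *= scale;
            if (axis == 0) ux = (un > 0 ? ct : -ct);
            else if (axis == 1) uy = (un > 0 ? ct : -ct);
            else uz = (un > 0 ? ct : -ct);
            double nrm = std::sqrt(ux * ux + uy * uy + uz * uz);
            ux /= nrm; uy /= nrm; uz /= nrm;
          }
          if (outside) {
            if (axis == 2 && sgn > 0) {
              pt = w; n_trans++;
              int b = ang_bin(ux, std::fabs(uz));
              ang_w[b] += w; ang_n[b]++;
            } else if (axis == 2) {
              pr = w;
            } else {
              ps = w;
            }
            break;
          }
          ix = jx; iy = jy; iz = jz;
        }
      }
    }
    T_sum += pt; R_sum += pr; A_sum += pa; S_sum += ps;
    double cl = pt + pr + pa + ps;
    closure_sumsq += cl * cl;
    T_sumsq += pt * pt;
  }

  flu.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(
    _["T_sum"] = T_sum, _["R_sum"] = R_sum, _["A_sum"] = A_sum,
    _["S_sum"] = S_sum,
    _["closure_sumsq"] = closure_sumsq, _["T_sumsq"] = T_sumsq,
    _["fluence"] = flu, _["depth_time"] = depth_time,
    _["ang_w"] = ang_w, _["ang_n"] = ang_n,
    _["n_transmitted"] = n_trans, _["dz"] = dzv, _["L"] = nz * dzv);
}
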