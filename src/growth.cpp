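#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared), separable lower-envelope
// algorithm, with anisotropic voxel spacing. Distances are measured between
// voxel centers.
// ---------------------------------------------------------------------------

// "infinite" squared distance: far larger than any domain extent, small
// enough that parabola-intersection arithmetic cannot overflow the sentinels
static const double DT_INF = 1e20;
static const double Z_NEG = -1e30;
static const double Z_POS = 1e30;

// 1-D squared distance transform along one line; samples at coordinates i*h
static void dt1d(const double* f, double* d, int n, double h,
                 std::vector<int>& v, std::vector<double>& z) {
  if (n == 1) { d[0] = f[0]; return; }
  const double h2 = h * h;
  int k = 0;
  v[0] = 0;
  z[0] = Z_NEG;
  z[1] = Z_POS;
  for (int q = 1; q < n; ++q) {
    if (f[q] >= DT_INF && f[v[k]] >= DT_INF) { v[k] = q; continue; }
    double s;  // intersection abscissa, in physical coordinates
    while (true) {
      double fq = f[q], fv = f[v[k]];
      s = ((fq + (double)q * q * h2) - (fv + (double)v[k] * v[k] * h2)) /
          (2.0 * h * (q - v[k]));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = Z_POS;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q * h) ++k;
    double dx = (q - v[k]) * h;
    d[q] = dx * dx + f[v[k]];
  }
}

// squared EDT over the sub-box [x0,x1]x[y0,y1]x[z0,z1] of a full grid;
// `out` has full-grid layout but only the sub-box is touched.
static void edt3_sq_box(const std::vector<char>& feat, double* out,
                        int nx, int ny, int nz,
                        double hx, double hy, double hz,
                        int x0, int x1, int y0, int y1, int z0, int z1) {
  const size_t sy = nx, sz = (size_t)nx * ny;
  for (int iz = z0; iz <= z1; ++iz)
    for (int iy = y0; iy <= y1; ++iy)
      for (int ix = x0; ix <= x1; ++ix) {
        size_t i = ix + sy * iy + sz * iz;
        out[i] = feat[i] ? 0.0 : DT_INF;
      }

  int bx = x1 - x0 + 1, by = y1 - y0 + 1, bz = z1 - z0 + 1;
  int nmax = std::max(bx, std::max(by, bz));
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1), line(nmax), dline(nmax);

  if (bx > 1)
    for (int iz = z0; iz <= z1; ++iz)
      for (int iy = y0; iy <= y1; ++iy) {
        double* row = out + x0 + sy * iy + sz * iz;
        dt1d(row, dline.data(), bx, hx, v, z);
        std::copy(dline.begin(), dline.begin() + bx, row);
      }
  if (by > 1)
    for (int iz = z0; iz <= z1; ++iz)
      for (int ix = x0; ix <= x1; ++ix) {
        for (int iy = 0; iy < by; ++iy)
          line[iy] = out[ix + sy * (iy + y0) + sz * iz];
        dt1d(line.data(), dline.data(), by, hy, v, z);
        for (int iy = 0; iy < by; ++iy)
          out[ix + sy * (iy + y0) + sz * iz] = dline[iy];
      }
  if (bz > 1)
    for (int iy = y0; iy <= y1; ++iy)
      for (int ix = x0; ix <= x1; ++ix) {
        for (int iz = 0; iz < bz; ++iz)
          line[iz] = out[ix + sy * iy + sz * (iz + z0)];
        dt1d(line.data(), dline.data(), bz, hz, v, z);
        for (int iz = 0; iz < bz; ++iz)
          out[ix + sy * iy + sz * (iz + z0)] = dline[iz];
      }
}

// Normalized distance-to-periphery d(x) for a tumor mask: 1 at mask
// boundary voxels and everywhere outside the mask, 0 at the deepest voxel.
// Work is confined to the mask bounding box.
static void periphery_distance(const std::vector<char>& tmask, double* d,
                               int nx, int ny, int nz,
                               double hx, double hy, double hz,
                               std::vector<char>& bnd,
                               std::vector<double>& depth) {
  const size_t n = (size_t)nx * ny * nz;
  const size_t sy = nx, sz = (size_t)nx * ny;

  int x0 = nx, x1 = -1, y0 = ny, y1 = -1, z0 = nz, z1 = -1;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix)
        if (tmask[ix + sy * iy + sz * iz]) {
          if (ix < x0) x0 = ix; if (ix > x1) x1 = ix;
          if (iy < y0) y0 = iy; if (iy > y1) y1 = iy;
          if (iz < z0) z0 = iz; if (iz > z1) z1 = iz;
        }
  if (x1 < 0) { for (size_t i = 0; i < n; ++i) d[i] = 1.0; return; }

  // periphery = in-mask voxels with an in-grid face neighbour outside the
  // mask; a mask face pressed against the array edge is not periphery
  bool any_bnd = false;
  for (int iz = z0; iz <= z1; ++iz)
    for (int iy = y0; iy <= y1; ++iy)
      for (int ix = x0; ix <= x1; ++ix) {
        size_t i = ix + sy * iy + sz * iz;
        if (!tmask[i]) { bnd[i] = 0; continue; }
        bool b = (ix > 0 && !tmask[i - 1]) ||
                 (ix < nx - 1 && !tmask[i + 1]) ||
                 (iy > 0 && !tmask[i - sy]) ||
                 (iy < ny - 1 && !tmask[i + sy]) ||
                 (iz > 0 && !tmask[i - sz]) ||
                 (iz < nz - 1 && !tmask[i + sz]);
        bnd[i] = b ? 1 : 0;
        if (b) any_bnd = true;
      }
  if (!any_bnd) {  // mask fills its whole domain: no periphery information
    for (size_t i = 0; i < n; ++i) d[i] = 1.0;
    return;
  }

  edt3_sq_box(bnd, depth.data(), nx, ny, nz, hx, hy, hz,
              x0, x1, y0, y1, z0, z1);

  double maxd = 0.0;
  for (int iz = z0; iz <= z1; ++iz)
    for (int iy = y0; iy <= y1; ++iy)
      for (int ix = x0; ix <= x1; ++ix) {
        size_t i = ix + sy * iy + sz * iz;
        if (tmask[i]) {
          double dd = std::sqrt(depth[i]);
          depth[i] = dd;
          if (dd > maxd) maxd = dd;
        }
      }
  for (size_t i = 0; i < n; ++i) d[i] = 1.0;
  if (maxd > 0.0)
    for (int iz = z0; iz <= z1; ++iz)
      for (int iy = y0; iy <= y1; ++iy)
        for (int ix = x0; ix <= x1; ++ix) {
          size_t i = ix + sy * iy + sz * iz;
          if (tmask[i]) d[i] = 1.0 - depth[i] / maxd;
        }
}

// [[Rcpp::export]]
NumericVector edt_depth_cpp(LogicalVector features, IntegerVector dims,
                            NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> feat(n);
  for (size_t i = 0; i < n; ++i) feat[i] = features[i] ? 1 : 0;
  NumericVector out(n);
  edt3_sq_box(feat, REAL(out), nx, ny, nz, spacing[0], spacing[1], spacing[2],
              0, nx - 1, 0, ny - 1, 0, nz - 1);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector periphery_distance_cpp(LogicalVector tumor_mask,
                                     IntegerVector dims,
                                     NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  std::vector<char> tmask(n), bnd(n);
  std::vector<double> depth(n);
  for (size_t i = 0; i < n; ++i) tmask[i] = tumor_mask[i] ? 1 : 0;
  NumericVector d(n);
  periphery_distance(tmask, REAL(d), nx, ny, nz,
                     spacing[0], spacing[1], spacing[2], bnd, depth);
  return d;
}

// ---------------------------------------------------------------------------
// Coupled tumor/vasculature reaction-diffusion stepper.
//
// Explicit forward Euler with divergence-form fluxes and face-averaged
// diffusivities / cross-diffusion weights; zero-flux boundaries at the
// brain mask edge. Interior faces and in-mask voxels are enumerated once so
// each step is a flat pass over faces (flux gather/scatter) and voxels
// (reactions, update, clipping). The periphery distance d(x) and carrying
// capacity are refreshed as requested; the mechanics-derived diffusivity
// fields are held fixed for the duration of the call.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List rd_advance_cpp(NumericVector nt_in, NumericVector nv_in,
                    NumericVector dtf, NumericVector dvf,
                    LogicalVector brain, IntegerVector dims,
                    NumericVector spacing,
                    double theta_min, double theta_max, double nv_thresh,
                    double k_t, double k_v, double k_dv,
                    double mask_thresh, double dt, int nsteps,
                    int d_update_every) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double ih2[3] = {1.0 / (hx * hx), 1.0 / (hy * hy), 1.0 / (hz * hz)};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};

  std::vector<double> nt(nt_in.begin(), nt_in.end());
  std::vector<double> nv(nv_in.begin(), nv_in.end());
  std::vector<char> msk(n);
  for (size_t i = 0; i < n; ++i) msk[i] = brain[i] ? 1 : 0;

  // active voxels and interior faces
  std::vector<int> act;
  act.reserve(n);
  for (size_t i = 0; i < n; ++i) {
    if (!msk[i]) continue;
    act.push_back((int)i);
    if (nt[i] < 0.0 || nv[i] < 0.0)
      stop("negative species fraction in input fields");
  }
  std::vector<int> fi, fj;
  std::vector<double> fh2;
  fi.reserve(3 * act.size());
  fj.reserve(3 * act.size());
  fh2.reserve(3 * act.size());
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        size_t i = ix + stride[1] * iy + stride[2] * iz;
        if (!msk[i]) continue;
        int at_end[3] = {ix == nx - 1, iy == ny - 1, iz == nz - 1};
        for (int ax = 0; ax < 3; ++ax) {
          if (at_end[ax]) continue;
          size_t j = i + stride[ax];
          if (!msk[j]) continue;
          fi.push_back((int)i);
          fj.push_back((int)j);
          fh2.push_back(ih2[ax]);
        }
      }
  const size_t nact = act.size(), nface = fi.size();

  std::vector<double> theta(n, theta_max), itheta(n, 1.0 / theta_max),
      dper(n, 1.0);
  std::vector<double> ant(n, 0.0), anv(n, 0.0);
  std::vector<char> tmask(n, 0), bnd(n, 0);
  std::vector<double> depth(n);
  const double slope = (theta_max - theta_min) / nv_thresh;

  for (int step = 0; step < nsteps; ++step) {
    if (d_update_every > 0 && step % d_update_every == 0) {
      for (size_t a = 0; a < nact; ++a) {
        int i = act[a];
        tmask[i] = nt[i] > mask_thresh ? 1 : 0;
      }
      periphery_distance(tmask, dper.data(), nx, ny, nz, hx, hy, hz,
                         bnd, depth);
    }
    for (size_t a = 0; a < nact; ++a) {
      int i = act[a];
      double th = nv[i] < nv_thresh ? theta_min + nv[i] * slope : theta_max;
      theta[i] = th;
      itheta[i] = 1.0 / th;
      ant[i] = 0.0;
      anv[i] = 0.0;
    }
    for (size_t f = 0; f < nface; ++f) {
      const int i = fi[f], j = fj[f];
      const double rti = nt[i] * itheta[i], rvi = nv[i] * itheta[i];
      const double rtj = nt[j] * itheta[j], rvj = nv[j] * itheta[j];
      const double dnt = nt[j] - nt[i], dnv = nv[j] - nv[i];
      const double Dt_f = 0.5 * (dtf[i] + dtf[j]);
      const double Dv_f = 0.5 * (dvf[i] + dvf[j]);
      const double Ft = Dt_f * ((1.0 - 0.5 * (rvi + rvj)) * dnt +
                                0.5 * (rti + rtj) * dnv) * fh2[f];
      const double Fv = Dv_f * ((1.0 - 0.5 * (rti + rtj)) * dnv +
                                0.5 * (rvi + rvj) * dnt) * fh2[f];
      ant[i] += Ft; ant[j] -= Ft;
      anv[i] += Fv; anv[j] -= Fv;
    }
    for (size_t a = 0; a < nact; ++a) {
      const int i = act[a];
      const double th = theta[i], dpx = dper[i];
      double t = nt[i], v = nv[i];
      t += dt * (ant[i] + k_t * t * (1.0 - t / th));
      v += dt * (anv[i] + k_v * v * (1.0 - v / th) * dpx -
                 k_dv * v * (1.0 - dpx));
      const double thn = v < nv_thresh
                           ? theta_min + std::max(v, 0.0) * slope : theta_max;
      nt[i] = t < 0.0 ? 0.0 : (t > thn ? thn : t);
      nv[i] = v < 0.0 ? 0.0 : (v > thn ? thn : v);
    }
  }

  NumericVector nt_out(nt.begin(), nt.end());
  NumericVector nv_out(nv.begin(), nv.end());
  NumericVector d_out(dper.begin(), dper.end());
  NumericVector th_out(theta.begin(), theta.end());
  return List::create(_["N_t"] = nt_out, _["N_v"] = nv_out,
                      _["d"] = d_out, _["theta_tot"] = th_out);
}
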