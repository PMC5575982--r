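// Low-level raster kernels: separable convolution, backward warping
// (tricubic / trilinear / nearest-neighbour), exact Euclidean distance
// transform, fixed-point DVF inversion, morphological DVF repair,
// patch-based pattern synthesis and the Demons update loop.
//
// All volumes are R arrays in column-major order, dim = (nx, ny, nz),
// linear index i + nx*(j + ny*k).  Vector fields append a 4th dimension
// of size 3 (x, y, z components, millimetres, world axes).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <queue>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Separable convolution along one axis, zero-padded (no normalisation).
// ---------------------------------------------------------------------------
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nx, int ny, int nz,
                      const std::vector<double>& k, int axis) {
  const int r = ((int)k.size() - 1) / 2;
  const int n[3] = {nx, ny, nz};
  const long sy = (long)nx, sz = (long)nx * ny;
  const long stride = axis == 0 ? 1 : (axis == 1 ? sy : sz);
  const int  len    = n[axis];
  const double* kc = k.data() + r;
  long idx = 0;
  for (int kk = 0; kk < nz; ++kk)
    for (int jj = 0; jj < ny; ++jj)
      for (int ii = 0; ii < nx; ++ii, ++idx) {
        const int ci = axis == 0 ? ii : (axis == 1 ? jj : kk);
        const int t0 = std::max(-r, -ci), t1 = std::min(r, len - 1 - ci);
        const double* src = in.data() + idx;
        double acc = 0.0;
        for (int t = t0; t <= t1; ++t) acc += kc[t] * src[(long)t * stride];
        out[idx] = acc;
      }
}

static void conv_sep3(std::vector<double>& buf, std::vector<double>& tmp,
                      int nx, int ny, int nz, const std::vector<double>& k) {
  conv_axis(buf, tmp, nx, ny, nz, k, 0);
  conv_axis(tmp, buf, nx, ny, nz, k, 1);
  conv_axis(buf, tmp, nx, ny, nz, k, 2);
  buf.swap(tmp);
}

// Separable kernel applied along all 3 axes, zero padding, then divided by
// the same convolution of a ones-volume (i.e. the kernel is renormalised
// where its support leaves the grid).
// [[Rcpp::export]]
NumericVector cpp_conv_sep_norm(NumericVector vol, IntegerVector dims,
                                NumericVector kernel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  std::vector<double> k(kernel.begin(), kernel.end());
  std::vector<double> buf(vol.begin(), vol.end()), tmp(n), ones(n, 1.0), tmp2(n);
  conv_sep3(buf, tmp, nx, ny, nz, k);
  conv_sep3(ones, tmp2, nx, ny, nz, k);
  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = ones[i] > 0 ? buf[i] / ones[i] : 0.0;
  out.attr("dim") = dims;
  return out;
}

// Moving-average box filter of width w restricted to a mask: each in-mask
// voxel becomes the mean of in-mask voxels in its w^3 window; out-of-mask
// voxels pass through unchanged.
// [[Rcpp::export]]
NumericVector cpp_boxfilter_masked(NumericVector vol, IntegerVector mask,
                                   IntegerVector dims, int w) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  std::vector<double> k(w, 1.0);
  std::vector<double> vm(n), wm(n), t1(n), t2(n);
  for (long i = 0; i < n; ++i) {
    wm[i] = mask[i] != 0 ? 1.0 : 0.0;
    vm[i] = wm[i] * vol[i];
  }
  conv_sep3(vm, t1, nx, ny, nz, k);
  conv_sep3(wm, t2, nx, ny, nz, k);
  NumericVector out(n);
  for (long i = 0; i < n; ++i)
    out[i] = (mask[i] != 0 && wm[i] > 0) ? vm[i] / wm[i] : vol[i];
  out.attr("dim") = dims;
  return out;
}

// Plain moving-average box filter (edge-renormalised).
// [[Rcpp::export]]
NumericVector cpp_boxfilter_plain(NumericVector vol, IntegerVector dims, int w) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  std::vector<double> k(w, 1.0);
  std::vector<double> vm(vol.begin(), vol.end()), wm(n, 1.0), t1(n), t2(n);
  conv_sep3(vm, t1, nx, ny, nz, k);
  conv_sep3(wm, t2, nx, ny, nz, k);
  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = vm[i] / wm[i];
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Interpolation
// ---------------------------------------------------------------------------
static inline double sample_trilinear_clamped(const double* v, int nx, int ny,
                                              int nz, double x, double y,
                                              double z) {
  x = std::min(std::max(x, 0.0), (double)(nx - 1));
  y = std::min(std::max(y, 0.0), (double)(ny - 1));
  z = std::min(std::max(z, 0.0), (double)(nz - 1));
  int i0 = std::min((int)std::floor(x), nx - 2); if (nx == 1) i0 = 0;
  int j0 = std::min((int)std::floor(y), ny - 2); if (ny == 1) j0 = 0;
  int k0 = std::min((int)std::floor(z), nz - 2); if (nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
      k1 = std::min(k0 + 1, nz - 1);
  const long sy = nx, sz = (long)nx * ny;
  double c00 = v[i0 + sy * j0 + sz * k0] * (1 - fx) + v[i1 + sy * j0 + sz * k0] * fx;
  double c10 = v[i0 + sy * j1 + sz * k0] * (1 - fx) + v[i1 + sy * j1 + sz * k0] * fx;
  double c01 = v[i0 + sy * j0 + sz * k1] * (1 - fx) + v[i1 + sy * j0 + sz * k1] * fx;
  double c11 = v[i0 + sy * j1 + sz * k1] * (1 - fx) + v[i1 + sy * j1 + sz * k1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Catmull-Rom weights (interpolating cubic, exact at nodes, reproduces
// linear and quadratic polynomials).
static inline void cr_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = -0.5 * t3 + t2 - 0.5 * t;
  w[1] =  1.5 * t3 - 2.5 * t2 + 1.0;
  w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
  w[3] =  0.5 * t3 - 0.5 * t2;
}

// Backward warp with tricubic interpolation: out(x) = vol(x + u(x)/spacing).
// Pullbacks outside the grid take `fill`.
// [[Rcpp::export]]
NumericVector cpp_warp_tricubic(NumericVector vol, IntegerVector dims,
                                NumericVector field, double spacing,
                                double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const double* v = vol.begin();
  const double* ux = field.begin();
  const double* uy = ux + n;
  const double* uz = uy + n;
  NumericVector out(n);
  const long sy = nx, sz = (long)nx * ny;
  long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + ux[idx] / spacing;
        double y = j + uy[idx] / spacing;
        double z = k + uz[idx] / spacing;
        if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1 || z < 0 || z > nz - 1) {
          out[idx] = fill;
          continue;
        }
        int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
            k0 = (int)std::floor(z);
        double wx[4], wy[4], wz[4];
        cr_weights(x - i0, wx);
        cr_weights(y - j0, wy);
        cr_weights(z - k0, wz);
        double acc = 0.0;
        for (int c = 0; c < 4; ++c) {
          int kk = clampi(k0 - 1 + c, 0, nz - 1);
          double accy = 0.0;
          for (int b = 0; b < 4; ++b) {
            int jj = clampi(j0 - 1 + b, 0, ny - 1);
            const double* row = v + sy * jj + sz * kk;
            double accx = 0.0;
            for (int a = 0; a < 4; ++a)
              accx += wx[a] * row[clampi(i0 - 1 + a, 0, nx - 1)];
            accy += wy[b] * accx;
          }
          acc += wz[c] * accy;
        }
        out[idx] = acc;
      }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_warp_trilinear(NumericVector vol, IntegerVector dims,
                                 NumericVector field, double spacing,
                                 double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const double* v = vol.begin();
  const double* ux = field.begin();
  const double* uy = ux + n;
  const double* uz = uy + n;
  NumericVector out(n);
  long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + ux[idx] / spacing;
        double y = j + uy[idx] / spacing;
        double z = k + uz[idx] / spacing;
        if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1 || z < 0 || z > nz - 1)
          out[idx] = fill;
        else
          out[idx] = sample_trilinear_clamped(v, nx, ny, nz, x, y, z);
      }
  out.attr("dim") = dims;
  return out;
}

// Nearest-neighbour backward pullback for label volumes.
// [[Rcpp::export]]
IntegerVector cpp_warp_nn(IntegerVector labels, IntegerVector dims,
                          NumericVector field, double spacing, int fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const double* ux = field.begin();
  const double* uy = ux + n;
  const double* uz = uy + n;
  IntegerVector out(n);
  const long sy = nx, sz = (long)nx * ny;
  long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + ux[idx] / spacing;
        double y = j + uy[idx] / spacing;
        double z = k + uz[idx] / spacing;
        int ii = (int)std::lround(x), jj = (int)std::lround(y),
            kk = (int)std::lround(z);
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          out[idx] = fill;
        else
          out[idx] = labels[ii + sy * jj + sz * kk];
      }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Fixed-point DVF inversion:  u_b(x) <- -u_f(x + u_b(x))
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_invert_dvf(NumericVector fwd, IntegerVector dims, double spacing,
                    int max_iter, double tol_mm, NumericVector u0,
                    double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const double* fx = fwd.begin();
  const double* fy = fx + n;
  const double* fz = fy + n;
  NumericVector back(3 * n);
  double* bx = back.begin();
  double* by = bx + n;
  double* bz = by + n;
  if (u0.size() == 3 * n) {
    for (long i = 0; i < n; ++i) { bx[i] = u0[i]; by[i] = u0[n + i]; bz[i] = u0[2 * n + i]; }
  } else {
    // initial guess u_b = -u_f(x)
    for (long i = 0; i < n; ++i) { bx[i] = -fx[i]; by[i] = -fy[i]; bz[i] = -fz[i]; }
  }
  double maxupd = R_PosInf;
  int it = 0;
  for (; it < max_iter && maxupd >= tol_mm; ++it) {
    maxupd = 0.0;
    long idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          double x = i + bx[idx] / spacing;
          double y = j + by[idx] / spacing;
          double z = k + bz[idx] / spacing;
          // under-relaxed update: stabilizes the iteration where the
          // coupled displacement Jacobian has spectral radius near 1
          double nxv = (1 - omega) * bx[idx] -
                       omega * sample_trilinear_clamped(fx, nx, ny, nz, x, y, z);
          double nyv = (1 - omega) * by[idx] -
                       omega * sample_trilinear_clamped(fy, nx, ny, nz, x, y, z);
          double nzv = (1 - omega) * bz[idx] -
                       omega * sample_trilinear_clamped(fz, nx, ny, nz, x, y, z);
          double d = std::max(std::fabs(nxv - bx[idx]),
                     std::max(std::fabs(nyv - by[idx]),
                              std::fabs(nzv - bz[idx])));
          if (d > maxupd) maxupd = d;
          bx[idx] = nxv; by[idx] = nyv; bz[idx] = nzv;
        }
  }
  // composition residual over voxels whose pullback stays in-grid
  double resid = 0.0;
  long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = i + bx[idx] / spacing;
        double y = j + by[idx] / spacing;
        double z = k + bz[idx] / spacing;
        if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1 || z < 0 || z > nz - 1)
          continue;
        double rx = sample_trilinear_clamped(fx, nx, ny, nz, x, y, z) + bx[idx];
        double ry = sample_trilinear_clamped(fy, nx, ny, nz, x, y, z) + by[idx];
        double rz = sample_trilinear_clamped(fz, nx, ny, nz, x, y, z) + bz[idx];
        double r = std::max(std::fabs(rx), std::max(std::fabs(ry), std::fabs(rz)));
        if (r > resid) resid = r;
      }
  back.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return List::create(_["field"] = back, _["iterations"] = it,
                      _["max_update"] = maxupd, _["residual"] = resid,
                      _["converged"] = maxupd < tol_mm);
}

// ---------------------------------------------------------------------------
// DVF repair: replace isolated outliers ("holes"/"spurs") by the 3^3
// neighbourhood median, component-wise.  A voxel is flagged when its value
// deviates from the 26-neighbour median by > dev_mm while at least
// min_agree of the 26 neighbours agree with that median within agree_mm.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_repair_dvf(NumericVector field, IntegerVector dims, double dev_mm,
                    double agree_mm, int min_agree, int max_sweeps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  NumericVector out = clone(field);
  const long sy = nx, sz = (long)nx * ny;
  long total_flagged = 0;
  for (int comp = 0; comp < 3; ++comp) {
    double* v = out.begin() + (long)comp * n;
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      std::vector<double> src(v, v + n);
      long flagged = 0;
      double nb[26];
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j)
          for (int i = 1; i < nx - 1; ++i) {
            long idx = i + sy * j + sz * k;
            int m = 0;
            for (int dk = -1; dk <= 1; ++dk)
              for (int dj = -1; dj <= 1; ++dj)
                for (int di = -1; di <= 1; ++di) {
                  if (di == 0 && dj == 0 && dk == 0) continue;
                  nb[m++] = src[idx + di + sy * dj + sz * dk];
                }
            std::nth_element(nb, nb + 13, nb + 26);
            double med = nb[13];
            if (std::fabs(src[idx] - med) <= dev_mm) continue;
            int agree = 0;
            for (int t = 0; t < 26; ++t)
              if (std::fabs(nb[t] - med) <= agree_mm) ++agree;
            if (agree >= min_agree) { v[idx] = med; ++flagged; }
          }
      total_flagged += flagged;
      if (flagged == 0) break;
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return List::create(_["field"] = out, _["n_repaired"] = (double)total_flagged);
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// distance (mm) from each nonzero voxel to the nearest zero voxel.
// ---------------------------------------------------------------------------
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& vv, std::vector<double>& zz, int len) {
  int k = 0;
  vv[0] = 0;
  zz[0] = -1e30; zz[1] = 1e30;
  for (int q = 1; q < len; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[vv[k]] + (double)vv[k] * vv[k])) /
          (2.0 * q - 2.0 * vv[k]);
      if (s <= zz[k]) { --k; } else break;
    }
    ++k;
    vv[k] = q;
    zz[k] = s;
    zz[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < len; ++q) {
    while (zz[k + 1] < q) ++k;
    double dq = q - vv[k];
    d[q] = dq * dq + f[vv[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(IntegerVector mask, IntegerVector dims, double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const double INF = 1e30;
  std::vector<double> g(n);
  for (long i = 0; i < n; ++i) g[i] = mask[i] != 0 ? INF : 0.0;
  int maxlen = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxlen), d(maxlen), zz(maxlen + 1);
  std::vector<int> vv(maxlen);
  const long sy = nx, sz = (long)nx * ny;
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      long base = sy * j + sz * k;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, vv, zz, nx);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      long base = i + sz * k;
      for (int j = 0; j < ny; ++j) f[j] = g[base + sy * j];
      dt1d(f, d, vv, zz, ny);
      for (int j = 0; j < ny; ++j) g[base + sy * j] = d[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      long base = i + sy * j;
      for (int k = 0; k < nz; ++k) f[k] = g[base + sz * k];
      dt1d(f, d, vv, zz, nz);
      for (int k = 0; k < nz; ++k) g[base + sz * k] = d[k];
    }
  NumericVector out(n);
  for (long i = 0; i < n; ++i)
    out[i] = g[i] >= 1e29 ? R_PosInf : std::sqrt(g[i]) * spacing;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Largest 26-connected component of a binary mask.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_largest_cc(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const long sy = nx, sz = (long)nx * ny;
  std::vector<int> comp(n, 0);
  int ncomp = 0;
  long best_size = 0;
  int best_comp = 0;
  std::vector<long> stack;
  for (long seed = 0; seed < n; ++seed) {
    if (mask[seed] == 0 || comp[seed] != 0) continue;
    ++ncomp;
    long size = 0;
    stack.clear();
    stack.push_back(seed);
    comp[seed] = ncomp;
    while (!stack.empty()) {
      long cur = stack.back();
      stack.pop_back();
      ++size;
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / sz);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            long nb = ii + sy * jj + sz * kk;
            if (mask[nb] != 0 && comp[nb] == 0) {
              comp[nb] = ncomp;
              stack.push_back(nb);
            }
          }
    }
    if (size > best_size) { best_size = size; best_comp = ncomp; }
  }
  IntegerVector out(n);
  for (long i = 0; i < n; ++i) out[i] = comp[i] == best_comp && best_comp > 0 ? 1 : 0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Iterative patch transplantation (pattern generation).
// Randomly chosen w^3 donor patches are copied into randomly chosen fully
// unassigned w^3 sites inside the SOI for w = 5, then 3; remaining voxels
// are filled one by one (w = 1).  Site sampling is uniform rejection
// sampling; after `max_reject` consecutive rejections the remaining valid
// sites are enumerated exhaustively and consumed in random order, which
// guarantees termination with every voxel assigned exactly once.
// Uses the R RNG, so results are reproducible under set.seed().
// ---------------------------------------------------------------------------
static inline long iunif(long n) {  // uniform integer in [0, n-1]
  double u;
  do { u = unif_rand(); } while (u >= 1.0);
  return (long)(u * n);
}

// [[Rcpp::export]]
List cpp_pattern_fill(IntegerVector soi, IntegerVector dims,
                      NumericVector donor, IntegerVector donor_dims,
                      IntegerVector roi, int max_reject) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const long sy = nx, sz = (long)nx * ny;
  const int dnx = donor_dims[0], dny = donor_dims[1], dnz = donor_dims[2];
  const long dsy = dnx, dsz = (long)dnx * dny;
  const long dn = (long)dnx * dny * dnz;
  // donor ROI bounding box and voxel list
  int bx0 = dnx, bx1 = -1, by0 = dny, by1 = -1, bz0 = dnz, bz1 = -1;
  std::vector<long> roi_vox;
  for (long idx = 0; idx < dn; ++idx) {
    if (roi[idx] == 0) continue;
    int i = (int)(idx % dnx), j = (int)((idx / dnx) % dny), k = (int)(idx / dsz);
    bx0 = std::min(bx0, i); bx1 = std::max(bx1, i);
    by0 = std::min(by0, j); by1 = std::max(by1, j);
    bz0 = std::min(bz0, k); bz1 = std::max(bz1, k);
    roi_vox.push_back(idx);
  }
  if (roi_vox.empty()) stop("donor ROI is empty");
  // SOI bounding box
  int px0 = nx, px1 = -1, py0 = ny, py1 = -1, pz0 = nz, pz1 = -1;
  long n_soi = 0;
  for (long idx = 0; idx < n; ++idx) {
    if (soi[idx] == 0) continue;
    ++n_soi;
    int i = (int)(idx % nx), j = (int)((idx / nx) % ny), k = (int)(idx / sz);
    px0 = std::min(px0, i); px1 = std::max(px1, i);
    py0 = std::min(py0, j); py1 = std::max(py1, j);
    pz0 = std::min(pz0, k); pz1 = std::max(pz1, k);
  }
  if (n_soi == 0) stop("SOI is empty");

  NumericVector values(n);  // zero outside SOI
  std::vector<char> assigned(n, 0);
  std::vector<int> plc_w;
  std::vector<int> plc_site, plc_donor;  // 0-based corner linear indices

  auto site_valid = [&](int i, int j, int k, int w) -> bool {
    for (int dk = 0; dk < w; ++dk)
      for (int dj = 0; dj < w; ++dj) {
        long row = (long)i + sy * (j + dj) + sz * (k + dk);
        for (int di = 0; di < w; ++di) {
          long idx = row + di;
          if (soi[idx] == 0 || assigned[idx]) return false;
        }
      }
    return true;
  };
  auto donor_valid = [&](int i, int j, int k, int w) -> bool {
    for (int dk = 0; dk < w; ++dk)
      for (int dj = 0; dj < w; ++dj) {
        long row = (long)i + dsy * (j + dj) + dsz * (k + dk);
        for (int di = 0; di < w; ++di)
          if (roi[row + di] == 0) return false;
      }
    return true;
  };
  auto place = [&](int i, int j, int k, int w) {
    // draw a donor patch fully inside the ROI
    int di = 0, dj = 0, dk = 0;
    int rx = bx1 - bx0 - w + 2, ry = by1 - by0 - w + 2, rz = bz1 - bz0 - w + 2;
    if (rx < 1 || ry < 1 || rz < 1) stop("donor ROI smaller than patch");
    for (int tries = 0; ; ++tries) {
      if (tries > 100000) stop("could not draw a donor patch inside the ROI");
      di = bx0 + (int)iunif(rx);
      dj = by0 + (int)iunif(ry);
      dk = bz0 + (int)iunif(rz);
      if (donor_valid(di, dj, dk, w)) break;
    }
    for (int ck = 0; ck < w; ++ck)
      for (int cj = 0; cj < w; ++cj)
        for (int ci = 0; ci < w; ++ci) {
          long sidx = (long)(i + ci) + sy * (j + cj) + sz * (k + ck);
          long didx = (long)(di + ci) + dsy * (dj + cj) + dsz * (dk + ck);
          values[sidx] = donor[didx];
          assigned[sidx] = 1;
        }
    plc_w.push_back(w);
    plc_site.push_back((int)((long)i + sy * j + sz * k));
    plc_donor.push_back((int)((long)di + dsy * dj + dsz * dk));
  };

  for (int w : {5, 3}) {
    int rx = px1 - px0 - w + 2, ry = py1 - py0 - w + 2, rz = pz1 - pz0 - w + 2;
    if (rx < 1 || ry < 1 || rz < 1) continue;
    int rejections = 0;
    while (rejections < max_reject) {
      int i = px0 + (int)iunif(rx);
      int j = py0 + (int)iunif(ry);
      int k = pz0 + (int)iunif(rz);
      if (site_valid(i, j, k, w)) { place(i, j, k, w); rejections = 0; }
      else ++rejections;
    }
    // exhaustive verification: consume any remaining valid sites in random
    // order (revalidating at pick time, since placements overlap candidates)
    std::vector<long> sites;
    for (int k = pz0; k <= pz1 - w + 1; ++k)
      for (int j = py0; j <= py1 - w + 1; ++j)
        for (int i = px0; i <= px1 - w + 1; ++i)
          if (site_valid(i, j, k, w)) sites.push_back((long)i + sy * j + sz * k);
    while (!sites.empty()) {
      long pick = iunif((long)sites.size());
      long s = sites[pick];
      sites[pick] = sites.back();
      sites.pop_back();
      int i = (int)(s % nx), j = (int)((s / nx) % ny), k = (int)(s / sz);
      if (site_valid(i, j, k, w)) place(i, j, k, w);
    }
  }
  // w = 1: every remaining SOI voxel gets a random donor ROI voxel
  for (long idx = 0; idx < n; ++idx) {
    if (soi[idx] == 0 || assigned[idx]) continue;
    long d = roi_vox[iunif((long)roi_vox.size())];
    values[idx] = donor[d];
    assigned[idx] = 1;
    plc_w.push_back(1);
    plc_site.push_back((int)idx);
    plc_donor.push_back((int)d);
  }
  values.attr("dim") = dims;
  long n_assigned = 0;
  for (long idx = 0; idx < n; ++idx) if (assigned[idx]) ++n_assigned;
  return List::create(_["values"] = values,
                      _["n_assigned"] = (double)n_assigned,
                      _["patch_w"] = wrap(plc_w),
                      _["site_corner"] = wrap(plc_site),
                      _["donor_corner"] = wrap(plc_donor));
}

// ---------------------------------------------------------------------------
// Demons registration, single resolution level.
// Classic force  du = diff * grad(Mw) / (|grad|^2 + diff^2 + eps),
// computed in voxel units on the warped moving image, with fluid smoothing
// of the update and diffusion smoothing of the accumulated field.
// Field is backward (sampling M at x + u matches F), in millimetres.
// ---------------------------------------------------------------------------
static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int t = -r; t <= r; ++t) {
    k[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + r];
  }
  for (auto& v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
NumericVector cpp_demons_level(NumericVector fixedI, NumericVector movingI,
                               IntegerVector dims, double spacing, int iters,
                               double sigma_fluid, double sigma_diff,
                               double eps, NumericVector u0, int symmetric,
                               double gain) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const long sy = nx, sz = (long)nx * ny;
  const double* F = fixedI.begin();
  const double* M = movingI.begin();
  std::vector<double> ux(n, 0.0), uy(n, 0.0), uz(n, 0.0);
  if (u0.size() == 3 * n) {
    for (long i = 0; i < n; ++i) { ux[i] = u0[i]; uy[i] = u0[n + i]; uz[i] = u0[2 * n + i]; }
  }
  std::vector<double> Mw(n), dux(n), duy(n), duz(n), tmp(n);
  std::vector<double> kf = gauss_kernel(sigma_fluid);
  std::vector<double> kd = gauss_kernel(sigma_diff);
  const double cap = 2.0;  // max update per iteration, voxels
  for (int it = 0; it < iters; ++it) {
    long idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx)
          Mw[idx] = sample_trilinear_clamped(
              M, nx, ny, nz, i + ux[idx] / spacing, j + uy[idx] / spacing,
              k + uz[idx] / spacing);
    idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          int im = std::max(i - 1, 0), ip = std::min(i + 1, nx - 1);
          int jm = std::max(j - 1, 0), jp = std::min(j + 1, ny - 1);
          int km = std::max(k - 1, 0), kp = std::min(k + 1, nz - 1);
          double gx = (Mw[ip + sy * j + sz * k] - Mw[im + sy * j + sz * k]) / (ip - im);
          double gy = (Mw[i + sy * jp + sz * k] - Mw[i + sy * jm + sz * k]) / (jp - jm);
          double gz = (Mw[i + sy * j + sz * kp] - Mw[i + sy * j + sz * km]) / (kp - km);
          if (symmetric) {
            // symmetric force: average the warped-moving and fixed
            // gradients, which keeps the force alive once the interfaces
            // overlap and roughly doubles its magnitude
            gx = 0.5 * (gx + (F[ip + sy * j + sz * k] - F[im + sy * j + sz * k]) / (ip - im));
            gy = 0.5 * (gy + (F[i + sy * jp + sz * k] - F[i + sy * jm + sz * k]) / (jp - jm));
            gz = 0.5 * (gz + (F[i + sy * j + sz * kp] - F[i + sy * j + sz * km]) / (kp - km));
          }
          double diff = F[idx] - Mw[idx];
          double denom = gx * gx + gy * gy + gz * gz + diff * diff + eps;
          double fac = denom > eps ? gain * diff / denom : 0.0;
          double sx = fac * gx, syv = fac * gy, szv = fac * gz;
          double mag = std::sqrt(sx * sx + syv * syv + szv * szv);
          if (mag > cap) { sx *= cap / mag; syv *= cap / mag; szv *= cap / mag; }
          dux[idx] = sx; duy[idx] = syv; duz[idx] = szv;
        }
    conv_sep3(dux, tmp, nx, ny, nz, kf);
    conv_sep3(duy, tmp, nx, ny, nz, kf);
    conv_sep3(duz, tmp, nx, ny, nz, kf);
    for (long q = 0; q < n; ++q) {
      ux[q] += dux[q] * spacing;
      uy[q] += duy[q] * spacing;
      uz[q] += duz[q] * spacing;
    }
    conv_sep3(ux, tmp, nx, ny, nz, kd);
    conv_sep3(uy, tmp, nx, ny, nz, kd);
    conv_sep3(uz, tmp, nx, ny, nz, kd);
  }
  NumericVector out(3 * n);
  for (long i = 0; i < n; ++i) { out[i] = ux[i]; out[n + i] = uy[i]; out[2 * n + i] = uz[i]; }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return out;
}

// Trilinear resampling to a new grid size (align-corners mapping); used by
// the multiresolution pyramid.
// [[Rcpp::export]]
NumericVector cpp_resample_linear(NumericVector vol, IntegerVector dims,
                                  IntegerVector new_dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = new_dims[0], my = new_dims[1], mz = new_dims[2];
  const double* v = vol.begin();
  NumericVector out((long)mx * my * mz);
  double fx = mx > 1 ? (double)(nx - 1) / (mx - 1) : 0.0;
  double fy = my > 1 ? (double)(ny - 1) / (my - 1) : 0.0;
  double fz = mz > 1 ? (double)(nz - 1) / (mz - 1) : 0.0;
  long idx = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++idx)
        out[idx] = sample_trilinear_clamped(v, nx, ny, nz, i * fx, j * fy, k * fz);
  out.attr("dim") = new_dims;
  return out;
}
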