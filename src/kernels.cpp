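#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Volumes are R arrays in (z, y, x) order, column-major: linear index
// i + nz * (j + ny * k) for 0-based (i, j, k).

static inline int reflect_idx(int t, int n) {
  // symmetric reflection including the edge sample: d c b a | a b c d | d c b a
  if (n == 1) return 0;
  while (t < 0 || t >= n) {
    if (t < 0) t = -t - 1;
    if (t >= n) t = 2 * n - t - 1;
  }
  return t;
}

static inline int clampi(int t, int lo, int hi) {
  return t < lo ? lo : (t > hi ? hi : t);
}

// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector vol, IntegerVector dim, int hw) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(vol.size());
  if (hw <= 0) { std::copy(vol.begin(), vol.end(), out.begin()); return out; }
  const int w = 2 * hw + 1;
  std::vector<double> buf(w * w * w);
  for (int k = 0; k < nx; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nz; ++i) {
        int m = 0;
        for (int dk = -hw; dk <= hw; ++dk) {
          const int kk = reflect_idx(k + dk, nx);
          for (int dj = -hw; dj <= hw; ++dj) {
            const int jj = reflect_idx(j + dj, ny);
            const R_xlen_t base = (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk);
            for (int di = -hw; di <= hw; ++di)
              buf[m++] = vol[reflect_idx(i + di, nz) + base];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)] = buf[m / 2];
      }
    }
  }
  return out;
}

// Separable truncated Gaussian smoothing (radius 3*sigma), weights
// renormalized at the faces.  Spatial (not periodic): commutes exactly with
// integer shifts away from the boundary.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3(NumericVector vol, IntegerVector dim, double sigma) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> w(2 * r + 1);
  for (int t = -r; t <= r; ++t) w[t + r] = std::exp(-0.5 * t * t / (sigma * sigma));
  NumericVector a(vol.size());
  std::copy(vol.begin(), vol.end(), a.begin());
  NumericVector b(vol.size());
  const int n[3] = {nz, ny, nx};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  for (int ax = 0; ax < 3; ++ax) {
    const R_xlen_t st = stride[ax];
    const int len = n[ax];
    for (int k = 0; k < nx; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nz; ++i) {
          const int pos[3] = {i, j, k};
          const R_xlen_t idx = i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
          const int c = pos[ax];
          double acc = 0.0, wsum = 0.0;
          const int lo = std::max(-r, -c), hi = std::min(r, len - 1 - c);
          for (int t = lo; t <= hi; ++t) {
            acc += w[t + r] * a[idx + (R_xlen_t)t * st];
            wsum += w[t + r];
          }
          b[idx] = acc / wsum;
        }
    std::copy(b.begin(), b.end(), a.begin());
  }
  return a;
}

// Catmull-Rom (Keys a = -1/2) cubic convolution weights; interpolating.
static inline void cubic_w(double f, double w[4]) {
  const double f2 = f * f, f3 = f2 * f;
  w[0] = 0.5 * (-f3 + 2.0 * f2 - f);
  w[1] = 0.5 * (3.0 * f3 - 5.0 * f2 + 2.0);
  w[2] = 0.5 * (-3.0 * f3 + 4.0 * f2 + f);
  w[3] = 0.5 * (f3 - f2);
}

static inline double tricubic_at(const double* v, int nz, int ny, int nx,
                                 double z, double y, double x) {
  const int iz = (int)std::floor(z), iy = (int)std::floor(y), ix = (int)std::floor(x);
  double wz[4], wy[4], wx[4];
  cubic_w(z - iz, wz); cubic_w(y - iy, wy); cubic_w(x - ix, wx);
  double acc = 0.0;
  for (int c = 0; c < 4; ++c) {
    const int kk = clampi(ix - 1 + c, 0, nx - 1);
    double accy = 0.0;
    for (int b = 0; b < 4; ++b) {
      const int jj = clampi(iy - 1 + b, 0, ny - 1);
      const double* col = v + (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk);
      double accz = 0.0;
      for (int a = 0; a < 4; ++a)
        accz += wz[a] * col[clampi(iz - 1 + a, 0, nz - 1)];
      accy += wy[b] * accz;
    }
    acc += wx[c] * accy;
  }
  return acc;
}

// [[Rcpp::export]]
NumericVector cpp_tricubic_sample(NumericVector vol, IntegerVector dim,
                                  NumericMatrix coords) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double* v = vol.begin();
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p)
    out[p] = tricubic_at(v, nz, ny, nx, coords(p, 0), coords(p, 1), coords(p, 2));
  return out;
}

// --- cubic B-spline interpolation (Unser prefilter + kernel) ---
// Interpolates the original samples exactly at integer positions and has a
// much smaller lattice-periodic ("peak-locking") bias than cubic
// convolution, which matters for sub-voxel displacement refinement.

static void bspline_line(double* c, int n, R_xlen_t stride) {
  const double p = std::sqrt(3.0) - 2.0;
  const double lambda = 6.0;
  if (n == 1) { c[0] *= 1.0; return; }
  for (int i = 0; i < n; ++i) c[(R_xlen_t)i * stride] *= lambda;
  // causal init (mirror boundary, truncated series)
  int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::abs(p)));
  if (horizon > n) horizon = n;
  double sum = c[0];
  double zk = p;
  for (int k = 1; k < horizon; ++k) { sum += zk * c[(R_xlen_t)k * stride]; zk *= p; }
  double prev = sum;
  c[0] = sum;
  for (int i = 1; i < n; ++i) {
    prev = c[(R_xlen_t)i * stride] + p * prev;
    c[(R_xlen_t)i * stride] = prev;
  }
  // anticausal init
  double last = (p / (p * p - 1.0)) *
    (c[(R_xlen_t)(n - 1) * stride] + p * c[(R_xlen_t)(n - 2) * stride]);
  c[(R_xlen_t)(n - 1) * stride] = last;
  for (int i = n - 2; i >= 0; --i) {
    last = p * (last - c[(R_xlen_t)i * stride]);
    c[(R_xlen_t)i * stride] = last;
  }
}

// [[Rcpp::export]]
NumericVector cpp_bspline_coef3(NumericVector vol, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector c(vol.size());
  std::copy(vol.begin(), vol.end(), c.begin());
  double* v = c.begin();
  for (int k = 0; k < nx; ++k)
    for (int j = 0; j < ny; ++j)
      bspline_line(v + (R_xlen_t)nz * (j + (R_xlen_t)ny * k), nz, 1);
  for (int k = 0; k < nx; ++k)
    for (int i = 0; i < nz; ++i)
      bspline_line(v + i + (R_xlen_t)nz * (R_xlen_t)ny * k, ny, nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nz; ++i)
      bspline_line(v + i + (R_xlen_t)nz * j, nx, (R_xlen_t)nz * ny);
  return c;
}

static inline void bspline_w(double f, double w[4]) {
  // weights for taps floor(x)-1 .. floor(x)+2, f = frac(x)
  const double f2 = f * f, f3 = f2 * f;
  w[0] = (1.0 - 3.0 * f + 3.0 * f2 - f3) / 6.0;
  w[1] = (4.0 - 6.0 * f2 + 3.0 * f3) / 6.0;
  w[2] = (1.0 + 3.0 * f + 3.0 * f2 - 3.0 * f3) / 6.0;
  w[3] = f3 / 6.0;
}

static inline double bspline_at(const double* c, int nz, int ny, int nx,
                                double z, double y, double x) {
  const int iz = (int)std::floor(z), iy = (int)std::floor(y), ix = (int)std::floor(x);
  double wz[4], wy[4], wx[4];
  bspline_w(z - iz, wz); bspline_w(y - iy, wy); bspline_w(x - ix, wx);
  double acc = 0.0;
  for (int q = 0; q < 4; ++q) {
    const int kk = clampi(ix - 1 + q, 0, nx - 1);
    double accy = 0.0;
    for (int b = 0; b < 4; ++b) {
      const int jj = clampi(iy - 1 + b, 0, ny - 1);
      const double* col = c + (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk);
      double accz = 0.0;
      for (int a = 0; a < 4; ++a)
        accz += wz[a] * col[clampi(iz - 1 + a, 0, nz - 1)];
      accy += wy[b] * accz;
    }
    acc += wx[q] * accy;
  }
  return acc;
}

// ZNCC between the reference window around `node` and the deformed window at
// integer offset (oz, oy, ox).  refc: centered reference window values,
// refsd2: sum of squares of refc.  Returns -2 when undefined.
static double zncc_offset(const double* defv, int nz, int ny, int nx,
                          const std::vector<double>& refc, double refss,
                          int z0, int y0, int x0, int w,
                          int oz, int oy, int ox) {
  const int za = z0 + oz, ya = y0 + oy, xa = x0 + ox;
  if (za < 0 || ya < 0 || xa < 0 || za + w > nz || ya + w > ny || xa + w > nx)
    return -2.0;
  const int n = w * w * w;
  double sd = 0.0, sdd = 0.0, srd = 0.0;
  int m = 0;
  for (int k = 0; k < w; ++k) {
    for (int j = 0; j < w; ++j) {
      const double* col = defv + (za + (R_xlen_t)nz * ((ya + j) + (R_xlen_t)ny * (xa + k)));
      for (int i = 0; i < w; ++i) {
        const double d = col[i];
        sd += d; sdd += d * d; srd += refc[m++] * d;
      }
    }
  }
  const double vard = sdd - sd * sd / n;
  if (vard <= 0.0 || refss <= 0.0) return -2.0;
  // refc is centered so sum(refc) = 0 and cov = srd
  return srd / std::sqrt(refss * vard);
}

// Integer ZNCC search over [-sr, sr]^3 with tie-break smallest |u| then
// lexicographic (z, y, x); also returns the 3x3x3 cc cube around the best.
// [[Rcpp::export]]
List cpp_zncc_search(NumericVector ref, NumericVector def, IntegerVector dim,
                     IntegerVector node, int cw, int sr) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int w = 2 * cw + 1, n = w * w * w;
  const int z0 = node[0] - cw, y0 = node[1] - cw, x0 = node[2] - cw;
  List fail = List::create(_["ok"] = false, _["u"] = IntegerVector::create(0, 0, 0),
                           _["cc"] = NA_REAL, _["cube"] = NumericVector(27, NA_REAL));
  if (z0 < 0 || y0 < 0 || x0 < 0 || z0 + w > nz || y0 + w > ny || x0 + w > nx)
    return fail;
  // centered reference window
  std::vector<double> refc(n);
  const double* rv = ref.begin();
  double sr_ = 0.0;
  int m = 0;
  for (int k = 0; k < w; ++k)
    for (int j = 0; j < w; ++j) {
      const double* col = rv + (z0 + (R_xlen_t)nz * ((y0 + j) + (R_xlen_t)ny * (x0 + k)));
      for (int i = 0; i < w; ++i) { refc[m++] = col[i]; sr_ += col[i]; }
    }
  const double mr = sr_ / n;
  double refss = 0.0;
  for (int t = 0; t < n; ++t) { refc[t] -= mr; refss += refc[t] * refc[t]; }
  if (refss <= 0.0) return fail;

  const double* dv = def.begin();
  double best = -3.0;
  int bz = 0, by = 0, bx = 0;
  long bestd2 = 0;
  bool any = false;
  for (int oz = -sr; oz <= sr; ++oz)
    for (int oy = -sr; oy <= sr; ++oy)
      for (int ox = -sr; ox <= sr; ++ox) {
        const double cc = zncc_offset(dv, nz, ny, nx, refc, refss,
                                      z0, y0, x0, w, oz, oy, ox);
        if (cc <= -2.0) continue;
        const long d2 = (long)oz * oz + (long)oy * oy + (long)ox * ox;
        bool take = false;
        if (!any || cc > best) take = true;
        else if (cc == best) {
          if (d2 < bestd2) take = true;
          else if (d2 == bestd2) {
            if (oz < bz || (oz == bz && (oy < by || (oy == by && ox < bx)))) take = true;
          }
        }
        if (take) { any = true; best = cc; bz = oz; by = oy; bx = ox; bestd2 = d2; }
      }
  if (!any) return fail;
  NumericVector cube(27);
  int q = 0;
  for (int ox = -1; ox <= 1; ++ox)
    for (int oy = -1; oy <= 1; ++oy)
      for (int oz = -1; oz <= 1; ++oz) {
        const double cc = zncc_offset(dv, nz, ny, nx, refc, refss, z0, y0, x0, w,
                                      bz + oz, by + oy, bx + ox);
        cube[q++] = (cc <= -2.0) ? NA_REAL : cc;
      }
  cube.attr("dim") = IntegerVector::create(3, 3, 3);
  return List::create(_["ok"] = true,
                      _["u"] = IntegerVector::create(bz, by, bx),
                      _["cc"] = best, _["cube"] = cube);
}

// ZNCC at a continuous displacement u: deformed window resampled by cubic
// B-spline interpolation from precomputed coefficients (cpp_bspline_coef3).
// [[Rcpp::export]]
double cpp_zncc_subvoxel(NumericVector ref, NumericVector def_coef,
                         IntegerVector dim, IntegerVector node, int cw,
                         NumericVector u) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int w = 2 * cw + 1, n = w * w * w;
  const int z0 = node[0] - cw, y0 = node[1] - cw, x0 = node[2] - cw;
  if (z0 < 0 || y0 < 0 || x0 < 0 || z0 + w > nz || y0 + w > ny || x0 + w > nx)
    return NA_REAL;
  const double* rv = ref.begin();
  const double* dv = def_coef.begin();
  double srr = 0.0, sdd = 0.0, srd = 0.0, sr_ = 0.0, sd_ = 0.0;
  for (int k = 0; k < w; ++k)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < w; ++i) {
        const double r = rv[(z0 + i) + (R_xlen_t)nz * ((y0 + j) + (R_xlen_t)ny * (x0 + k))];
        const double d = bspline_at(dv, nz, ny, nx,
                                    z0 + i + u[0], y0 + j + u[1], x0 + k + u[2]);
        sr_ += r; sd_ += d; srr += r * r; sdd += d * d; srd += r * d;
      }
  const double varr = srr - sr_ * sr_ / n;
  const double vard = sdd - sd_ * sd_ / n;
  if (varr <= 0.0 || vard <= 0.0) return NA_REAL;
  return (srd - sr_ * sd_ / n) / std::sqrt(varr * vard);
}

// Sample a (2cw+1)^3 window of the B-spline coefficient volume at a uniform
// fractional displacement u via separable 4-tap convolution; then ZNCC with
// the centered reference window.  refc/refss as in zncc_offset.
static double zncc_bspline_window(const double* dv, int nz, int ny, int nx,
                                  const std::vector<double>& refc, double refss,
                                  int z0, int y0, int x0, int w,
                                  double uz, double uy, double ux,
                                  std::vector<double>& bufA,
                                  std::vector<double>& bufB) {
  const int wp = w + 3;
  const int zb = (int)std::floor(z0 + uz) - 1;
  const int yb = (int)std::floor(y0 + uy) - 1;
  const int xb = (int)std::floor(x0 + ux) - 1;
  double wz[4], wy[4], wx[4];
  bspline_w(z0 + uz - std::floor(z0 + uz), wz);
  bspline_w(y0 + uy - std::floor(y0 + uy), wy);
  bspline_w(x0 + ux - std::floor(x0 + ux), wx);
  // gather block (wp^3) with clamping, convolve along z -> (w, wp, wp)
  bufA.assign((size_t)w * wp * wp, 0.0);
  for (int k = 0; k < wp; ++k) {
    const int kk = clampi(xb + k, 0, nx - 1);
    for (int j = 0; j < wp; ++j) {
      const int jj = clampi(yb + j, 0, ny - 1);
      const double* col = dv + (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk);
      for (int i = 0; i < w; ++i) {
        double acc = 0.0;
        for (int a = 0; a < 4; ++a)
          acc += wz[a] * col[clampi(zb + i + a, 0, nz - 1)];
        bufA[(size_t)i + (size_t)w * (j + (size_t)wp * k)] = acc;
      }
    }
  }
  // convolve along y -> (w, w, wp)
  bufB.assign((size_t)w * w * wp, 0.0);
  for (int k = 0; k < wp; ++k)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < w; ++i) {
        double acc = 0.0;
        for (int b = 0; b < 4; ++b)
          acc += wy[b] * bufA[(size_t)i + (size_t)w * ((j + b) + (size_t)wp * k)];
        bufB[(size_t)i + (size_t)w * (j + (size_t)w * k)] = acc;
      }
  // convolve along x and accumulate ZNCC sums
  const int n = w * w * w;
  double sd = 0.0, sdd = 0.0, srd = 0.0;
  int m = 0;
  for (int k = 0; k < w; ++k)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < w; ++i) {
        double acc = 0.0;
        for (int c = 0; c < 4; ++c)
          acc += wx[c] * bufB[(size_t)i + (size_t)w * (j + (size_t)w * (k + c))];
        sd += acc; sdd += acc * acc; srd += refc[m++] * acc;
      }
  const double vard = sdd - sd * sd / n;
  if (vard <= 0.0 || refss <= 0.0) return -2.0;
  return srd / std::sqrt(refss * vard);
}

// Sub-voxel ZNCC refinement: per-axis parabolic ascent on the B-spline
// resampled correlation, bounded to +/-1 voxel around the integer optimum.
// Returns the best displacement found and its CC.
// [[Rcpp::export]]
List cpp_subpixel_refine(NumericVector ref, NumericVector def_coef,
                         IntegerVector dim, IntegerVector node, int cw,
                         IntegerVector u0, NumericVector start) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int w = 2 * cw + 1, n = w * w * w;
  const int z0 = node[0] - cw, y0 = node[1] - cw, x0 = node[2] - cw;
  List fail = List::create(_["u"] = NumericVector::create(u0[0], u0[1], u0[2]),
                           _["cc"] = NA_REAL);
  if (z0 < 0 || y0 < 0 || x0 < 0 || z0 + w > nz || y0 + w > ny || x0 + w > nx)
    return fail;
  std::vector<double> refc(n);
  const double* rv = ref.begin();
  double sr_ = 0.0;
  int m = 0;
  for (int k = 0; k < w; ++k)
    for (int j = 0; j < w; ++j) {
      const double* col = rv + (z0 + (R_xlen_t)nz * ((y0 + j) + (R_xlen_t)ny * (x0 + k)));
      for (int i = 0; i < w; ++i) { refc[m++] = col[i]; sr_ += col[i]; }
    }
  const double mr = sr_ / n;
  double refss = 0.0;
  for (int t = 0; t < n; ++t) { refc[t] -= mr; refss += refc[t] * refc[t]; }
  if (refss <= 0.0) return fail;

  std::vector<double> bufA, bufB;
  const double* dv = def_coef.begin();
  double lo[3] = {(double)u0[0] - 1, (double)u0[1] - 1, (double)u0[2] - 1};
  double hi[3] = {(double)u0[0] + 1, (double)u0[1] + 1, (double)u0[2] + 1};
  double p[3];
  for (int a = 0; a < 3; ++a)
    p[a] = std::min(hi[a], std::max(lo[a], (double)start[a]));
  auto eval = [&](const double q[3]) {
    return zncc_bspline_window(dv, nz, ny, nx, refc, refss, z0, y0, x0, w,
                               q[0], q[1], q[2], bufA, bufB);
  };
  double fc = eval(p);
  if (fc <= -2.0) return fail;
  double best[3] = {p[0], p[1], p[2]};
  double fbest = fc;
  double h = 0.5;
  for (int sweep = 0; sweep < 8; ++sweep) {
    for (int a = 0; a < 3; ++a) {
      double qm[3] = {p[0], p[1], p[2]};
      double qp[3] = {p[0], p[1], p[2]};
      qm[a] = std::max(lo[a], p[a] - h);
      qp[a] = std::min(hi[a], p[a] + h);
      const double fm = eval(qm), fp = eval(qp);
      if (fm > fbest) { fbest = fm; best[0] = qm[0]; best[1] = qm[1]; best[2] = qm[2]; }
      if (fp > fbest) { fbest = fp; best[0] = qp[0]; best[1] = qp[1]; best[2] = qp[2]; }
      // parabola through (p-h, p, p+h); step clamped to [-h, h]
      const double denom = fm - 2.0 * fc + fp;
      double step;
      if (denom < -1e-15) step = 0.5 * h * (fm - fp) / denom;
      else step = (fp > fm) ? h : -h;
      if (step > h) step = h;
      if (step < -h) step = -h;
      const double pa = std::min(hi[a], std::max(lo[a], p[a] + step));
      if (pa != p[a]) {
        p[a] = pa;
        fc = eval(p);
        if (fc > fbest) { fbest = fc; best[0] = p[0]; best[1] = p[1]; best[2] = p[2]; }
      }
    }
    h *= 0.45;
    if (h < 5e-4) break;
  }
  return List::create(_["u"] = NumericVector::create(best[0], best[1], best[2]),
                      _["cc"] = fbest);
}

// Felzenszwalb-Huttenlocher 1D squared distance transform.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& vtx, std::vector<double>& zb, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  vtx[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k == 0 && f[vtx[0]] == INF) { vtx[0] = q; continue; }
    double s;
    while (true) {
      const int p = vtx[k];
      s = ((f[q] + q * q) - (f[p] + p * p)) / (2.0 * q - 2.0 * p);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; vtx[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    if (f[vtx[0]] == INF) { d[q] = INF; continue; }
    while (zb[kk + 1] < q) ++kk;
    const int p = vtx[kk];
    d[q] = (double)(q - p) * (q - p) + f[p];
  }
}

// Squared Euclidean distance (voxel units) from every voxel to the nearest
// feature (true) voxel; Inf when no feature exists.
// [[Rcpp::export]]
NumericVector cpp_edt2(LogicalVector feature, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector g(feature.size());
  for (R_xlen_t t = 0; t < feature.size(); ++t) g[t] = feature[t] ? 0.0 : INF;
  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> vtx(nmax);
  // along z
  for (int k = 0; k < nx; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nz; ++i) f[i] = g[base + i];
      dt1d(f, d, vtx, zb, nz);
      for (int i = 0; i < nz; ++i) g[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nx; ++k)
    for (int i = 0; i < nz; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, vtx, zb, ny);
      for (int j = 0; j < ny; ++j) g[i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)] = d[j];
    }
  // along x
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nz; ++i) {
      for (int k = 0; k < nx; ++k) f[k] = g[i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, vtx, zb, nx);
      for (int k = 0; k < nx; ++k) g[i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)] = d[k];
    }
  return g;
}

// Connected-component labels (0 = background), connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<int> nb;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        const int man = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && man > 1) continue;
        nb.push_back(di); nb.push_back(dj); nb.push_back(dk);
      }
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t t = stack.back(); stack.pop_back();
      const int i = (int)(t % nz), j = (int)((t / nz) % ny), k = (int)(t / ((R_xlen_t)nz * ny));
      for (size_t q = 0; q < nb.size(); q += 3) {
        const int ii = i + nb[q], jj = j + nb[q + 1], kk = k + nb[q + 2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nz || jj >= ny || kk >= nx) continue;
        const R_xlen_t tt = ii + (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk);
        if (mask[tt] && lab[tt] == 0) { lab[tt] = next; stack.push_back(tt); }
      }
    }
  }
  return lab;
}

// Local thickness by sphere marking (Hildebrand-Ruegsegger): each bone voxel
// carries the diameter 2*r of the largest sphere {x : d(x, c) < r} fully in
// bone that contains it, r = center-to-center distance to nearest background.
// exact = false prunes centers already covered by an equal-or-larger sphere.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector bone, IntegerVector dim, bool exact) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  LogicalVector bg(bone.size());
  for (R_xlen_t t = 0; t < bone.size(); ++t) bg[t] = !bone[t];
  NumericVector r2 = cpp_edt2(bg, dim);
  NumericVector th(bone.size(), 0.0);
  struct Cand { double r2; R_xlen_t idx; };
  std::vector<Cand> cands;
  for (R_xlen_t t = 0; t < bone.size(); ++t)
    if (bone[t] && std::isfinite(r2[t])) cands.push_back({r2[t], t});
  std::sort(cands.begin(), cands.end(),
            [](const Cand& a, const Cand& b) { return a.r2 > b.r2; });
  for (const Cand& c : cands) {
    const double rc = std::sqrt(c.r2);
    const double dia = 2.0 * rc;
    if (!exact && th[c.idx] >= dia) continue;
    const int i = (int)(c.idx % nz), j = (int)((c.idx / nz) % ny),
              k = (int)(c.idx / ((R_xlen_t)nz * ny));
    const int rr = (int)std::ceil(rc) ;
    for (int dk = -rr; dk <= rr; ++dk) {
      const int kk = k + dk;
      if (kk < 0 || kk >= nx) continue;
      for (int dj = -rr; dj <= rr; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        const double d2yx = (double)dk * dk + (double)dj * dj;
        if (d2yx >= c.r2) continue;
        for (int di = -rr; di <= rr; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nz) continue;
          if (d2yx + (double)di * di >= c.r2) continue;  // strict d < r
          const R_xlen_t t = ii + (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk);
          if (th[t] < dia) th[t] = dia;
        }
      }
    }
  }
  return th;
}
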