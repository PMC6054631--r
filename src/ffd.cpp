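#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cubic B-spline basis on [0,1): weights for control points i-1..i+2.
static inline void bspline_weights(double t, double w[4]) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (3 * t3 - 6 * t2 + 4) / 6.0;
  w[2] = (-3 * t3 + 3 * t2 + 3 * t + 1) / 6.0;
  w[3] = t3 / 6.0;
}

// Cubic B-spline Parzen kernel (support |s| < 2) and its derivative.
static inline double beta3(double s) {
  s = std::fabs(s);
  if (s < 1.0) return (4.0 - 6.0 * s * s + 3.0 * s * s * s) / 6.0;
  if (s < 2.0) { double u = 2.0 - s; return u * u * u / 6.0; }
  return 0.0;
}
static inline double beta3d(double s) {
  double a = std::fabs(s), sgn = (s < 0) ? -1.0 : 1.0;
  if (a < 1.0) return sgn * (-2.0 * a + 1.5 * a * a);
  if (a < 2.0) { double u = 2.0 - a; return sgn * (-0.5 * u * u); }
  return 0.0;
}

struct FFD {
  double ox, oy, sx, sy;
  int ncx, ncy;
  const double *cx, *cy;
  // displacement at world (x, y); returns false when outside support
  bool displace(double x, double y, double &ux, double &uy) const {
    double u = (x - ox) / sx, v = (y - oy) / sy;
    const double eps = 1e-9;
    if (u < 1.0) { if (u < 1.0 - eps) return false; u = 1.0; }
    if (u > ncx - 2.0) { if (u > ncx - 2.0 + eps) return false; u = ncx - 2.0; }
    if (v < 1.0) { if (v < 1.0 - eps) return false; v = 1.0; }
    if (v > ncy - 2.0) { if (v > ncy - 2.0 + eps) return false; v = ncy - 2.0; }
    int iu = (int)std::floor(u), iv = (int)std::floor(v);
    if (iu > ncx - 3) iu = ncx - 3;
    if (iv > ncy - 3) iv = ncy - 3;
    double wu[4], wv[4];
    bspline_weights(u - iu, wu);
    bspline_weights(v - iv, wv);
    ux = 0.0; uy = 0.0;
    for (int b = 0; b < 4; ++b) {
      int jc = iv - 1 + b;
      for (int a = 0; a < 4; ++a) {
        int ic = iu - 1 + a;
        double w = wu[a] * wv[b];
        ux += w * cx[ic + jc * ncx];
        uy += w * cy[ic + jc * ncx];
      }
    }
    return true;
  }
};

static FFD make_ffd(NumericVector t_origin, NumericVector t_spacing,
                    NumericMatrix coef_x, NumericMatrix coef_y) {
  FFD f;
  f.ox = t_origin[0]; f.oy = t_origin[1];
  f.sx = t_spacing[0]; f.sy = t_spacing[1];
  f.ncx = coef_x.nrow(); f.ncy = coef_x.ncol();
  f.cx = coef_x.begin(); f.cy = coef_y.begin();
  return f;
}

// [[Rcpp::export]]
NumericMatrix cpp_bspline_displace(NumericMatrix pts, NumericVector t_origin,
                                   NumericVector t_spacing,
                                   NumericMatrix coef_x, NumericMatrix coef_y) {
  FFD f = make_ffd(t_origin, t_spacing, coef_x, coef_y);
  int n = pts.nrow();
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    double ux, uy;
    if (!f.displace(pts(i, 0), pts(i, 1), ux, uy))
      stop("point %d (%.4g, %.4g) mm is outside the transform support",
           i + 1, pts(i, 0), pts(i, 1));
    out(i, 0) = pts(i, 0) + ux;
    out(i, 1) = pts(i, 1) + uy;
  }
  return out;
}

// bilinear interpolation at continuous 0-based pixel coords (x=col, y=row);
// returns false outside the image
static inline bool interp_linear(const double *img, int H, int W,
                                 double x, double y, double &val) {
  if (x < 0 || y < 0 || x > W - 1 || y > H - 1) return false;
  int j = (int)std::floor(x), i = (int)std::floor(y);
  if (j >= W - 1) j = W - 2;
  if (i >= H - 1) i = H - 2;
  double tx = x - j, ty = y - i;
  double v00 = img[i + j * H], v10 = img[i + (j + 1) * H];
  double v01 = img[i + 1 + j * H], v11 = img[i + 1 + (j + 1) * H];
  val = (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
        (1 - tx) * ty * v01 + tx * ty * v11;
  return true;
}

// gradient (per pixel unit) of the bilinear interpolant
static inline void interp_grad(const double *img, int H, int W,
                               double x, double y, double &gx, double &gy) {
  int j = (int)std::floor(x), i = (int)std::floor(y);
  if (j < 0) j = 0; if (i < 0) i = 0;
  if (j >= W - 1) j = W - 2;
  if (i >= H - 1) i = H - 2;
  double tx = x - j, ty = y - i;
  double v00 = img[i + j * H], v10 = img[i + (j + 1) * H];
  double v01 = img[i + 1 + j * H], v11 = img[i + 1 + (j + 1) * H];
  gx = (1 - ty) * (v10 - v00) + ty * (v11 - v01);
  gy = (1 - tx) * (v01 - v00) + tx * (v11 - v10);
}

// Keys cubic convolution kernel (a = -0.5)
static inline double keys(double s) {
  s = std::fabs(s);
  if (s < 1.0) return 1.5 * s * s * s - 2.5 * s * s + 1.0;
  if (s < 2.0) return -0.5 * s * s * s + 2.5 * s * s - 4.0 * s + 2.0;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double interp_cubic(const double *img, int H, int W,
                                  double x, double y) {
  int j = (int)std::floor(x), i = (int)std::floor(y);
  double acc = 0.0;
  for (int b = -1; b <= 2; ++b) {
    double wy = keys(y - (i + b));
    if (wy == 0.0) continue;
    int ii = clampi(i + b, 0, H - 1);
    for (int a = -1; a <= 2; ++a) {
      double wx = keys(x - (j + a));
      if (wx == 0.0) continue;
      int jj = clampi(j + a, 0, W - 1);
      acc += wx * wy * img[ii + jj * H];
    }
  }
  return acc;
}

// Resample `img` through the FFD: out(p) = img(p + u(p)), cubic
// interpolation, replicate border; out-of-image targets clamp to border.
// [[Rcpp::export]]
NumericMatrix cpp_warp_image(NumericMatrix img, NumericVector i_origin,
                             NumericVector i_spacing, NumericVector t_origin,
                             NumericVector t_spacing, NumericMatrix coef_x,
                             NumericMatrix coef_y) {
  FFD f = make_ffd(t_origin, t_spacing, coef_x, coef_y);
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    double x = i_origin[0] + j * i_spacing[0];
    for (int i = 0; i < H; ++i) {
      double y = i_origin[1] + i * i_spacing[1];
      double ux = 0.0, uy = 0.0;
      f.displace(x, y, ux, uy);  // outside support: identity (ux=uy=0)
      double xp = (x + ux - i_origin[0]) / i_spacing[0];
      double yp = (y + uy - i_origin[1]) / i_spacing[1];
      if (xp < 0) xp = 0; if (xp > W - 1) xp = W - 1;
      if (yp < 0) yp = 0; if (yp > H - 1) yp = H - 1;
      out(i, j) = interp_cubic(img.begin(), H, W, xp, yp);
    }
  }
  return out;
}

// Resample so the CONTENT moves by the transform: out(T(q)) = img(q),
// i.e. out(p) = img(T^{-1}(p)) with T^{-1} found by fixed-point iteration
// (converges for the moderate displacements used here). Cubic sampling.
// [[Rcpp::export]]
NumericMatrix cpp_warp_image_forward(NumericMatrix img, NumericVector i_origin,
                                     NumericVector i_spacing,
                                     NumericVector t_origin,
                                     NumericVector t_spacing,
                                     NumericMatrix coef_x,
                                     NumericMatrix coef_y) {
  FFD f = make_ffd(t_origin, t_spacing, coef_x, coef_y);
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    double x = i_origin[0] + j * i_spacing[0];
    for (int i = 0; i < H; ++i) {
      double y = i_origin[1] + i * i_spacing[1];
      double qx = x, qy = y;
      for (int it = 0; it < 25; ++it) {
        double ux = 0.0, uy = 0.0;
        f.displace(qx, qy, ux, uy);
        double nx = x - ux, ny = y - uy;
        if (std::fabs(nx - qx) < 1e-12 && std::fabs(ny - qy) < 1e-12) {
          qx = nx; qy = ny; break;
        }
        qx = nx; qy = ny;
      }
      double xp = (qx - i_origin[0]) / i_spacing[0];
      double yp = (qy - i_origin[1]) / i_spacing[1];
      if (xp < 0) xp = 0; if (xp > W - 1) xp = W - 1;
      if (yp < 0) yp = 0; if (yp > H - 1) yp = H - 1;
      out(i, j) = interp_cubic(img.begin(), H, W, xp, yp);
    }
  }
  return out;
}

// Hard-binned mutual information (bits) from samples given in world mm.
// Linear binning over the min-max of the retained sampled intensities.
// Returns MI, the marginal entropies, and the retained sample count.
// [[Rcpp::export]]
List cpp_mi_hard(NumericMatrix fixed, NumericMatrix moving,
                 NumericVector i_origin, NumericVector i_spacing,
                 NumericMatrix pts, int bins,
                 Nullable<NumericMatrix> coef_x_, Nullable<NumericMatrix> coef_y_,
                 Nullable<NumericVector> t_origin_, Nullable<NumericVector> t_spacing_) {
  int H = fixed.nrow(), W = fixed.ncol();
  bool has_t = coef_x_.isNotNull();
  NumericMatrix cx, cy;
  NumericVector to, ts;
  FFD f;
  if (has_t) {
    cx = as<NumericMatrix>(coef_x_); cy = as<NumericMatrix>(coef_y_);
    to = as<NumericVector>(t_origin_); ts = as<NumericVector>(t_spacing_);
    f = make_ffd(to, ts, cx, cy);
  }
  int n = pts.nrow();
  std::vector<double> fv, mv;
  fv.reserve(n); mv.reserve(n);
  for (int k = 0; k < n; ++k) {
    double x = pts(k, 0), y = pts(k, 1);
    double fx = (x - i_origin[0]) / i_spacing[0];
    double fy = (y - i_origin[1]) / i_spacing[1];
    double fval;
    if (!interp_linear(fixed.begin(), H, W, fx, fy, fval)) continue;
    double ux = 0.0, uy = 0.0;
    if (has_t && !f.displace(x, y, ux, uy)) continue;
    double mx = (x + ux - i_origin[0]) / i_spacing[0];
    double my = (y + uy - i_origin[1]) / i_spacing[1];
    double mval;
    if (!interp_linear(moving.begin(), H, W, mx, my, mval)) continue;
    fv.push_back(fval); mv.push_back(mval);
  }
  int m = (int)fv.size();
  if (m < 2) return List::create(_["mi"] = 0.0, _["h_fixed"] = 0.0,
                                 _["h_moving"] = 0.0, _["n_eff"] = m);
  double flo = fv[0], fhi = fv[0], mlo = mv[0], mhi = mv[0];
  for (int k = 1; k < m; ++k) {
    if (fv[k] < flo) flo = fv[k];
    if (fv[k] > fhi) fhi = fv[k];
    if (mv[k] < mlo) mlo = mv[k];
    if (mv[k] > mhi) mhi = mv[k];
  }
  // a range at floating-point rounding scale is degenerate (interpolating
  // a constant image yields values differing by ~1e-15)
  double feps = 1e-12 * std::max(std::fabs(fhi), std::max(std::fabs(flo), 1.0));
  double meps = 1e-12 * std::max(std::fabs(mhi), std::max(std::fabs(mlo), 1.0));
  if (fhi - flo <= feps || mhi - mlo <= meps)
    return List::create(_["mi"] = 0.0, _["h_fixed"] = 0.0,
                        _["h_moving"] = 0.0, _["n_eff"] = m);
  std::vector<double> joint(bins * bins, 0.0);
  for (int k = 0; k < m; ++k) {
    int bf = (int)((fv[k] - flo) / (fhi - flo) * bins);
    int bm = (int)((mv[k] - mlo) / (mhi - mlo) * bins);
    if (bf >= bins) bf = bins - 1;
    if (bm >= bins) bm = bins - 1;
    joint[bf + bm * bins] += 1.0;
  }
  std::vector<double> pf(bins, 0.0), pm(bins, 0.0);
  for (int b = 0; b < bins; ++b)
    for (int a = 0; a < bins; ++a) {
      double p = joint[a + b * bins] / m;
      pf[a] += p; pm[b] += p;
    }
  double mi = 0.0, hf = 0.0, hm = 0.0;
  const double l2 = std::log(2.0);
  for (int a = 0; a < bins; ++a) if (pf[a] > 0) hf -= pf[a] * std::log(pf[a]) / l2;
  for (int b = 0; b < bins; ++b) if (pm[b] > 0) hm -= pm[b] * std::log(pm[b]) / l2;
  for (int b = 0; b < bins; ++b)
    for (int a = 0; a < bins; ++a) {
      double p = joint[a + b * bins] / m;
      if (p > 0) mi += p * std::log(p / (pf[a] * pm[b])) / l2;
    }
  return List::create(_["mi"] = mi, _["h_fixed"] = hf, _["h_moving"] = hm,
                      _["n_eff"] = m);
}

// ---- Parzen-window MI (nats) used by the optimizer ---------------------

struct ParzenMI {
  const double *fixed, *moving;
  int H, W, bins;
  double iox, ioy, isx, isy;
  double flo, fsc, mlo, msc;  // intensity -> bin-coordinate mapping

  void set_ranges(NumericMatrix f, NumericMatrix m) {
    double f0 = f[0], f1 = f[0], m0 = m[0], m1 = m[0];
    int n = H * W;
    for (int k = 1; k < n; ++k) {
      if (f[k] < f0) f0 = f[k];
      if (f[k] > f1) f1 = f[k];
      if (m[k] < m0) m0 = m[k];
      if (m[k] > m1) m1 = m[k];
    }
    double fe = 1e-12 * std::max(std::fabs(f1), std::max(std::fabs(f0), 1.0));
    double me = 1e-12 * std::max(std::fabs(m1), std::max(std::fabs(m0), 1.0));
    flo = f0; fsc = (f1 - f0 > fe) ? (bins - 1e-9) / (f1 - f0) : 0.0;
    mlo = m0; msc = (m1 - m0 > me) ? (bins - 3.0) / (m1 - m0) : 0.0;
  }
  int fixed_bin(double v) const {
    int b = (int)((v - flo) * fsc);
    return b < 0 ? 0 : (b >= bins ? bins - 1 : b);
  }
  // continuous moving bin coordinate, clamped so the 4-bin window fits
  double moving_coord(double v) const {
    double u = 1.0 + (v - mlo) * msc;
    if (u < 1.0) u = 1.0;
    if (u > bins - 2.0) u = bins - 2.0;
    return u;
  }
};

// Parzen MI value at given world sample points under an FFD.
// [[Rcpp::export]]
double cpp_mi_parzen(NumericMatrix fixed, NumericMatrix moving,
                     NumericVector i_origin, NumericVector i_spacing,
                     NumericMatrix pts, int bins,
                     NumericMatrix coef_x, NumericMatrix coef_y,
                     NumericVector t_origin, NumericVector t_spacing) {
  FFD f = make_ffd(t_origin, t_spacing, coef_x, coef_y);
  ParzenMI pz;
  pz.fixed = fixed.begin(); pz.moving = moving.begin();
  pz.H = fixed.nrow(); pz.W = fixed.ncol(); pz.bins = bins;
  pz.iox = i_origin[0]; pz.ioy = i_origin[1];
  pz.isx = i_spacing[0]; pz.isy = i_spacing[1];
  pz.set_ranges(fixed, moving);
  if (pz.fsc == 0.0 || pz.msc == 0.0) return 0.0;
  std::vector<double> joint(bins * bins, 0.0);
  int n = pts.nrow(), m = 0;
  for (int k = 0; k < n; ++k) {
    double x = pts(k, 0), y = pts(k, 1);
    double fval;
    if (!interp_linear(pz.fixed, pz.H, pz.W, (x - pz.iox) / pz.isx,
                       (y - pz.ioy) / pz.isy, fval)) continue;
    double ux, uy;
    if (!f.displace(x, y, ux, uy)) continue;
    double mval;
    if (!interp_linear(pz.moving, pz.H, pz.W, (x + ux - pz.iox) / pz.isx,
                       (y + uy - pz.ioy) / pz.isy, mval)) continue;
    int bf = pz.fixed_bin(fval);
    double um = pz.moving_coord(mval);
    int j0 = (int)std::floor(um);
    for (int b = -1; b <= 2; ++b)
      joint[bf + (j0 + b) * bins] += beta3(um - (j0 + b));
    ++m;
  }
  if (m < 2) return 0.0;
  std::vector<double> pf(bins, 0.0), pmarg(bins, 0.0);
  for (int b = 0; b < bins; ++b)
    for (int a = 0; a < bins; ++a) {
      double p = joint[a + b * bins] / m;
      pf[a] += p; pmarg[b] += p;
    }
  double mi = 0.0;
  for (int b = 0; b < bins; ++b)
    for (int a = 0; a < bins; ++a) {
      double p = joint[a + b * bins] / m;
      if (p > 1e-300) mi += p * std::log(p / (pf[a] * pmarg[b]));
    }
  return mi;
}

// Parzen MI value and analytic gradient wrt coefficients at fixed sample
// points (deterministic; used for gradient verification and debugging).
// [[Rcpp::export]]
List cpp_mi_parzen_grad(NumericMatrix fixed, NumericMatrix moving,
                        NumericVector i_origin, NumericVector i_spacing,
                        NumericMatrix pts, int bins,
                        NumericMatrix coef_x, NumericMatrix coef_y,
                        NumericVector t_origin, NumericVector t_spacing) {
  FFD f = make_ffd(t_origin, t_spacing, coef_x, coef_y);
  ParzenMI pz;
  pz.fixed = fixed.begin(); pz.moving = moving.begin();
  pz.H = fixed.nrow(); pz.W = fixed.ncol(); pz.bins = bins;
  pz.iox = i_origin[0]; pz.ioy = i_origin[1];
  pz.isx = i_spacing[0]; pz.isy = i_spacing[1];
  pz.set_ranges(fixed, moving);
  int ncx = coef_x.nrow(), ncy = coef_x.ncol();
  NumericMatrix gx(ncx, ncy), gy(ncx, ncy);
  int n = pts.nrow(), m = 0;
  std::vector<double> joint(bins * bins, 0.0), pmarg(bins, 0.0);
  std::vector<int> keep; keep.reserve(n);
  std::vector<double> sum_(n), sgx(n), sgy(n), swu(4 * n), swv(4 * n);
  std::vector<int> sbf(n), siu(n), siv(n);
  if (pz.fsc == 0.0 || pz.msc == 0.0)
    return List::create(_["mi"] = 0.0, _["grad_x"] = gx, _["grad_y"] = gy);
  for (int k = 0; k < n; ++k) {
    double x = pts(k, 0), y = pts(k, 1);
    double fval;
    if (!interp_linear(pz.fixed, pz.H, pz.W, (x - pz.iox) / pz.isx,
                       (y - pz.ioy) / pz.isy, fval)) continue;
    double u = (x - f.ox) / f.sx, v = (y - f.oy) / f.sy;
    int iu = (int)std::floor(u), iv = (int)std::floor(v);
    if (iu < 1 || iu > ncx - 3 || iv < 1 || iv > ncy - 3) continue;
    double wu[4], wv[4];
    bspline_weights(u - iu, wu);
    bspline_weights(v - iv, wv);
    double ux = 0.0, uy = 0.0;
    for (int b = 0; b < 4; ++b)
      for (int a = 0; a < 4; ++a) {
        double w = wu[a] * wv[b];
        ux += w * coef_x[(iu - 1 + a) + (iv - 1 + b) * ncx];
        uy += w * coef_y[(iu - 1 + a) + (iv - 1 + b) * ncx];
      }
    double mx = (x + ux - pz.iox) / pz.isx;
    double my = (y + uy - pz.ioy) / pz.isy;
    double mval;
    if (!interp_linear(pz.moving, pz.H, pz.W, mx, my, mval)) continue;
    double ggx, ggy;
    interp_grad(pz.moving, pz.H, pz.W, mx, my, ggx, ggy);
    int q = m;
    sbf[q] = pz.fixed_bin(fval);
    sum_[q] = pz.moving_coord(mval);
    sgx[q] = ggx / pz.isx; sgy[q] = ggy / pz.isy;
    for (int a = 0; a < 4; ++a) { swu[4 * q + a] = wu[a]; swv[4 * q + a] = wv[a]; }
    siu[q] = iu; siv[q] = iv;
    int j0 = (int)std::floor(sum_[q]);
    for (int b = -1; b <= 2; ++b)
      joint[sbf[q] + (j0 + b) * bins] += beta3(sum_[q] - (j0 + b));
    ++m;
  }
  if (m < 2)
    return List::create(_["mi"] = 0.0, _["grad_x"] = gx, _["grad_y"] = gy);
  for (int b = 0; b < bins; ++b)
    for (int a = 0; a < bins; ++a) pmarg[b] += joint[a + b * bins];
  double mi = 0.0;
  std::vector<double> pf(bins, 0.0);
  for (int b = 0; b < bins; ++b)
    for (int a = 0; a < bins; ++a) pf[a] += joint[a + b * bins] / m;
  for (int b = 0; b < bins; ++b)
    for (int a = 0; a < bins; ++a) {
      double p = joint[a + b * bins] / m;
      if (p > 1e-300) mi += p * std::log(p / (pf[a] * (pmarg[b] / m)));
    }
  for (int k = 0; k < m; ++k) {
    int j0 = (int)std::floor(sum_[k]);
    double g = 0.0;
    for (int b = -1; b <= 2; ++b) {
      int jb = j0 + b;
      double pj = joint[sbf[k] + jb * bins];
      if (pj <= 1e-300 || pmarg[jb] <= 1e-300) continue;
      g += beta3d(sum_[k] - jb) * std::log(pj / pmarg[jb]);
    }
    if (g == 0.0) continue;
    double cxx = g * pz.msc * sgx[k] / m;
    double cyy = g * pz.msc * sgy[k] / m;
    for (int b = 0; b < 4; ++b) {
      int jc = siv[k] - 1 + b;
      for (int a = 0; a < 4; ++a) {
        int ic = siu[k] - 1 + a;
        double w = swu[4 * k + a] * swv[4 * k + b];
        gx(ic, jc) += cxx * w;
        gy(ic, jc) += cyy * w;
      }
    }
  }
  return List::create(_["mi"] = mi, _["grad_x"] = gx, _["grad_y"] = gy);
}

// One pyramid level of stochastic-gradient FFD optimisation of Parzen MI.
// Samples are drawn with R's RNG (seed the R side for determinism).
// Returns the best-evaluated coefficients (checkpoint evaluation on the
// fixed `eval_pts` set, so -MI never worsens relative to the initial
// transform under that evaluation).
// [[Rcpp::export]]
List cpp_ffd_optimize(NumericMatrix fixed, NumericMatrix moving,
                      NumericVector i_origin, NumericVector i_spacing,
                      NumericMatrix coef_x0, NumericMatrix coef_y0,
                      NumericVector t_origin, NumericVector t_spacing,
                      int bins, int iterations, int n_samples,
                      double step0, NumericMatrix eval_pts, int eval_every) {
  int H = fixed.nrow(), W = fixed.ncol();
  int ncx = coef_x0.nrow(), ncy = coef_x0.ncol();
  NumericMatrix cx(clone(coef_x0)), cy(clone(coef_y0));
  ParzenMI pz;
  pz.fixed = fixed.begin(); pz.moving = moving.begin();
  pz.H = H; pz.W = W; pz.bins = bins;
  pz.iox = i_origin[0]; pz.ioy = i_origin[1];
  pz.isx = i_spacing[0]; pz.isy = i_spacing[1];
  pz.set_ranges(fixed, moving);

  auto eval_mi = [&](NumericMatrix &ex, NumericMatrix &ey) {
    return cpp_mi_parzen(fixed, moving, i_origin, i_spacing, eval_pts, bins,
                         ex, ey, t_origin, t_spacing);
  };
  double mi_init = eval_mi(cx, cy);
  double mi_best = mi_init;
  NumericMatrix best_x(clone(cx)), best_y(clone(cy));
  std::vector<double> trace;
  trace.push_back(mi_init);
  // candidate pool for final model selection: every checkpoint iterate,
  // the tail average and the initial transform compete on the independent
  // evaluation sample set; among near-ties the smallest deformation wins
  struct Cand { double mi, norm; std::vector<double> x, y; };
  std::vector<Cand> cands;
  auto coef_norm = [&](const double *px, const double *py) {
    double s = 0.0;
    for (int q = 0; q < ncx * ncy; ++q) s += px[q] * px[q] + py[q] * py[q];
    return s;
  };
  cands.push_back(Cand{mi_init, coef_norm(cx.begin(), cy.begin()),
                       std::vector<double>(cx.begin(), cx.end()),
                       std::vector<double>(cy.begin(), cy.end())});
  if (pz.fsc == 0.0 || pz.msc == 0.0) {
    return List::create(_["coef_x"] = best_x, _["coef_y"] = best_y,
                        _["mi_init"] = mi_init, _["mi_best"] = mi_best,
                        _["trace"] = trace, _["n_eff_mean"] = 0.0);
  }

  FFD f;
  f.ox = t_origin[0]; f.oy = t_origin[1];
  f.sx = t_spacing[0]; f.sy = t_spacing[1];
  f.ncx = ncx; f.ncy = ncy;
  f.cx = cx.begin(); f.cy = cy.begin();

  std::vector<double> joint(bins * bins), pmarg(bins);
  std::vector<double> sx(n_samples), sy(n_samples), smval(n_samples),
      sum(n_samples), sgx(n_samples), sgy(n_samples);
  std::vector<int> sbf(n_samples), sw0(n_samples);
  std::vector<double> swx(4 * n_samples), swy(4 * n_samples);
  std::vector<int> siu(n_samples), siv(n_samples);
  std::vector<double> gx(ncx * ncy), gy(ncx * ncy);
  double n_eff_sum = 0.0;
  int n_eff_cnt = 0;
  // tail iterate average (Polyak): damps the stochastic-gradient noise
  std::vector<double> avg_x(ncx * ncy, 0.0), avg_y(ncx * ncy, 0.0);
  int avg_cnt = 0, avg_start = (3 * iterations) / 4;

  for (int it = 0; it < iterations; ++it) {
    std::fill(joint.begin(), joint.end(), 0.0);
    int m = 0;
    for (int k = 0; k < n_samples; ++k) {
      double xpx = unif_rand() * (W - 1);
      double ypx = unif_rand() * (H - 1);
      double x = pz.iox + xpx * pz.isx;
      double y = pz.ioy + ypx * pz.isy;
      double fval;
      if (!interp_linear(pz.fixed, H, W, xpx, ypx, fval)) continue;
      double u = (x - f.ox) / f.sx, v = (y - f.oy) / f.sy;
      int iu = (int)std::floor(u), iv = (int)std::floor(v);
      if (iu < 1 || iu > ncx - 3 || iv < 1 || iv > ncy - 3) continue;
      double wu[4], wv[4];
      bspline_weights(u - iu, wu);
      bspline_weights(v - iv, wv);
      double ux = 0.0, uy = 0.0;
      for (int b = 0; b < 4; ++b)
        for (int a = 0; a < 4; ++a) {
          double w = wu[a] * wv[b];
          ux += w * cx[(iu - 1 + a) + (iv - 1 + b) * ncx];
          uy += w * cy[(iu - 1 + a) + (iv - 1 + b) * ncx];
        }
      double mx = (x + ux - pz.iox) / pz.isx;
      double my = (y + uy - pz.ioy) / pz.isy;
      double mval;
      if (!interp_linear(pz.moving, H, W, mx, my, mval)) continue;
      double ggx, ggy;
      interp_grad(pz.moving, H, W, mx, my, ggx, ggy);
      // record sample
      sx[m] = x; sy[m] = y; smval[m] = mval;
      sgx[m] = ggx / pz.isx;  // intensity gradient per mm
      sgy[m] = ggy / pz.isy;
      sbf[m] = pz.fixed_bin(fval);
      double um = pz.moving_coord(mval);
      sum[m] = um;
      int j0 = (int)std::floor(um);
      sw0[m] = j0;
      for (int b = -1; b <= 2; ++b)
        joint[sbf[m] + (j0 + b) * bins] += beta3(um - (j0 + b));
      for (int a = 0; a < 4; ++a) { swx[4 * m + a] = wu[a]; swy[4 * m + a] = wv[a]; }
      siu[m] = iu; siv[m] = iv;
      ++m;
    }
    if (m < 16) { trace.push_back(mi_best); continue; }
    n_eff_sum += m; ++n_eff_cnt;
    std::fill(pmarg.begin(), pmarg.end(), 0.0);
    for (int b = 0; b < bins; ++b)
      for (int a = 0; a < bins; ++a) pmarg[b] += joint[a + b * bins];
    // gradient of MI wrt coefficients
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    for (int k = 0; k < m; ++k) {
      int j0 = sw0[k];
      double g = 0.0;
      for (int b = -1; b <= 2; ++b) {
        int jb = j0 + b;
        double pj = joint[sbf[k] + jb * bins];
        if (pj <= 1e-300 || pmarg[jb] <= 1e-300) continue;
        g += beta3d(sum[k] - jb) * std::log(pj / pmarg[jb]);
      }
      if (g == 0.0) continue;
      // d um / d coef = msc * gradM . w ; dMI = (1/m) * sum g * dum
      double cxx = g * pz.msc * sgx[k] / m;
      double cyy = g * pz.msc * sgy[k] / m;
      for (int b = 0; b < 4; ++b) {
        int jc = siv[k] - 1 + b;
        for (int a = 0; a < 4; ++a) {
          int ic = siu[k] - 1 + a;
          double w = swx[4 * k + a] * swy[4 * k + b];
          gx[ic + jc * ncx] += cxx * w;
          gy[ic + jc * ncx] += cyy * w;
        }
      }
    }
    double gmax = 0.0;
    for (size_t q = 0; q < gx.size(); ++q) {
      double a1 = std::fabs(gx[q]), a2 = std::fabs(gy[q]);
      if (a1 > gmax) gmax = a1;
      if (a2 > gmax) gmax = a2;
    }
    if (gmax > 0) {
      double step = step0 / (1.0 + it / 20.0);
      for (size_t q = 0; q < gx.size(); ++q) {
        cx[q] += step * gx[q] / gmax;
        cy[q] += step * gy[q] / gmax;
      }
    }
    if (it >= avg_start) {
      for (int q = 0; q < ncx * ncy; ++q) { avg_x[q] += cx[q]; avg_y[q] += cy[q]; }
      ++avg_cnt;
    }
    if ((it + 1) % eval_every == 0 || it == iterations - 1) {
      double mi = eval_mi(cx, cy);
      trace.push_back(mi);
      cands.push_back(Cand{mi, coef_norm(cx.begin(), cy.begin()),
                           std::vector<double>(cx.begin(), cx.end()),
                           std::vector<double>(cy.begin(), cy.end())});
    }
  }
  if (avg_cnt > 0) {
    NumericMatrix ax(ncx, ncy), ay(ncx, ncy);
    for (int q = 0; q < ncx * ncy; ++q) {
      ax[q] = avg_x[q] / avg_cnt;
      ay[q] = avg_y[q] / avg_cnt;
    }
    double mi_avg = eval_mi(ax, ay);
    trace.push_back(mi_avg);
    cands.push_back(Cand{mi_avg, coef_norm(ax.begin(), ay.begin()),
                         std::vector<double>(ax.begin(), ax.end()),
                         std::vector<double>(ay.begin(), ay.end())});
  }
  // model selection: maximize evaluation MI; within `mi_tol` of the best,
  // prefer the minimum-deformation candidate (Occam tie-break against
  // drift along directions the metric does not constrain)
  const double mi_tol = 0.018;
  double top = cands[0].mi;
  for (size_t c = 1; c < cands.size(); ++c) top = std::max(top, cands[c].mi);
  int sel = -1;
  for (size_t c = 0; c < cands.size(); ++c) {
    if (cands[c].mi >= top - mi_tol &&
        (sel < 0 || cands[c].norm < cands[sel].norm))
      sel = (int)c;
  }
  mi_best = cands[sel].mi;
  std::copy(cands[sel].x.begin(), cands[sel].x.end(), best_x.begin());
  std::copy(cands[sel].y.begin(), cands[sel].y.end(), best_y.begin());
  return List::create(_["coef_x"] = best_x, _["coef_y"] = best_y,
                      _["mi_init"] = mi_init, _["mi_best"] = mi_best,
                      _["trace"] = trace,
                      _["n_eff_mean"] = n_eff_cnt ? n_eff_sum / n_eff_cnt : 0.0);
}
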