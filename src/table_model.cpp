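// Fast evaluation of the pixel-integrated PSF model from a precomputed
// intensity lookup table, with analytic gradients with respect to (x, y, d).
//
// The table holds the continuous image-plane intensity of one fixed
// (orientation, aberration, optics) context on a regular lateral grid
// (spacing h, typically pixel/9) for a stack of defocus planes (spacing hd).
// A model evaluation interpolates the table by separable Catmull-Rom cubics
// in x, y and d at the fitting subpixel positions, sums subpixels into camera
// pixels, normalizes the ROI sum to one, scales by the photon number and adds
// the background mean. Because the interpolant is an explicit piecewise
// polynomial, the gradient of the objective is exact for the tabulated model.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void cr_weights(double t, double* w, double* dw) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = 0.5 * (-t + 2 * t2 - t3);
  w[1] = 0.5 * (2 - 5 * t2 + 3 * t3);
  w[2] = 0.5 * (t + 4 * t2 - 3 * t3);
  w[3] = 0.5 * (-t2 + t3);
  if (dw) {
    dw[0] = 0.5 * (-1 + 4 * t - 3 * t2);
    dw[1] = 0.5 * (-10 * t + 9 * t2);
    dw[2] = 0.5 * (1 + 8 * t - 9 * t2);
    dw[3] = 0.5 * (-2 * t + 3 * t2);
  }
}

struct AxisInterp {
  std::vector<int> i0;          // leftmost of the 4 support indices
  std::vector<double> w, dw;    // 4 weights (+ d/dcoord) per sample
};

// Interpolation setup along one axis for query positions q on grid
// g_k = g0 + k * h, k = 0..n-1. dscale is dq/dparameter (e.g. -1 for x since
// q = s - x).
static AxisInterp axis_setup(const std::vector<double>& q, double g0, double h,
                             int n, double dscale) {
  AxisInterp ax;
  const int m = q.size();
  ax.i0.resize(m);
  ax.w.resize(4 * m);
  ax.dw.resize(4 * m);
  for (int i = 0; i < m; ++i) {
    double u = (q[i] - g0) / h;
    int k = (int)std::floor(u);
    if (k < 1 || k > n - 3) {
      stop("lookup-table query outside the tabulated range; rebuild the table with larger margins");
    }
    double t = u - k;
    double w[4], dw[4];
    cr_weights(t, w, dw);
    ax.i0[i] = k - 1;
    for (int a = 0; a < 4; ++a) {
      ax.w[4 * i + a] = w[a];
      ax.dw[4 * i + a] = dw[a] * dscale / h;
    }
  }
  return ax;
}

// Core: binned model P (npx x npx) and its derivatives wrt x, y, d.
static void table_bin(const NumericVector& tab, int nx, int ny, int nd,
                      const AxisInterp& ax, const AxisInterp& ay,
                      int jd0, const double* wd, const double* dwd,
                      int npx, int os,
                      std::vector<double>& P, std::vector<double>& Px,
                      std::vector<double>& Py, std::vector<double>& Pd) {
  const int ns = npx * os;
  const double* T = tab.begin();
  P.assign(npx * npx, 0.0);
  Px.assign(npx * npx, 0.0);
  Py.assign(npx * npx, 0.0);
  Pd.assign(npx * npx, 0.0);
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int k = 0; k < 4; ++k) {
    const double* S = T + (R_xlen_t)(jd0 + k) * plane;
    const double wdk = wd[k], dwdk = dwd[k];
    for (int j = 0; j < ns; ++j) {
      const double* wyj = &ay.w[4 * j];
      const double* dwyj = &ay.dw[4 * j];
      const int jy = ay.i0[j];
      const int pj = (j / os) * npx;
      for (int i = 0; i < ns; ++i) {
        const double* wxi = &ax.w[4 * i];
        const double* dwxi = &ax.dw[4 * i];
        const int ix = ax.i0[i];
        double v = 0.0, vx = 0.0, vy = 0.0;
        for (int b = 0; b < 4; ++b) {
          const double* col = S + (R_xlen_t)(jy + b) * nx + ix;
          const double wyb = wyj[b], dwyb = dwyj[b];
          double rv = 0.0, rvx = 0.0;
          for (int a = 0; a < 4; ++a) {
            rv += wxi[a] * col[a];
            rvx += dwxi[a] * col[a];
          }
          v += wyb * rv;
          vx += wyb * rvx;
          vy += dwyb * rv;
        }
        const int pk = pj + i / os;
        P[pk] += wdk * v;
        Px[pk] += wdk * vx;
        Py[pk] += wdk * vy;
        Pd[pk] += dwdk * v;
      }
    }
  }
}

struct Eval {
  double value;
  double grad[3];
  std::vector<double> nu;
};

// type: 0 = Poisson negative log-likelihood on raw counts (factorial term
// dropped), 1 = sum of squared residuals, 2 = model image only.
static Eval table_eval(const NumericVector& tab, IntegerVector dims,
                       double g0, double h, double d0, double hd,
                       double x, double y, double d,
                       const NumericVector& z, double neff, double bg,
                       int npx, int os, double px_nm, int type,
                       double xy_bound, double d_lo, double d_hi,
                       double pen_w) {
  const int nx = dims[0], ny = dims[1], nd = dims[2];
  Eval ev;
  ev.value = 0.0;
  ev.grad[0] = ev.grad[1] = ev.grad[2] = 0.0;

  // soft box: clamp the evaluation point, add a quadratic penalty so the
  // unconstrained optimizer is pushed back into the tabulated domain
  double xe = x, ye = y, de = d;
  double pen = 0.0, pgx = 0.0, pgy = 0.0, pgd = 0.0;
  if (xe > xy_bound) { pen += pen_w * (xe - xy_bound) * (xe - xy_bound); pgx = 2 * pen_w * (xe - xy_bound); xe = xy_bound; }
  if (xe < -xy_bound) { pen += pen_w * (xe + xy_bound) * (xe + xy_bound); pgx = 2 * pen_w * (xe + xy_bound); xe = -xy_bound; }
  if (ye > xy_bound) { pen += pen_w * (ye - xy_bound) * (ye - xy_bound); pgy = 2 * pen_w * (ye - xy_bound); ye = xy_bound; }
  if (ye < -xy_bound) { pen += pen_w * (ye + xy_bound) * (ye + xy_bound); pgy = 2 * pen_w * (ye + xy_bound); ye = -xy_bound; }
  if (de > d_hi) { pen += pen_w * (de - d_hi) * (de - d_hi); pgd = 2 * pen_w * (de - d_hi); de = d_hi; }
  if (de < d_lo) { pen += pen_w * (de - d_lo) * (de - d_lo); pgd = 2 * pen_w * (de - d_lo); de = d_lo; }

  const int ns = npx * os;
  std::vector<double> qx(ns), qy(ns);
  for (int i = 0; i < ns; ++i) {
    double s = (i - (ns - 1) / 2.0) * px_nm / os;
    qx[i] = s - xe;
    qy[i] = s - ye;
  }
  AxisInterp ax = axis_setup(qx, g0, h, nx, -1.0);
  AxisInterp ay = axis_setup(qy, g0, h, ny, -1.0);

  double ud = (de - d0) / hd;
  int jd = (int)std::floor(ud);
  if (jd < 1) jd = 1;
  if (jd > nd - 3) jd = nd - 3;
  double td = ud - jd;
  double wd[4], dwd[4];
  cr_weights(td, wd, dwd);
  for (int k = 0; k < 4; ++k) dwd[k] /= hd;

  std::vector<double> P, Px, Py, Pd;
  table_bin(tab, nx, ny, nd, ax, ay, jd - 1, wd, dwd, npx, os, P, Px, Py, Pd);

  const int K = npx * npx;
  double S = 0, Sx = 0, Sy = 0, Sd = 0;
  for (int kq = 0; kq < K; ++kq) { S += P[kq]; Sx += Px[kq]; Sy += Py[kq]; Sd += Pd[kq]; }
  if (S <= 0) stop("tabulated PSF mass is not positive; corrupt table?");

  ev.nu.resize(K);
  double gx = 0, gy = 0, gd = 0;
  const double inv_s = 1.0 / S;
  for (int kq = 0; kq < K; ++kq) {
    const double pn = P[kq] * inv_s;
    double nu = neff * pn + bg;
    const double dnx = neff * (Px[kq] - pn * Sx) * inv_s;
    const double dny = neff * (Py[kq] - pn * Sy) * inv_s;
    const double dnd = neff * (Pd[kq] - pn * Sd) * inv_s;
    if (nu < 1e-12) nu = 1e-12;
    ev.nu[kq] = nu;
    if (type == 0) {
      // half-deviance: the Poisson NLL recentred on the saturated model, so
      // the objective is O(K) instead of O(sum z) and the optimizer's
      // relative termination test is scale-free
      const double zk = z[kq];
      ev.value += nu - zk * std::log(nu);
      if (zk > 0) ev.value += zk * std::log(zk) - zk;
      const double f = 1.0 - zk / nu;
      gx += f * dnx; gy += f * dny; gd += f * dnd;
    } else if (type == 1) {
      const double r = z[kq] - nu;
      ev.value += r * r;
      gx += -2 * r * dnx; gy += -2 * r * dny; gd += -2 * r * dnd;
    }
  }
  ev.value += pen;
  ev.grad[0] = gx + pgx;
  ev.grad[1] = gy + pgy;
  ev.grad[2] = gd + pgd;
  return ev;
}

// [[Rcpp::export]]
List table_objective_cpp(NumericVector tab, IntegerVector dims,
                         double g0, double h, double d0, double hd,
                         double x, double y, double d,
                         NumericVector z, double neff, double bg,
                         int npx, int os, double px_nm, int type,
                         double xy_bound, double d_lo, double d_hi,
                         double pen_w) {
  Eval ev = table_eval(tab, dims, g0, h, d0, hd, x, y, d, z, neff, bg,
                       npx, os, px_nm, type, xy_bound, d_lo, d_hi, pen_w);
  return List::create(_["value"] = ev.value,
                      _["gradient"] = NumericVector::create(ev.grad[0], ev.grad[1], ev.grad[2]));
}

// [[Rcpp::export]]
NumericMatrix table_model_cpp(NumericVector tab, IntegerVector dims,
                              double g0, double h, double d0, double hd,
                              double x, double y, double d,
                              double neff, double bg,
                              int npx, int os, double px_nm,
                              double xy_bound, double d_lo, double d_hi) {
  NumericVector z(npx * npx);
  Eval ev = table_eval(tab, dims, g0, h, d0, hd, x, y, d, z, neff, bg,
                       npx, os, px_nm, 2, xy_bound, d_lo, d_hi, 0.0);
  NumericMatrix out(npx, npx);
  std::copy(ev.nu.begin(), ev.nu.end(), out.begin());
  return out;
}
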