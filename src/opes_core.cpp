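#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 1-D surrogate potential: polynomial + Gaussian terms + charge coupling.
struct Potential {
  NumericVector poly, gh, gc, gw;
  double q, phic, phiw;

  double energy(double x) const {
    double u = 0.0, xp = 1.0;
    for (int k = 0; k < poly.size(); ++k) { u += poly[k] * xp; xp *= x; }
    for (int j = 0; j < gh.size(); ++j) {
      double d = x - gc[j];
      u += gh[j] * std::exp(-d * d / (2.0 * gw[j] * gw[j]));
    }
    if (q != 0.0) {
      double d = x - phic;
      u += q * std::exp(-d * d / (2.0 * phiw * phiw));
    }
    return u;
  }

  // returns -dU/dx
  double force(double x) const {
    double du = 0.0, xp = 1.0;
    for (int k = 1; k < poly.size(); ++k) { du += k * poly[k] * xp; xp *= x; }
    // note: xp starts at x^0 for the k=1 term
    for (int j = 0; j < gh.size(); ++j) {
      double d = x - gc[j], w2 = gw[j] * gw[j];
      du += -gh[j] * d / w2 * std::exp(-d * d / (2.0 * w2));
    }
    if (q != 0.0) {
      double d = x - phic, w2 = phiw * phiw;
      du += -q * d / w2 * std::exp(-d * d / (2.0 * w2));
    }
    return -du;
  }
};

// Piecewise-linear lookup table on a uniform grid (value + derivative).
struct Table {
  NumericVector grid, val, der;
  bool active;
  double g0, dg;
  void init() {
    active = grid.size() > 1;
    if (active) { g0 = grid[0]; dg = grid[1] - grid[0]; }
  }
  // value and derivative at x; linear extrapolation at the edges
  void eval(double x, double &v, double &d) const {
    int n = grid.size();
    double t = (x - g0) / dg;
    int i = (int)std::floor(t);
    if (i < 0) i = 0;
    if (i > n - 2) i = n - 2;
    double frac = (x - (g0 + i * dg)) / dg;
    double fc = frac < 0.0 ? 0.0 : (frac > 1.0 ? 1.0 : frac);
    v = val[i] + frac * (val[i + 1] - val[i]);
    d = der[i] + fc * (der[i + 1] - der[i]);
  }
};

// OPES kernel bias over the CV: V(s) = pref * log(P(s)/Z + eps),
// P a height-weighted normalized-Gaussian mixture of the deposited
// kernels (kernel-density estimate of the sampled CV distribution).
struct KernelBias {
  NumericVector kc, kw, kh;
  double Z, eps, pref, H;
  void init() {
    H = 0.0;
    for (int j = 0; j < kh.size(); ++j) H += kh[j];
  }
  void eval(double s, double &V, double &dVds) const {
    if (kc.size() == 0 || H <= 0.0) { V = 0.0; dVds = 0.0; return; }
    double P = 0.0, dP = 0.0;
    const double inv_sqrt2pi = 0.3989422804014327;
    for (int j = 0; j < kc.size(); ++j) {
      double d = s - kc[j], w = kw[j];
      double g = kh[j] * inv_sqrt2pi / w * std::exp(-d * d / (2.0 * w * w));
      P += g;
      dP += -d / (w * w) * g;
    }
    P /= H; dP /= H;
    double a = P / Z + eps;
    V = pref * std::log(a);
    dVds = pref * (dP / Z) / a;
  }
};

// [[Rcpp::export(name = ".opes_segment_cpp")]]
List opes_segment_cpp(NumericVector x, NumericVector v,
                      int n_steps, double dt, double friction,
                      double kT, double mass,
                      NumericVector poly, NumericVector gh,
                      NumericVector gc, NumericVector gw,
                      double q, double phic, double phiw,
                      NumericVector cv_grid, NumericVector cv_s,
                      NumericVector cv_dsdx,
                      NumericVector kc, NumericVector kw, NumericVector kh,
                      double Z, double eps, double pref,
                      NumericVector bias_grid, NumericVector bias_V,
                      NumericVector bias_dV,
                      double wall_lo, double wall_hi, double wall_k,
                      double domain_guard, int stride) {
  int nw = x.size();
  Potential pot{poly, gh, gc, gw, q, phic, phiw};
  Table cvt{cv_grid, cv_s, cv_dsdx, false, 0, 0};  cvt.init();
  Table ext{bias_grid, bias_V, bias_dV, false, 0, 0}; ext.init();
  KernelBias kb{kc, kw, kh, Z, eps, pref, 0.0}; kb.init();

  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt((1.0 - c1 * c1) * kT / mass);

  int n_rec = n_steps / stride;
  NumericMatrix pos(n_rec, nw), bias_e(n_rec, nw), wall_e(n_rec, nw),
                pot_e(n_rec, nw), cvs(n_rec, nw);

  std::vector<double> f(nw), xx(nw), vv(nw);
  for (int w = 0; w < nw; ++w) { xx[w] = x[w]; vv[w] = v[w]; }

  // total force, bias energy and wall energy at position x
  auto forces = [&](double xi, double &ftot, double &Vb, double &Ew,
                    double &s_out) {
    ftot = pot.force(xi);
    // the bias lives on the walled domain: beyond a wall it is frozen at
    // its wall value, so only the wall force acts there
    double xb = xi;
    if (wall_k > 0.0) {
      if (xb > wall_hi) xb = wall_hi;
      if (xb < wall_lo) xb = wall_lo;
    }
    double s = xb, dsdx = 1.0;
    if (cvt.active) cvt.eval(xb, s, dsdx);
    if (wall_k > 0.0 && xb != xi) dsdx = 0.0;
    s_out = s;
    double V = 0.0, dVds = 0.0;
    kb.eval(s, V, dVds);
    Vb = V;
    ftot += -dVds * dsdx;
    if (ext.active) {
      double Ve, dVe;
      ext.eval(xi, Ve, dVe);
      Vb += Ve;
      ftot += -dVe;
    }
    Ew = 0.0;
    if (wall_k > 0.0) {
      if (xi > wall_hi) {
        double d = xi - wall_hi;
        Ew = 0.5 * wall_k * d * d;
        ftot += -wall_k * d;
      } else if (xi < wall_lo) {
        double d = xi - wall_lo;
        Ew = 0.5 * wall_k * d * d;
        ftot += -wall_k * d;
      }
    }
  };

  double Vb, Ew, s;
  for (int w = 0; w < nw; ++w) forces(xx[w], f[w], Vb, Ew, s);

  for (int step = 1; step <= n_steps; ++step) {
    for (int w = 0; w < nw; ++w) {
      vv[w] += 0.5 * dt * f[w] / mass;
      xx[w] += 0.5 * dt * vv[w];
      vv[w] = c1 * vv[w] + c2 * norm_rand();
      xx[w] += 0.5 * dt * vv[w];
      forces(xx[w], f[w], Vb, Ew, s);
      vv[w] += 0.5 * dt * f[w] / mass;
      if (!std::isfinite(xx[w]) || std::fabs(xx[w]) > domain_guard) {
        stop("trajectory diverged at step %d (walker %d): |x| exceeded "
             "the domain guard", step, w + 1);
      }
      if (step % stride == 0) {
        int r = step / stride - 1;
        pos(r, w) = xx[w];
        bias_e(r, w) = Vb;
        wall_e(r, w) = Ew;
        pot_e(r, w) = pot.energy(xx[w]);
        cvs(r, w) = s;
      }
    }
  }

  NumericVector xf(nw), vf(nw);
  for (int w = 0; w < nw; ++w) { xf[w] = xx[w]; vf[w] = vv[w]; }
  return List::create(_["positions"] = pos, _["cv"] = cvs,
                      _["bias"] = bias_e, _["wall"] = wall_e,
                      _["potential"] = pot_e,
                      _["x_final"] = xf, _["v_final"] = vf);
}
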