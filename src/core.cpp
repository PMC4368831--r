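// Core numerics: large-deviation Hamiltonians, geometric (Maupertuis) action,
// path relaxation, quasi-potential grid fill, and exact stochastic simulation
// of the cell-cycle reaction network.  Everything here works on the
// concentration scale; volume enters only through the SSA routines.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double PMAX = 35.0;   // momentum clip: keeps exp() finite near degenerate faces
static const double EPSA = 1e-14;  // propensity considered extinct below this

// ---------------------------------------------------------------------------
// Models.  Each model provides per-coordinate birth/death propensity sums
// (concentration scale) and their spatial gradients.  drift = B - D.
//   1 cellcycle  d=3  par = j1 j2 j3 k1 k2 k3 ki ks ka1 ka2 a0
//   2 bd1        d=1  par = c k          (birth c, death k*x)
//   3 quadwell   d=2  par = a1 a2 m1 m2  (drift-only: b = -A (x - m))
//   4 dwell1     d=1  drift-only: b = x - x^3 (double well, minima at +/-1)
// ---------------------------------------------------------------------------

static inline double hill2(double v, double j) { return v * v / (j * j + v * v); }
static inline double hill2d(double v, double j) {
  double s = j * j + v * v;
  return 2.0 * j * j * v / (s * s);
}

static int model_dim(int model) {
  switch (model) {
  case 1: return 3;
  case 2: return 1;
  case 3: return 2;
  case 4: return 1;
  }
  Rcpp::stop("unknown model code");
}

static bool model_has_jump(int model) { return model == 1 || model == 2; }

// birth/death sums per coordinate
static void rates(int model, const double* par, const double* x,
                  double* B, double* D) {
  if (model == 1) {
    const double j1 = par[0], j2 = par[1], j3 = par[2];
    const double k1 = par[3], k2 = par[4], k3 = par[5];
    const double ki = par[6], ks = par[7], ka1 = par[8], ka2 = par[9], a0 = par[10];
    B[0] = hill2(x[0], j1) + a0;
    D[0] = k1 * x[0] + x[0] * x[1];
    B[1] = hill2(x[1], j2) + ka1 * x[0];
    D[1] = k2 * x[1] + x[1] * x[2];
    B[2] = ks * hill2(x[2], j3) + ka2 * x[1];
    D[2] = k3 * x[2] + ki * x[2] * x[0];
  } else if (model == 2) {
    B[0] = par[0];
    D[0] = par[1] * x[0];
  } else {
    Rcpp::stop("model has no jump-process representation");
  }
}

// gradients of the birth/death sums: dB[k*d + l] = dB_k/dx_l
static void rates_grad(int model, const double* par, const double* x,
                       double* dB, double* dD) {
  if (model == 1) {
    const double j1 = par[0], j2 = par[1], j3 = par[2];
    const double k1 = par[3], k2 = par[4], k3 = par[5];
    const double ki = par[6], ks = par[7], ka1 = par[8], ka2 = par[9];
    for (int i = 0; i < 9; ++i) { dB[i] = 0.0; dD[i] = 0.0; }
    dB[0] = hill2d(x[0], j1);
    dD[0] = k1 + x[1];        dD[1] = x[0];
    dB[3] = ka1;              dB[4] = hill2d(x[1], j2);
    dD[4] = k2 + x[2];        dD[5] = x[1];
    dB[7] = ka2;              dB[8] = ks * hill2d(x[2], j3);
    dD[6] = ki * x[2];        dD[8] = k3 + ki * x[0];
  } else if (model == 2) {
    dB[0] = 0.0;
    dD[0] = par[1];
  } else {
    Rcpp::stop("model has no jump-process representation");
  }
}

static void drift(int model, const double* par, const double* x, double* b) {
  if (model == 3) {
    b[0] = -par[0] * (x[0] - par[2]);
    b[1] = -par[1] * (x[1] - par[3]);
  } else if (model == 4) {
    b[0] = x[0] - x[0] * x[0] * x[0];
  } else {
    double B[3], D[3];
    rates(model, par, x, B, D);
    int d = model_dim(model);
    for (int k = 0; k < d; ++k) b[k] = B[k] - D[k];
  }
}

static void jac(int model, const double* par, const double* x, double* J) {
  int d = model_dim(model);
  if (model == 3) {
    J[0] = -par[0]; J[1] = 0.0; J[2] = 0.0; J[3] = -par[1];
  } else if (model == 4) {
    J[0] = 1.0 - 3.0 * x[0] * x[0];
  } else {
    double dB[9], dD[9];
    rates_grad(model, par, x, dB, dD);
    for (int i = 0; i < d * d; ++i) J[i] = dB[i] - dD[i];
  }
}

// ---------------------------------------------------------------------------
// Hamiltonians.  kind 1 = intrinsic jump: H = sum_k B_k(e^{p_k}-1)+D_k(e^{-p_k}-1)
//                kind 2 = extrinsic additive: H = p.b + |p|^2/2
// ---------------------------------------------------------------------------

static double ham(int kind, int model, const double* par,
                  const double* x, const double* p) {
  int d = model_dim(model);
  if (kind == 1) {
    double B[3], D[3], H = 0.0;
    rates(model, par, x, B, D);
    for (int k = 0; k < d; ++k) {
      double pk = std::max(-PMAX, std::min(PMAX, p[k]));
      H += B[k] * std::expm1(pk) + D[k] * std::expm1(-pk);
    }
    return H;
  }
  double b[3], H = 0.0;
  drift(model, par, x, b);
  for (int k = 0; k < d; ++k) H += p[k] * b[k] + 0.5 * p[k] * p[k];
  return H;
}

static void ham_dp(int kind, int model, const double* par,
                   const double* x, const double* p, double* out) {
  int d = model_dim(model);
  if (kind == 1) {
    double B[3], D[3];
    rates(model, par, x, B, D);
    for (int k = 0; k < d; ++k) {
      double pk = std::max(-PMAX, std::min(PMAX, p[k]));
      out[k] = B[k] * std::exp(pk) - D[k] * std::exp(-pk);
    }
    return;
  }
  double b[3];
  drift(model, par, x, b);
  for (int k = 0; k < d; ++k) out[k] = b[k] + p[k];
}

// ---------------------------------------------------------------------------
// Geometric local action l(x, v) = sup { p.v : H(x,p) <= 0 }
//                               = inf_{tau>0} tau * L(x, v/tau).
// For the separable jump Hamiltonian the inner conjugate is closed-form
// per coordinate; the scalar Maupertuis condition H(x, p*(v/tau)) = 0 is
// solved for log(tau) (H is monotone decreasing in tau).
// For the extrinsic Hamiltonian the whole thing is closed-form:
// l = |b||v| - b.v,  p* = |b| v/|v| - b.
// ---------------------------------------------------------------------------

struct SegWork {
  double p[3];      // maximizing momentum
  double tau;       // optimal local time scale (jump kind)
  double gx[3];     // d l / d x at fixed chord
  double cost;
};

// conjugate-optimal momentum per coordinate for w = v/tau
static inline double popt1(double B, double D, double w) {
  double p;
  if (B > EPSA && D > EPSA) {
    double s = std::sqrt(w * w + 4.0 * B * D);
    p = std::log((w + s) / (2.0 * B));
  } else if (B > EPSA) {
    p = (w > EPSA) ? std::log(w / B) : -PMAX;
  } else if (D > EPSA) {
    p = (w < -EPSA) ? -std::log(-w / D) : PMAX;
  } else {
    p = (w > EPSA) ? PMAX : (w < -EPSA ? -PMAX : 0.0);
  }
  if (p > PMAX) p = PMAX;
  if (p < -PMAX) p = -PMAX;
  return p;
}

// evaluate H(x, p*(v/tau)) for the jump kind; fills p
static inline double ham_at_tau(int d, const double* B, const double* D,
                                const double* v, double ltau, double* p) {
  double tau = std::exp(ltau), H = 0.0;
  for (int k = 0; k < d; ++k) {
    p[k] = popt1(B[k], D[k], v[k] / tau);
    H += B[k] * std::expm1(p[k]) + D[k] * std::expm1(-p[k]);
  }
  return H;
}

static void seg_cost(int kind, int model, const double* par,
                     const double* xmid, const double* v, SegWork& w,
                     bool want_grad, double tau_ws) {
  int d = model_dim(model);
  double vn = 0.0;
  for (int k = 0; k < d; ++k) vn += v[k] * v[k];
  vn = std::sqrt(vn);
  if (vn < 1e-14) {
    w.cost = 0.0; w.tau = tau_ws;
    for (int k = 0; k < d; ++k) { w.p[k] = 0.0; w.gx[k] = 0.0; }
    return;
  }

  if (kind == 2) {                     // extrinsic: closed form
    double b[3], bn = 0.0, bv = 0.0;
    drift(model, par, xmid, b);
    for (int k = 0; k < d; ++k) { bn += b[k] * b[k]; bv += b[k] * v[k]; }
    bn = std::sqrt(bn);
    w.cost = bn * vn - bv;
    if (w.cost < 0.0) w.cost = 0.0;    // roundoff guard along the flow
    double bsafe = std::max(bn, 1e-12);
    for (int k = 0; k < d; ++k) w.p[k] = bn * v[k] / vn - b[k];
    if (want_grad) {
      double J[9];
      jac(model, par, xmid, J);
      for (int l = 0; l < d; ++l) {
        double Jb = 0.0, Jv = 0.0;
        for (int k = 0; k < d; ++k) { Jb += J[k * d + l] * b[k]; Jv += J[k * d + l] * v[k]; }
        w.gx[l] = vn * Jb / bsafe - Jv;
      }
    }
    w.tau = vn / bsafe;
    return;
  }

  // jump kind: solve H(x, p*(v/tau)) = 0 on log(tau) by bracketing around a
  // physically sensible initial time scale, then Illinois false position.
  // H is monotone decreasing in tau.
  double B[3], D[3];
  rates(model, par, xmid, B, D);
  const double LTMIN = -40.0, LTMAX = 40.0;
  double p[3];
  double ltau;
  // initial scale: |v| over a drift/rate magnitude
  double rmag = 1e-12;
  for (int k = 0; k < d; ++k)
    rmag = std::max(rmag, std::max(std::fabs(B[k] - D[k]), 1e-3 * (B[k] + D[k])));
  double c0 = (R_finite(tau_ws) && tau_ws > 0.0) ? std::log(tau_ws)
                                                 : std::log(vn / rmag);
  c0 = std::min(std::max(c0, LTMIN), LTMAX);
  double fl = ham_at_tau(d, B, D, v, c0, p);
  double lo, hi, fh;
  if (fl > 0.0) {                 // root is above c0
    lo = c0;
    double step = 0.7;
    hi = lo; fh = fl;
    while (fh > 0.0 && hi < LTMAX) {
      lo = hi; fl = fh;
      hi = std::min(hi + step, LTMAX);
      fh = ham_at_tau(d, B, D, v, hi, p);
      step *= 2.0;
    }
  } else {                        // root is below c0
    hi = c0; fh = fl;
    double step = 0.7;
    lo = hi; fl = fh;
    while (fl < 0.0 && lo > LTMIN) {
      hi = lo; fh = fl;
      lo = std::max(lo - step, LTMIN);
      fl = ham_at_tau(d, B, D, v, lo, p);
      step *= 2.0;
    }
  }
  if (fl <= 0.0) {
    ltau = lo;                    // even infinitesimal time is free: v ~ 0
  } else if (fh >= 0.0) {
    ltau = hi;                    // rates balanced (near attractor)
  } else {
    double hscale = 1e-300;
    for (int k = 0; k < d; ++k) hscale = std::max(hscale, B[k] + D[k]);
    ltau = 0.5 * (lo + hi);
    for (int it = 0; it < 100; ++it) {
      double mid = (fl * hi - fh * lo) / (fl - fh);
      if (!(mid > lo && mid < hi)) mid = 0.5 * (lo + hi);
      double fm = ham_at_tau(d, B, D, v, mid, p);
      ltau = mid;
      if (std::fabs(fm) < 1e-14 * hscale || hi - lo < 1e-14) break;
      if (fm > 0.0) {
        if (fl > 0.0) fh *= 0.5;  // Illinois damping on the stagnant side
        lo = mid; fl = fm;
      } else {
        if (fh < 0.0) fl *= 0.5;
        hi = mid; fh = fm;
      }
    }
  }
  ham_at_tau(d, B, D, v, ltau, p);
  w.tau = std::exp(ltau);
  double cost = 0.0;
  for (int k = 0; k < d; ++k) { w.p[k] = p[k]; cost += p[k] * v[k]; }
  w.cost = std::max(cost, 0.0);
  if (want_grad) {
    double dB[9], dD[9];
    rates_grad(model, par, xmid, dB, dD);
    for (int l = 0; l < d; ++l) {
      double g = 0.0;
      for (int k = 0; k < d; ++k)
        g += dB[k * d + l] * std::expm1(p[k]) + dD[k * d + l] * std::expm1(-p[k]);
      w.gx[l] = -w.tau * g;
    }
  }
}

// ---------------------------------------------------------------------------
// Path-level action and gradient (midpoint rule per chord)
// ---------------------------------------------------------------------------

static double path_action(int kind, int model, const double* par,
                          const std::vector<double>& path, int N, int d,
                          std::vector<double>* grad,
                          std::vector<double>* tau_ws) {
  double A = 0.0;
  SegWork w;
  if (grad) std::fill(grad->begin(), grad->end(), 0.0);
  double m[3], v[3];
  for (int i = 0; i < N - 1; ++i) {
    for (int k = 0; k < d; ++k) {
      m[k] = 0.5 * (path[i * d + k] + path[(i + 1) * d + k]);
      v[k] = path[(i + 1) * d + k] - path[i * d + k];
    }
    double ws = tau_ws ? (*tau_ws)[i] : NA_REAL;
    seg_cost(kind, model, par, m, v, w, grad != nullptr, ws);
    if (tau_ws) (*tau_ws)[i] = w.tau;
    A += w.cost;
    if (grad) {
      for (int k = 0; k < d; ++k) {
        (*grad)[i * d + k]       += -w.p[k] + 0.5 * w.gx[k];
        (*grad)[(i + 1) * d + k] +=  w.p[k] + 0.5 * w.gx[k];
      }
    }
  }
  return A;
}

// resample polyline to equal arc length, endpoints fixed
static void reparam(std::vector<double>& path, int N, int d) {
  std::vector<double> cum(N, 0.0);
  for (int i = 1; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      double dx = path[i * d + k] - path[(i - 1) * d + k];
      s += dx * dx;
    }
    cum[i] = cum[i - 1] + std::sqrt(s);
  }
  double L = cum[N - 1];
  if (L < 1e-300) return;
  std::vector<double> out(path);
  int j = 1;
  for (int i = 1; i < N - 1; ++i) {
    double target = L * i / (N - 1);
    while (j < N - 1 && cum[j] < target) ++j;
    double t = (target - cum[j - 1]) / std::max(cum[j] - cum[j - 1], 1e-300);
    for (int k = 0; k < d; ++k)
      out[i * d + k] = (1.0 - t) * path[(j - 1) * d + k] + t * path[j * d + k];
  }
  path.swap(out);
}

// relax a path by projected adaptive gradient descent with arc-length
// reparametrization; endpoints pinned.  Returns final action.
static double minimize_path(int kind, int model, const double* par,
                            std::vector<double>& path, int N, int d,
                            int maxit, double tol, double lb,
                            bool& converged, int& iters) {
  const int nint = (N - 2) * d;
  std::vector<double> grad(N * d), tau_ws(N - 1, NA_REAL), trial(N * d), tau_trial(N - 1);
  std::vector<double> prev_x(nint), prev_g(nint);
  reparam(path, N, d);
  double A = path_action(kind, model, par, path, N, d, &grad, &tau_ws);
  double L = 0.0;
  for (int i = 1; i < N; ++i) {
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      double dx = path[i * d + k] - path[(i - 1) * d + k];
      s += dx * dx;
    }
    L += std::sqrt(s);
  }
  double gmax = 1e-12;
  for (int i = d; i < (N - 1) * d; ++i) gmax = std::max(gmax, std::fabs(grad[i]));
  double step0 = 0.02 * std::max(L, 1e-6) / gmax;
  double step = step0;
  converged = false;
  int ok_in_row = 0;
  iters = 0;
  bool have_prev = false;
  // non-monotone reference: max action over the last few accepted iterates
  double ref[5] = {A, A, A, A, A};
  int ri = 0;
  for (int it = 0; it < maxit; ++it) {
    ++iters;
    // BB spectral step from the previous accepted iterate
    if (have_prev) {
      double sy = 0.0, yy = 0.0;
      for (int i = 0; i < nint; ++i) {
        double sx = path[d + i] - prev_x[i];
        double yg = grad[d + i] - prev_g[i];
        sy += sx * yg;
        yy += yg * yg;
      }
      if (sy > 0.0 && yy > 1e-300) {
        double bb = sy / yy;
        step = std::min(std::max(bb, 1e-4 * step0), 1e4 * step0);
      }
    }
    double refmax = ref[0];
    for (int r = 1; r < 5; ++r) refmax = std::max(refmax, ref[r]);
    bool accepted = false;
    double Anew = A;
    for (int bt = 0; bt < 12; ++bt) {
      trial = path;
      for (int i = 1; i < N - 1; ++i)
        for (int k = 0; k < d; ++k) {
          double v = trial[i * d + k] - step * grad[i * d + k];
          if (v < lb) v = lb;
          trial[i * d + k] = v;
        }
      reparam(trial, N, d);
      tau_trial = tau_ws;
      Anew = path_action(kind, model, par, trial, N, d, nullptr, &tau_trial);
      if (R_finite(Anew) && Anew <= refmax + 1e-12) {
        accepted = true;
        break;
      }
      step *= 0.3;
    }
    if (!accepted) { converged = true; break; }
    for (int i = 0; i < nint; ++i) { prev_x[i] = path[d + i]; prev_g[i] = grad[d + i]; }
    have_prev = true;
    double dA = std::fabs(A - Anew);
    path.swap(trial);
    tau_ws.swap(tau_trial);
    A = Anew;
    ref[ri] = A;
    ri = (ri + 1) % 5;
    path_action(kind, model, par, path, N, d, &grad, &tau_ws);
    if (dA < tol * std::max(std::fabs(A), 1e-10)) {
      if (++ok_in_row >= 3) { converged = true; break; }
    } else ok_in_row = 0;
  }
  return A;
}

// ---------------------------------------------------------------------------
// Exported wrappers
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_drift(int model, NumericVector par, NumericVector x) {
  int d = model_dim(model);
  NumericVector out(d);
  drift(model, REAL(par), REAL(x), REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_jac(int model, NumericVector par, NumericVector x) {
  int d = model_dim(model);
  std::vector<double> J(d * d);
  jac(model, REAL(par), REAL(x), J.data());
  NumericMatrix out(d, d);
  for (int k = 0; k < d; ++k)
    for (int l = 0; l < d; ++l) out(k, l) = J[k * d + l];  // row k: eq, col l: d/dx_l
  return out;
}

// [[Rcpp::export]]
List cpp_rates(int model, NumericVector par, NumericVector x) {
  int d = model_dim(model);
  NumericVector B(d), D(d);
  rates(model, REAL(par), REAL(x), REAL(B), REAL(D));
  return List::create(_["birth"] = B, _["death"] = D);
}

// [[Rcpp::export]]
double cpp_ham(int kind, int model, NumericVector par,
               NumericVector x, NumericVector p) {
  return ham(kind, model, REAL(par), REAL(x), REAL(p));
}

// [[Rcpp::export]]
NumericVector cpp_ham_dp(int kind, int model, NumericVector par,
                         NumericVector x, NumericVector p) {
  int d = model_dim(model);
  NumericVector out(d);
  ham_dp(kind, model, REAL(par), REAL(x), REAL(p), REAL(out));
  return out;
}

// [[Rcpp::export]]
bool cpp_model_has_jump(int model) { return model_has_jump(model); }

// geometric action of a fixed path (rows = nodes)
// [[Rcpp::export]]
List cpp_action(int kind, int model, NumericVector par, NumericMatrix path) {
  int N = path.nrow(), d = path.ncol();
  if (d != model_dim(model)) Rcpp::stop("path dimension does not match model");
  std::vector<double> p(N * d);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < d; ++k) p[i * d + k] = path(i, k);
  std::vector<double> tau(N - 1, NA_REAL);
  double A = path_action(kind, model, REAL(par), p, N, d, nullptr, &tau);
  return List::create(_["action"] = A, _["tau"] = NumericVector(tau.begin(), tau.end()));
}

// [[Rcpp::export]]
NumericMatrix cpp_action_grad(int kind, int model, NumericVector par, NumericMatrix path) {
  int N = path.nrow(), d = path.ncol();
  std::vector<double> p(N * d), g(N * d);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < d; ++k) p[i * d + k] = path(i, k);
  std::vector<double> tau(N - 1, NA_REAL);
  path_action(kind, model, REAL(par), p, N, d, &g, &tau);
  NumericMatrix out(N, d);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < d; ++k) out(i, k) = g[i * d + k];
  return out;
}

// [[Rcpp::export]]
List cpp_minimize(int kind, int model, NumericVector par, NumericMatrix path0,
                  int maxit, double tol, double lb) {
  int N = path0.nrow(), d = path0.ncol();
  if (d != model_dim(model)) Rcpp::stop("path dimension does not match model");
  std::vector<double> p(N * d);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < d; ++k) p[i * d + k] = path0(i, k);
  bool conv; int iters;
  double A = minimize_path(kind, model, REAL(par), p, N, d, maxit, tol, lb, conv, iters);
  NumericMatrix out(N, d);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < d; ++k) out(i, k) = p[i * d + k];
  return List::create(_["path"] = out, _["action"] = A,
                      _["converged"] = conv, _["iterations"] = iters);
}

// fill a regular grid with local quasi-potential values by continuation:
// nodes processed outward from the attractor set, each warm-started from the
// best converged grid neighbour.
// resample an explicit polyline (given as flat vector) to nnodes
static void resample_to(const std::vector<double>& poly, int M, int d,
                        int nnodes, std::vector<double>& out) {
  std::vector<double> cum(M, 0.0);
  for (int i = 1; i < M; ++i) {
    double s = 0.0;
    for (int k = 0; k < d; ++k) {
      double dx = poly[i * d + k] - poly[(i - 1) * d + k];
      s += dx * dx;
    }
    cum[i] = cum[i - 1] + std::sqrt(s);
  }
  double L = std::max(cum[M - 1], 1e-300);
  out.resize(nnodes * d);
  int j = 1;
  for (int i = 0; i < nnodes; ++i) {
    double target = L * i / (nnodes - 1);
    while (j < M - 1 && cum[j] < target) ++j;
    double t = (target - cum[j - 1]) / std::max(cum[j] - cum[j - 1], 1e-300);
    for (int k = 0; k < d; ++k)
      out[i * d + k] = (1.0 - t) * poly[(j - 1) * d + k] + t * poly[j * d + k];
  }
}

// [[Rcpp::export]]
List cpp_fill_grid(int kind, int model, NumericVector par, List axes,
                   NumericMatrix attr_pts, NumericMatrix skeleton,
                   int nnodes, int maxit_first,
                   int maxit, double tol, double lb, int n_sweeps) {
  int d = model_dim(model);
  const double* par_ptr = REAL(par);
  if ((int)axes.size() != d) Rcpp::stop("axes length must equal model dimension");
  std::vector<std::vector<double> > ax(d);
  std::vector<int> nn(d);
  int ntot = 1;
  for (int k = 0; k < d; ++k) {
    NumericVector a = axes[k];
    ax[k] = std::vector<double>(a.begin(), a.end());
    nn[k] = a.size();
    ntot *= nn[k];
  }
  int na = attr_pts.nrow();

  // strides for flattening (first axis fastest, R array order)
  std::vector<int> stride(d);
  stride[0] = 1;
  for (int k = 1; k < d; ++k) stride[k] = stride[k - 1] * nn[k - 1];

  std::vector<double> S(ntot, NA_REAL);
  std::vector<int> conv(ntot, 0), done(ntot, 0), nearattr(ntot, 0);
  std::vector<double> dist(ntot);
  std::vector<double> pts(ntot * d);

  for (int idx = 0; idx < ntot; ++idx) {
    int rem = idx;
    double best = std::numeric_limits<double>::infinity();
    int bestk = 0;
    for (int k = 0; k < d; ++k) {
      int ik = rem % nn[k];
      rem /= nn[k];
      pts[idx * d + k] = ax[k][ik];
    }
    for (int a = 0; a < na; ++a) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double dx = pts[idx * d + k] - attr_pts(a, k);
        s += dx * dx;
      }
      if (s < best) { best = s; bestk = a; }
    }
    dist[idx] = std::sqrt(best);
    nearattr[idx] = bestk;
  }

  std::vector<int> order(ntot);
  for (int i = 0; i < ntot; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return dist[a] < dist[b]; });

  std::vector<double> paths(static_cast<size_t>(ntot) * nnodes * d);
  std::vector<double> work(nnodes * d), alt(nnodes * d), poly;
  int nskel = skeleton.nrow();
  std::vector<double> skel(nskel * d);
  for (int i = 0; i < nskel; ++i)
    for (int k = 0; k < d; ++k) skel[i * d + k] = skeleton(i, k);
  bool first_done = false;

  for (int oi = 0; oi < ntot; ++oi) {
    int idx = order[oi];
    const double* tgt = &pts[idx * d];
    if (dist[idx] < 1e-12) {
      S[idx] = 0.0; conv[idx] = 1; done[idx] = 1;
      for (int i = 0; i < nnodes; ++i)
        for (int k = 0; k < d; ++k) paths[(size_t)idx * nnodes * d + i * d + k] = tgt[k];
      continue;
    }
    // warm start: best converged neighbour
    int src = -1;
    double bestS = std::numeric_limits<double>::infinity();
    int rem = idx;
    std::vector<int> ik(d);
    for (int k = 0; k < d; ++k) { ik[k] = rem % nn[k]; rem /= nn[k]; }
    for (int k = 0; k < d; ++k) {
      for (int s = -1; s <= 1; s += 2) {
        int j = ik[k] + s;
        if (j < 0 || j >= nn[k]) continue;
        int nidx = idx + s * stride[k];
        if (done[nidx] && conv[nidx] && R_finite(S[nidx]) && S[nidx] < bestS) {
          bestS = S[nidx]; src = nidx;
        }
      }
    }
    bool have_init = false;
    double A_init = std::numeric_limits<double>::infinity();
    std::vector<double> tau_dummy;
    if (src >= 0) {
      const double* sp = &paths[(size_t)src * nnodes * d];
      const double* old_end = sp + (nnodes - 1) * d;
      for (int i = 0; i < nnodes; ++i) {
        // ramp the endpoint displacement over the tail quarter only, so the
        // converged trunk of the neighbour's path is preserved
        double u = (double)i / (nnodes - 1);
        double t = u <= 0.75 ? 0.0 : (u - 0.75) / 0.25;
        for (int k = 0; k < d; ++k) {
          double v = sp[i * d + k] + t * (tgt[k] - old_end[k]);
          work[i * d + k] = std::max(v, lb);
        }
      }
      reparam(work, nnodes, d);
      A_init = path_action(kind, model, par_ptr, work, nnodes, d, nullptr, nullptr);
      have_init = true;
    }
    if (nskel >= 2) {
      // skeleton init: follow the reference path to its nearest point, then
      // run straight to the target
      int mbest = 0;
      double dbest = std::numeric_limits<double>::infinity();
      for (int m = 0; m < nskel; ++m) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double dx = skel[m * d + k] - tgt[k];
          s += dx * dx;
        }
        if (s < dbest) { dbest = s; mbest = m; }
      }
      poly.assign(skel.begin(), skel.begin() + (mbest + 1) * d);
      for (int k = 0; k < d; ++k) poly.push_back(tgt[k]);
      resample_to(poly, mbest + 2, d, nnodes, alt);
      for (int i = 0; i < nnodes * d; ++i) alt[i] = std::max(alt[i], lb);
      double A_alt = path_action(kind, model, par_ptr, alt, nnodes, d, nullptr, nullptr);
      if (!have_init || (R_finite(A_alt) && A_alt < A_init)) {
        work = alt;
        A_init = A_alt;
        have_init = true;
      }
    }
    {
      // straight line from the nearest attractor point: a third family that
      // covers targets interior to the cycle loop
      for (int i = 0; i < nnodes; ++i) {
        double t = (double)i / (nnodes - 1);
        for (int k = 0; k < d; ++k) {
          double start = attr_pts(nearattr[idx], k);
          alt[i * d + k] = std::max(start + t * (tgt[k] - start), lb);
        }
      }
      double A_line = have_init
        ? path_action(kind, model, par_ptr, alt, nnodes, d, nullptr, nullptr)
        : 0.0;
      if (!have_init || (R_finite(A_line) && A_line < A_init)) {
        work = alt;
        have_init = true;
      }
    }
    bool cv; int iters;
    int effort = first_done ? maxit : maxit_first;
    double A = minimize_path(kind, model, REAL(par), work, nnodes, d,
                             effort, tol, lb, cv, iters);
    first_done = true;
    S[idx] = R_finite(A) ? A : NA_REAL;
    conv[idx] = cv ? 1 : 0;
    done[idx] = 1;
    std::copy(work.begin(), work.end(), paths.begin() + (size_t)idx * nnodes * d);
    if (oi % 512 == 0) Rcpp::checkUserInterrupt();
  }

  // improvement sweeps: each node retries a warm start morphed from every
  // neighbour's stored path and keeps the best relaxed result.  This removes
  // route inconsistencies between neighbouring nodes (the continuation can
  // leave a node on a locally-minimal but globally inferior path family).
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    int improved = 0;
    for (int oi = 0; oi < ntot; ++oi) {
      int idx = order[oi];
      if (dist[idx] < 1e-12) continue;
      const double* tgt = &pts[idx * d];
      int rem = idx;
      std::vector<int> ik(d);
      for (int k = 0; k < d; ++k) { ik[k] = rem % nn[k]; rem /= nn[k]; }
      double bestA = R_finite(S[idx]) ? S[idx] : std::numeric_limits<double>::infinity();
      bool found = false;
      for (int k = 0; k < d; ++k) {
        for (int s = -1; s <= 1; s += 2) {
          int j = ik[k] + s;
          if (j < 0 || j >= nn[k]) continue;
          int nidx = idx + s * stride[k];
          if (!done[nidx] || !R_finite(S[nidx])) continue;
          if (S[nidx] >= bestA) continue;   // neighbour cannot seed a better route
          const double* sp = &paths[(size_t)nidx * nnodes * d];
          const double* old_end = sp + (nnodes - 1) * d;
          for (int i = 0; i < nnodes; ++i) {
            double u = (double)i / (nnodes - 1);
            double t = u <= 0.75 ? 0.0 : (u - 0.75) / 0.25;
            for (int kk = 0; kk < d; ++kk) {
              double v = sp[i * d + kk] + t * (tgt[kk] - old_end[kk]);
              alt[i * d + kk] = std::max(v, lb);
            }
          }
          reparam(alt, nnodes, d);
          double A0 = path_action(kind, model, par_ptr, alt, nnodes, d, nullptr, nullptr);
          if (R_finite(A0) && A0 < bestA - std::max(1e-3 * std::fabs(bestA), 1e-6)) {
            bestA = A0;
            work = alt;
            found = true;
          }
        }
      }
      if (found) {
        bool cv; int iters;
        double A = minimize_path(kind, model, par_ptr, work, nnodes, d,
                                 maxit, tol, lb, cv, iters);
        if (R_finite(A) && A < S[idx]) {
          S[idx] = A;
          conv[idx] = cv ? 1 : conv[idx];
          std::copy(work.begin(), work.end(), paths.begin() + (size_t)idx * nnodes * d);
          ++improved;
        }
      }
      if (oi % 512 == 0) Rcpp::checkUserInterrupt();
    }
    if (improved == 0) break;
  }

  NumericVector Sout(S.begin(), S.end());
  Sout.attr("dim") = IntegerVector(nn.begin(), nn.end());
  IntegerVector cvout(conv.begin(), conv.end());
  cvout.attr("dim") = IntegerVector(nn.begin(), nn.end());
  return List::create(_["S"] = Sout, _["converged"] = cvout);
}

// ---------------------------------------------------------------------------
// Exact SSA (Gillespie direct method) for the 12-channel cell-cycle network.
// Channel order follows the equations term by term:
//   eq 1a: +hill1, -k1 X, -XY/V, +a0 V        (channels 1..4)
//   eq 1b: +hill2, -k2 Y, -YZ/V, +ka1 X       (channels 5..8)
//   eq 1c: +ks hill3, -k3 Z, -ki XZ/V, +ka2 Y (channels 9..12)
// Uses R's RNG so that set.seed() on the R side fixes the event stream.
// ---------------------------------------------------------------------------

static void cc_propensities(const double* par, double V, const double* X, double* a) {
  const double j1 = par[0], j2 = par[1], j3 = par[2];
  const double k1 = par[3], k2 = par[4], k3 = par[5];
  const double ki = par[6], ks = par[7], ka1 = par[8], ka2 = par[9], a0 = par[10];
  double x = X[0] / V, y = X[1] / V, z = X[2] / V;
  a[0] = V * hill2(x, j1);
  a[1] = k1 * X[0];
  a[2] = X[0] * X[1] / V;
  a[3] = a0 * V;
  a[4] = V * hill2(y, j2);
  a[5] = k2 * X[1];
  a[6] = X[1] * X[2] / V;
  a[7] = ka1 * X[0];
  a[8] = V * ks * hill2(z, j3);
  a[9] = k3 * X[2];
  a[10] = ki * X[0] * X[2] / V;
  a[11] = ka2 * X[1];
}

static const int CC_NU_SP[12]  = {0, 0, 0, 0, 1, 1, 1, 1, 2, 2, 2, 2};
static const int CC_NU_SGN[12] = {1, -1, -1, 1, 1, -1, -1, 1, 1, -1, -1, 1};

// [[Rcpp::export]]
List cpp_ssa_cc(NumericVector par, double V, IntegerVector X0, double t_end,
                int max_events, int record_every) {
  RNGScope scope;
  double X[3] = {(double)X0[0], (double)X0[1], (double)X0[2]};
  double t = 0.0, a[12];
  std::vector<double> times;
  std::vector<double> xs, ys, zs;
  times.push_back(0.0); xs.push_back(X[0]); ys.push_back(X[1]); zs.push_back(X[2]);
  bool absorbed = false;
  long ev = 0;
  while (t < t_end && ev < (long)max_events) {
    cc_propensities(REAL(par), V, X, a);
    double atot = 0.0;
    for (int j = 0; j < 12; ++j) atot += a[j];
    if (atot <= 0.0) { absorbed = true; break; }
    double dt = -std::log(unif_rand()) / atot;
    t += dt;
    if (t > t_end) { t = t_end; break; }
    double r = unif_rand() * atot, c = 0.0;
    int j = 0;
    for (; j < 11; ++j) { c += a[j]; if (r <= c) break; }
    X[CC_NU_SP[j]] += CC_NU_SGN[j];
    if (X[CC_NU_SP[j]] < 0) X[CC_NU_SP[j]] = 0;  // cannot happen: propensity vanishes
    ++ev;
    if (ev % record_every == 0) {
      times.push_back(t); xs.push_back(X[0]); ys.push_back(X[1]); zs.push_back(X[2]);
    }
    if (ev % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  times.push_back(t); xs.push_back(X[0]); ys.push_back(X[1]); zs.push_back(X[2]);
  return List::create(_["time"] = NumericVector(times.begin(), times.end()),
                      _["X"] = NumericVector(xs.begin(), xs.end()),
                      _["Y"] = NumericVector(ys.begin(), ys.end()),
                      _["Z"] = NumericVector(zs.begin(), zs.end()),
                      _["absorbed"] = absorbed, _["n_events"] = (double)ev);
}

// residence-time histogram over concentration space, optional reinjection
// conditioning: entering the ball around `center` resets the walker to
// `restart` counts; residence inside `excl_radius` of center is not scored.
// [[Rcpp::export]]
List cpp_ssa_hist_cc(NumericVector par, double V, IntegerVector X0,
                     double t_total, double burn_in,
                     double lo, double hi, int nbins,
                     bool reinject, IntegerVector restart,
                     NumericVector center, double ball_radius, double excl_radius,
                     double max_events) {
  RNGScope scope;
  double X[3] = {(double)X0[0], (double)X0[1], (double)X0[2]};
  double t = 0.0, a[12];
  std::vector<double> counts((size_t)nbins * nbins * nbins, 0.0);
  double wtot = 0.0;
  double binw = (hi - lo) / nbins;
  long ev = 0;
  bool absorbed = false;
  while (t < t_total && ev < (long)max_events) {
    double x = X[0] / V, y = X[1] / V, z = X[2] / V;
    double dc = std::sqrt((x - center[0]) * (x - center[0]) +
                          (y - center[1]) * (y - center[1]) +
                          (z - center[2]) * (z - center[2]));
    if (reinject && dc <= ball_radius) {
      X[0] = restart[0]; X[1] = restart[1]; X[2] = restart[2];
      x = X[0] / V; y = X[1] / V; z = X[2] / V;
      dc = std::sqrt((x - center[0]) * (x - center[0]) +
                     (y - center[1]) * (y - center[1]) +
                     (z - center[2]) * (z - center[2]));
    }
    cc_propensities(REAL(par), V, X, a);
    double atot = 0.0;
    for (int j = 0; j < 12; ++j) atot += a[j];
    if (atot <= 0.0) { absorbed = true; break; }
    double dt = -std::log(unif_rand()) / atot;
    double tnext = std::min(t + dt, t_total);
    double w = tnext - std::max(t, burn_in);
    if (w > 0.0 && dc > excl_radius) {
      int ix = (int)((x - lo) / binw), iy = (int)((y - lo) / binw), iz = (int)((z - lo) / binw);
      if (ix >= 0 && ix < nbins && iy >= 0 && iy < nbins && iz >= 0 && iz < nbins) {
        counts[(size_t)ix + (size_t)nbins * (iy + (size_t)nbins * iz)] += w;
        wtot += w;
      }
    }
    t = tnext;
    if (t >= t_total) break;
    double r = unif_rand() * atot, c = 0.0;
    int j = 0;
    for (; j < 11; ++j) { c += a[j]; if (r <= c) break; }
    X[CC_NU_SP[j]] += CC_NU_SGN[j];
    ++ev;
    if (ev % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector out(counts.begin(), counts.end());
  out.attr("dim") = IntegerVector::create(nbins, nbins, nbins);
  return List::create(_["counts"] = out, _["total_weight"] = wtot,
                      _["t_final"] = t, _["n_events"] = (double)ev,
                      _["absorbed"] = absorbed);
}

// first-passage time of the cell-cycle walker out of a ball
// [[Rcpp::export]]
double cpp_ssa_exit_cc(NumericVector par, double V, IntegerVector X0,
                       NumericVector center, double radius, double t_cap) {
  RNGScope scope;
  double X[3] = {(double)X0[0], (double)X0[1], (double)X0[2]};
  double t = 0.0, a[12];
  long ev = 0;
  while (t < t_cap) {
    double x = X[0] / V, y = X[1] / V, z = X[2] / V;
    double dc = std::sqrt((x - center[0]) * (x - center[0]) +
                          (y - center[1]) * (y - center[1]) +
                          (z - center[2]) * (z - center[2]));
    if (dc > radius) return t;
    cc_propensities(REAL(par), V, X, a);
    double atot = 0.0;
    for (int j = 0; j < 12; ++j) atot += a[j];
    if (atot <= 0.0) return NA_REAL;
    t += -std::log(unif_rand()) / atot;
    double r = unif_rand() * atot, c = 0.0;
    int j = 0;
    for (; j < 11; ++j) { c += a[j]; if (r <= c) break; }
    X[CC_NU_SP[j]] += CC_NU_SGN[j];
    if (++ev % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  return NA_REAL;  // censored
}

// Euler-Maruyama simulation of the extrinsic-noise model
// dx = b(x) dt + amp dW, reflected at the coordinate planes
// [[Rcpp::export]]
List cpp_em_cc(NumericVector par, double amp, NumericVector x0, double t_end,
               double dt, int record_every) {
  RNGScope scope;
  double x[3] = {x0[0], x0[1], x0[2]};
  double b[3];
  long nsteps = (long)(t_end / dt);
  double sq = amp * std::sqrt(dt);
  std::vector<double> times, xs, ys, zs;
  times.push_back(0.0); xs.push_back(x[0]); ys.push_back(x[1]); zs.push_back(x[2]);
  for (long s = 1; s <= nsteps; ++s) {
    drift(1, REAL(par), x, b);
    for (int k = 0; k < 3; ++k) {
      x[k] += b[k] * dt + sq * norm_rand();
      if (x[k] < 0.0) x[k] = -x[k];   // reflect
    }
    if (s % record_every == 0) {
      times.push_back(s * dt);
      xs.push_back(x[0]); ys.push_back(x[1]); zs.push_back(x[2]);
    }
    if (s % 200000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["time"] = NumericVector(times.begin(), times.end()),
                      _["X"] = NumericVector(xs.begin(), xs.end()),
                      _["Y"] = NumericVector(ys.begin(), ys.end()),
                      _["Z"] = NumericVector(zs.begin(), zs.end()));
}

// ---------------------------------------------------------------------------
// 1-D birth-death test system: birth c*V, death k*X
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ssa_bd1(double c, double k, double V, int X0, double t_end,
                 int max_events, int record_every) {
  RNGScope scope;
  double X = X0, t = 0.0;
  std::vector<double> times, xs;
  times.push_back(0.0); xs.push_back(X);
  bool absorbed = false;
  long ev = 0;
  while (t < t_end && ev < (long)max_events) {
    double ab = c * V, ad = k * X, atot = ab + ad;
    if (atot <= 0.0) { absorbed = true; break; }
    double dt = -std::log(unif_rand()) / atot;
    t += dt;
    if (t > t_end) { t = t_end; break; }
    X += (unif_rand() * atot <= ab) ? 1.0 : -1.0;
    ++ev;
    if (ev % record_every == 0) { times.push_back(t); xs.push_back(X); }
  }
  times.push_back(t); xs.push_back(X);
  return List::create(_["time"] = NumericVector(times.begin(), times.end()),
                      _["X"] = NumericVector(xs.begin(), xs.end()),
                      _["absorbed"] = absorbed, _["n_events"] = (double)ev);
}

// [[Rcpp::export]]
List cpp_ssa_hist_bd1(double c, double k, double V, int X0,
                      double t_total, double burn_in, int xmax) {
  RNGScope scope;
  double X = X0, t = 0.0;
  std::vector<double> counts(xmax + 1, 0.0);
  double wtot = 0.0;
  while (t < t_total) {
    double ab = c * V, ad = k * X, atot = ab + ad;
    if (atot <= 0.0) break;
    double dt = -std::log(unif_rand()) / atot;
    double tnext = std::min(t + dt, t_total);
    double w = tnext - std::max(t, burn_in);
    if (w > 0.0 && X <= xmax) { counts[(int)X] += w; wtot += w; }
    t = tnext;
    if (t >= t_total) break;
    X += (unif_rand() * atot <= ab) ? 1.0 : -1.0;
  }
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["total_weight"] = wtot);
}

// [[Rcpp::export]]
double cpp_ssa_exit_bd1(double c, double k, double V, int X0, int X_exit,
                        double t_cap) {
  RNGScope scope;
  double X = X0, t = 0.0;
  while (t < t_cap) {
    if (X >= X_exit) return t;
    double ab = c * V, ad = k * X, atot = ab + ad;
    if (atot <= 0.0) return NA_REAL;
    t += -std::log(unif_rand()) / atot;
    X += (unif_rand() * atot <= ab) ? 1.0 : -1.0;
  }
  return NA_REAL;
}

// exact mean first-passage time for the 1-D chain (tridiagonal solve),
// used as an independent oracle in tests
// [[Rcpp::export]]
double cpp_mfpt_bd1(double c, double k, double V, int X0, int X_exit) {
  // tau_i = (1 + b_i tau_{i+1} + d_i tau_{i-1}) / (b_i + d_i), absorbing at X_exit,
  // reflecting at 0; solved by the standard forward recursion
  int n = X_exit;
  std::vector<double> tau(n + 1, 0.0);
  // theta_i = tau_i - tau_{i+1}; theta_0 from balance, recursion upward
  // Standard formula: tau_i = sum_{j=i}^{n-1} sum_{l=0}^{j} (1/b_j) prod_{m=l+1}^{j} (d_m/b_m)
  long double total0 = 0.0L;
  std::vector<long double> theta(n, 0.0L);
  for (int j = 0; j < n; ++j) {
    long double s = 0.0L, prod = 1.0L;
    // l = j term
    s = 1.0L / (c * V);
    prod = 1.0L;
    for (int l = j; l >= 1; --l) {
      prod *= (long double)(k * l) / (c * V);
      s += prod / (c * V);
    }
    theta[j] = s;
  }
  std::vector<long double> taux(n + 1, 0.0L);
  for (int i = n - 1; i >= 0; --i) taux[i] = taux[i + 1] + theta[i];
  total0 = taux[std::min(std::max(X0, 0), n)];
  return (double)total0;
}
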