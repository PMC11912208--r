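// Core MASH propagation: analytic two-state models, adiabatization,
// Bloch-spin rotations, hop energetics, and the family of integrators
// (asym/nonrev/rev/rev-pc with NAC, ATDC and LD spin propagation).
// All quantities in atomic units (hbar = 1).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <string>

using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::IntegerVector;
using Rcpp::CharacterVector;
using Rcpp::Named;
using Rcpp::stop;

static const double TWO_PI = 6.283185307179586476925286766559;

// ---------------------------------------------------------------------------
// Model definition
// ---------------------------------------------------------------------------

struct Model {
  int type;               // 0 = tully1, 1 = lvc
  // tully1
  double A, B, C, D;
  // lvc (dimensionless mass-weighted normal modes)
  int F;                  // degrees of freedom
  std::vector<double> omega, kappa1, kappa2, lambda;
  double E1, E2;
  std::vector<double> mass;     // per-dof mass
  double degen_thr;
};

static Model parse_model(const List& m) {
  Model md;
  std::string type = Rcpp::as<std::string>(m["type"]);
  md.degen_thr = m.containsElementNamed("degen_thr")
    ? Rcpp::as<double>(m["degen_thr"]) : 1e-12;
  if (type == "tully1") {
    md.type = 0;
    md.A = Rcpp::as<double>(m["A"]); md.B = Rcpp::as<double>(m["B"]);
    md.C = Rcpp::as<double>(m["C"]); md.D = Rcpp::as<double>(m["D"]);
    md.F = 1;
    md.mass.assign(1, Rcpp::as<double>(m["mass"]));
  } else if (type == "lvc") {
    md.type = 1;
    md.omega  = Rcpp::as<std::vector<double>>(m["omega"]);
    md.kappa1 = Rcpp::as<std::vector<double>>(m["kappa1"]);
    md.kappa2 = Rcpp::as<std::vector<double>>(m["kappa2"]);
    md.lambda = Rcpp::as<std::vector<double>>(m["lambda"]);
    md.E1 = Rcpp::as<double>(m["E1"]); md.E2 = Rcpp::as<double>(m["E2"]);
    md.F = (int) md.omega.size();
    if ((int) md.kappa1.size() != md.F || (int) md.kappa2.size() != md.F ||
        (int) md.lambda.size() != md.F)
      stop("lvc parameter vectors must all have the same length as omega");
    // dimensionless convention: kinetic energy sum_j omega_j p_j^2 / 2
    md.mass.resize(md.F);
    for (int j = 0; j < md.F; ++j) md.mass[j] = 1.0 / md.omega[j];
  } else {
    stop("unknown model type '%s'", type.c_str());
  }
  return md;
}

// Diabatic evaluation: H (h11, h22, h12) and per-dof gradients.
struct Diab {
  double h11, h22, h12;
  std::vector<double> d11, d22, d12;  // length F
};

static void eval_diab(const Model& md, const double* q, Diab& de) {
  de.d11.resize(md.F); de.d22.resize(md.F); de.d12.resize(md.F);
  if (md.type == 0) {
    double x = q[0];
    double h11, g11;
    if (x > 0) { h11 =  md.A * (1.0 - std::exp(-md.B * x)); g11 = md.A * md.B * std::exp(-md.B * x); }
    else       { h11 = -md.A * (1.0 - std::exp( md.B * x)); g11 = md.A * md.B * std::exp( md.B * x); }
    double h12 = md.C * std::exp(-md.D * x * x);
    de.h11 = h11; de.h22 = -h11; de.h12 = h12;
    de.d11[0] = g11; de.d22[0] = -g11;
    de.d12[0] = -2.0 * md.D * x * h12;
  } else {
    double harm = 0.0, t1 = 0.0, t2 = 0.0, cpl = 0.0;
    for (int j = 0; j < md.F; ++j) {
      harm += 0.5 * md.omega[j] * q[j] * q[j];
      t1 += md.kappa1[j] * q[j];
      t2 += md.kappa2[j] * q[j];
      cpl += md.lambda[j] * q[j];
    }
    de.h11 = harm + md.E1 + t1;
    de.h22 = harm + md.E2 + t2;
    de.h12 = cpl;
    for (int j = 0; j < md.F; ++j) {
      double gh = md.omega[j] * q[j];
      de.d11[j] = gh + md.kappa1[j];
      de.d22[j] = gh + md.kappa2[j];
      de.d12[j] = md.lambda[j];
    }
  }
}

// ---------------------------------------------------------------------------
// Adiabatization
// ---------------------------------------------------------------------------

struct Elec {
  double V0, V1, gap;
  std::vector<double> F0, F1, d;  // forces and NAC, length F
  double U[4];                    // column-major: U[0]=U00, U[1]=U10, U[2]=U01, U[3]=U11
};

// uref == nullptr -> default sign convention (upper column: largest component
// positive; lower column sign chosen so that det(U) = +1).
static void adiabatize(const Model& md, const Diab& de, const double* uref, Elec& el) {
  double mean = 0.5 * (de.h11 + de.h22);
  double delta = 0.5 * (de.h11 - de.h22);
  double c = de.h12;
  double r = std::sqrt(delta * delta + c * c);
  el.V0 = mean - r; el.V1 = mean + r; el.gap = 2.0 * r;
  if (el.gap < md.degen_thr)
    stop("degenerate electronic states (gap %.3e below threshold %.3e)", el.gap, md.degen_thr);
  double phi = 0.5 * std::atan2(2.0 * c, de.h11 - de.h22);
  // u1 (upper) = (cos phi, sin phi); u0 (lower) = (sin phi, -cos phi); det = +1
  double u0a = std::sin(phi), u0b = -std::cos(phi);
  double u1a = std::cos(phi), u1b =  std::sin(phi);
  if (uref != nullptr) {
    if (uref[0] * u0a + uref[1] * u0b < 0) { u0a = -u0a; u0b = -u0b; }
    if (uref[2] * u1a + uref[3] * u1b < 0) { u1a = -u1a; u1b = -u1b; }
  } else {
    if ((std::fabs(u1a) >= std::fabs(u1b) ? u1a : u1b) < 0) { u1a = -u1a; u1b = -u1b; }
    if (u0a * u1b - u0b * u1a < 0) { u0a = -u0a; u0b = -u0b; }
  }
  el.U[0] = u0a; el.U[1] = u0b; el.U[2] = u1a; el.U[3] = u1b;
  el.F0.resize(md.F); el.F1.resize(md.F); el.d.resize(md.F);
  for (int j = 0; j < md.F; ++j) {
    double a11 = de.d11[j], a22 = de.d22[j], a12 = de.d12[j];
    // u^T dH u for each column
    el.F0[j] = -(u0a * (a11 * u0a + a12 * u0b) + u0b * (a12 * u0a + a22 * u0b));
    el.F1[j] = -(u1a * (a11 * u1a + a12 * u1b) + u1b * (a12 * u1a + a22 * u1b));
    el.d[j]  =  (u0a * (a11 * u1a + a12 * u1b) + u0b * (a12 * u1a + a22 * u1b)) / el.gap;
  }
}

static void eval_elec(const Model& md, const double* q, const double* uref, Elec& el) {
  static thread_local Diab de;  // scratch: avoids per-step allocation
  eval_diab(md, q, de);
  adiabatize(md, de, uref, el);
}

// ---------------------------------------------------------------------------
// Overlap between eigenvector frames, special-orthogonal polar factor, chi
// ---------------------------------------------------------------------------

// Returns chi (wavefunction rotation angle). O_raw is computed from U0, U1
// with the columns of U1 sign-flipped until both diagonal entries are
// positive (the smooth-continuation phase convention).
static double overlap_chi(const double* U0, const double* U1raw, double* O_out,
                          double swap_tol = 0.1) {
  double u1[4] = { U1raw[0], U1raw[1], U1raw[2], U1raw[3] };
  double o00 = U0[0] * u1[0] + U0[1] * u1[1];
  double o11 = U0[2] * u1[2] + U0[3] * u1[3];
  if (o00 < 0) { u1[0] = -u1[0]; u1[1] = -u1[1]; o00 = -o00; }
  if (o11 < 0) { u1[2] = -u1[2]; u1[3] = -u1[3]; o11 = -o11; }
  double o01 = U0[0] * u1[2] + U0[1] * u1[3];
  double o10 = U0[2] * u1[0] + U0[3] * u1[1];
  if (o00 < swap_tol || o11 < swap_tol)
    stop("overlap diagonal below %.3g: state-character swap or trivial crossing; reduce the time-step", swap_tol);
  // nearest SO(2): rotation by psi = atan2(o10 - o01, o00 + o11)
  double psi = std::atan2(o10 - o01, o00 + o11);
  double cs = std::cos(psi), sn = std::sin(psi);
  if (O_out != nullptr) {
    O_out[0] = cs; O_out[1] = sn; O_out[2] = -sn; O_out[3] = cs;  // column-major
    O_out[4] = o00; O_out[5] = o10; O_out[6] = o01; O_out[7] = o11; // raw, sign-fixed
  }
  return std::atan2(-sn, cs); // chi = atan2(O[0,1], O[0,0]) = -psi
}

// ---------------------------------------------------------------------------
// Spin rotations
// ---------------------------------------------------------------------------

// Rotate S about axis w/|w| by angle |w|*dt (Rodrigues; exact, norm-preserving).
static void rotate_spin(double* S, const double* w, double dt) {
  double nw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (nw == 0.0 || dt == 0.0) return;
  double kx = w[0] / nw, ky = w[1] / nw, kz = w[2] / nw;
  double th = nw * dt;
  double ct = std::cos(th), st = std::sin(th);
  double dotkS = kx * S[0] + ky * S[1] + kz * S[2];
  double cx = ky * S[2] - kz * S[1];
  double cy = kz * S[0] - kx * S[2];
  double cz = kx * S[1] - ky * S[0];
  double om = 1.0 - ct;
  double Sx = S[0] * ct + cx * st + kx * dotkS * om;
  double Sy = S[1] * ct + cy * st + ky * dotkS * om;
  double Sz = S[2] * ct + cz * st + kz * dotkS * om;
  S[0] = Sx; S[1] = Sy; S[2] = Sz;
}

static void rotate_y(double* S, double angle) {
  double w[3] = { 0.0, 1.0, 0.0 };
  rotate_spin(S, w, angle);
}

// ---------------------------------------------------------------------------
// Hop energetics: rescale along the mass-weighted NAC or reflect
// ---------------------------------------------------------------------------

struct HopResult { bool accepted; double dp_norm; };

// p, S, active modified in place. el must be evaluated at the hop geometry.
static HopResult rescale_or_reflect(const Model& md, double* p, double* S,
                                    int& active, const Elec& el) {
  int F = md.F;
  static thread_local std::vector<double> dir;
  dir.resize(F);
  double nrm = 0.0;
  for (int j = 0; j < F; ++j) {
    dir[j] = el.d[j] / std::sqrt(md.mass[j]);
    nrm += dir[j] * dir[j];
  }
  nrm = std::sqrt(nrm);
  if (nrm == 0.0)
    stop("attempted hop with zero nonadiabatic coupling vector: direction undefined");
  double a = 0.0;
  for (int j = 0; j < F; ++j) {
    dir[j] /= nrm;
    a += (p[j] / std::sqrt(md.mass[j])) * dir[j];
  }
  double V_init = active == 1 ? el.V1 : el.V0;
  double V_fin  = active == 1 ? el.V0 : el.V1;
  double E_av = 0.5 * a * a + V_init;
  HopResult hr;
  if (E_av >= V_fin) {
    double anew = std::copysign(std::sqrt(2.0 * (E_av - V_fin)), a);
    for (int j = 0; j < F; ++j) p[j] += std::sqrt(md.mass[j]) * (anew - a) * dir[j];
    active = 1 - active;
    hr.accepted = true;
    hr.dp_norm = std::fabs(anew - a);
  } else {
    for (int j = 0; j < F; ++j) p[j] -= 2.0 * std::sqrt(md.mass[j]) * a * dir[j];
    S[2] = -S[2];
    hr.accepted = false;
    hr.dp_norm = 2.0 * std::fabs(a);
  }
  return hr;
}

// ---------------------------------------------------------------------------
// Propagation state and bookkeeping
// ---------------------------------------------------------------------------

struct State {
  std::vector<double> q, p;
  double S[3];
  int active;
  Elec el;  // electronic structure at q, sign-continuous
};

struct HopLog {
  std::vector<double> t, gap, dp;
  std::vector<int> kind;        // 0 accepted, 1 frustrated
  std::vector<int> iters;       // root-search propagations (rev-pc), else 0
  void add(double tt, bool acc, double g, double d, int it) {
    t.push_back(tt); kind.push_back(acc ? 0 : 1);
    gap.push_back(g); dp.push_back(d); iters.push_back(it);
  }
};

struct Sim {
  Model md;
  double xi;
  double swap_tol;
  int max_root_iters;
  int method;   // 0 asym,1 nonrev-nacs,2 nonrev-atdc,3 nonrev-ld,4 rev-nacs,5-7 rev-pc
};

static double energy_of(const Model& md, const State& st) {
  double ke = 0.0;
  for (int j = 0; j < md.F; ++j) ke += st.p[j] * st.p[j] / (2.0 * md.mass[j]);
  return ke + (st.active == 1 ? st.el.V1 : st.el.V0);
}

static void nac_generator(const Model& md, const Elec& el, const double* p, double* w) {
  double vd = 0.0;
  for (int j = 0; j < md.F; ++j) vd += (p[j] / md.mass[j]) * el.d[j];
  w[0] = 0.0; w[1] = -2.0 * vd; w[2] = el.gap;
}

// ---------------------------------------------------------------------------
// Standard step: velocity-Verlet + one full spin step (asym / nonrev variants)
// variant: 0 asym-nacs, 1 nonrev-nacs, 2 atdc, 3 ld
// If process_hop, an equator crossing triggers rescale/reflect at q(1).
// Returns true if a crossing was detected (before any hop processing).
// ---------------------------------------------------------------------------

static bool step_standard(const Sim& sim, State& st, double dt, int variant,
                          bool process_hop, double t_end, HopLog* hops) {
  const Model& md = sim.md;
  static thread_local Elec el0;
  static thread_local std::vector<double> v0;
  el0 = st.el;
  v0.resize(md.F);
  for (int j = 0; j < md.F; ++j) v0[j] = st.p[j] / md.mass[j];
  const std::vector<double>& Fa0 = st.active == 1 ? el0.F1 : el0.F0;
  for (int j = 0; j < md.F; ++j) st.p[j] += 0.5 * dt * Fa0[j];
  for (int j = 0; j < md.F; ++j) st.q[j] += dt * st.p[j] / md.mass[j];
  eval_elec(md, st.q.data(), el0.U, st.el);
  const std::vector<double>& Fa1 = st.active == 1 ? st.el.F1 : st.el.F0;
  for (int j = 0; j < md.F; ++j) st.p[j] += 0.5 * dt * Fa1[j];

  double w[3];
  if (variant == 0) {
    nac_generator(md, st.el, st.p.data(), w);
    rotate_spin(st.S, w, dt);
  } else if (variant == 1) {
    double vd0 = 0.0, vd1 = 0.0;
    for (int j = 0; j < md.F; ++j) {
      vd0 += v0[j] * el0.d[j];
      vd1 += (st.p[j] / md.mass[j]) * st.el.d[j];
    }
    w[0] = 0.0; w[1] = -(vd0 + vd1); w[2] = 0.5 * (el0.gap + st.el.gap);
    rotate_spin(st.S, w, dt);
  } else {
    double chi = overlap_chi(el0.U, st.el.U, nullptr, sim.swap_tol);
    if (variant == 2) {
      w[0] = 0.0; w[1] = -2.0 * chi / dt; w[2] = 0.5 * (el0.gap + st.el.gap);
      rotate_spin(st.S, w, dt);
    } else {
      double wz0[3] = { 0.0, 0.0, el0.gap }, wz1[3] = { 0.0, 0.0, st.el.gap };
      rotate_spin(st.S, wz0, 0.5 * dt);
      rotate_y(st.S, -2.0 * chi);
      rotate_spin(st.S, wz1, 0.5 * dt);
    }
  }

  // crossing: end-of-step hemisphere inconsistent with the active surface
  bool crossed = (st.S[2] != 0.0) && ((st.S[2] > 0.0) != (st.active == 1));
  if (crossed && process_hop) {
    HopResult hr = rescale_or_reflect(md, st.p.data(), st.S, st.active, st.el);
    if (hops) hops->add(t_end, hr.accepted, st.el.gap, hr.dp_norm, 0);
  }
  return crossed;
}

// ---------------------------------------------------------------------------
// rev-NACs: spin half-steps split analytically at equator crossings
// ---------------------------------------------------------------------------

// Rotate S for duration dur under the NAC generator at fixed geometry (elec
// el), interrupting the rotation exactly where Sz crosses zero to attempt a
// hop. Momentum (through v.d) and active surface update at each crossing.
static void spin_segment_with_hops(const Sim& sim, State& st, const Elec& el,
                                   double dur, double t_hop_base, HopLog* hops) {
  const Model& md = sim.md;
  double rem = dur;
  for (int guard = 0; guard < 16 && rem > 0.0; ++guard) {
    double w[3];
    nac_generator(md, el, st.p.data(), w);
    double nw = std::sqrt(w[1] * w[1] + w[2] * w[2]);
    if (nw == 0.0) return;
    double kx = 0.0, ky = w[1] / nw, kz = w[2] / nw;
    double Phi = nw * rem;
    // Sz(phi) = A + B cos(phi) + C sin(phi)
    double dotkS = ky * st.S[1] + kz * st.S[2];
    double A = kz * dotkS;
    double B = st.S[2] - A;
    double C = kx * st.S[1] - ky * st.S[0];
    double R = std::hypot(B, C);
    double eps = 1e-7 * Phi;
    double phi_star = -1.0;
    if (R >= std::fabs(A) && R > 0.0) {
      double delta = std::atan2(C, B);
      double base = std::acos(std::max(-1.0, std::min(1.0, -A / R)));
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double root0 = delta + sgn * base;
        // smallest k with root0 + k*2pi > eps
        double k = std::ceil((eps - root0) / TWO_PI);
        double cand = root0 + k * TWO_PI;
        if (cand <= Phi) {
          double slope = -B * std::sin(cand) + C * std::cos(cand);
          if (std::fabs(slope) > 1e-14 && (phi_star < 0.0 || cand < phi_star))
            phi_star = cand;
        }
      }
    }
    if (phi_star < 0.0) {
      rotate_spin(st.S, w, rem);
      return;
    }
    rotate_spin(st.S, w, phi_star / nw);
    st.S[2] = 0.0;  // land exactly on the equator (|Sz| ~ round-off here)
    rem -= phi_star / nw;
    HopResult hr = rescale_or_reflect(md, st.p.data(), st.S, st.active, el);
    if (hops) hops->add(t_hop_base + (dur - rem), hr.accepted, el.gap, hr.dp_norm, 0);
  }
  if (rem > 0.0)
    stop("more than 16 equator crossings within one spin half-step; reduce the time-step");
}

static void step_rev_nacs(const Sim& sim, State& st, double dt, double t_start,
                          HopLog* hops) {
  const Model& md = sim.md;
  Elec el0 = st.el;
  spin_segment_with_hops(sim, st, el0, 0.5 * dt, t_start, hops);
  const std::vector<double>& Fa0 = st.active == 1 ? el0.F1 : el0.F0;
  for (int j = 0; j < md.F; ++j) st.p[j] += 0.5 * dt * Fa0[j];
  for (int j = 0; j < md.F; ++j) st.q[j] += dt * st.p[j] / md.mass[j];
  eval_elec(md, st.q.data(), el0.U, st.el);
  const std::vector<double>& Fa1 = st.active == 1 ? st.el.F1 : st.el.F0;
  for (int j = 0; j < md.F; ++j) st.p[j] += 0.5 * dt * Fa1[j];
  spin_segment_with_hops(sim, st, st.el, 0.5 * dt, t_start + 0.5 * dt, hops);
}

// pool of reusable State buffers (indexed by recursion depth) so the
// per-step trial propagations do not allocate
static State& scratch_state(int i) {
  static thread_local std::vector<State> pool(64);
  return pool[i];
}

// ---------------------------------------------------------------------------
// Reversible piecewise-continuous steps: root search for the hop time tau
// ---------------------------------------------------------------------------

// Newton divided-difference interpolation through up to 4 (tau, Sz) points.
struct Interp {
  std::vector<double> x, coef;
  void fit(std::vector<std::pair<double, double>> pts) {
    size_t n = pts.size();
    x.resize(n); coef.resize(n);
    std::vector<double> f(n);
    for (size_t i = 0; i < n; ++i) { x[i] = pts[i].first; f[i] = pts[i].second; }
    for (size_t lvl = 0; lvl < n; ++lvl) {
      coef[lvl] = f[0];
      for (size_t i = 0; i + lvl + 1 < n + 0; ++i)
        f[i] = (f[i + 1] - f[i]) / (x[i + lvl + 1] - x[i]);
    }
  }
  double eval(double t) const {
    double acc = 0.0;
    for (size_t i = coef.size(); i-- > 0;)
      acc = acc * (t - x[i]) + coef[i];
    return acc;
  }
};

// Bisection root of the interpolant on [lo, hi] (values flo, fhi of opposite sign).
static double interp_root(const Interp& ip, double lo, double hi, double flo) {
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (lo + hi);
    double fm = ip.eval(mid);
    if (fm == 0.0) return mid;
    if ((fm > 0.0) == (flo > 0.0)) { lo = mid; flo = fm; }
    else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// Find the hop time within (0, dt) for a trial step that detected a crossing.
// Returns the converged tau, the state propagated to tau, and the number of
// sub-step propagations used.
static double find_tau(const Sim& sim, const State& st0, double dt, int variant,
                       double s1, State& at_tau, int& iters) {
  double s0 = st0.S[2];
  if (s0 == 0.0) s0 = st0.active == 1 ? 1e-300 : -1e-300;
  if ((s0 > 0.0) == (s1 > 0.0)) {
    // no bracket: the crossing sits at the very start of the step (the
    // previous step ended inside the xi band); hop at tau = 0
    at_tau = st0;
    iters = 0;
    return 0.0;
  }
  double lo = 0.0, hi = dt, flo = s0;
  std::vector<std::pair<double, double>> pts = { { 0.0, s0 }, { dt, s1 } };
  double tau = dt * s0 / (s0 - s1);
  if (!(tau > 0.0 && tau < dt)) tau = 0.5 * dt;
  iters = 0;
  for (int k = 0; k < sim.max_root_iters; ++k) {
    at_tau = st0;
    step_standard(sim, at_tau, tau, variant, false, 0.0, nullptr);
    ++iters;
    double sz = at_tau.S[2];
    if (std::fabs(sz) <= sim.xi) return tau;
    pts.push_back({ tau, sz });
    if ((sz > 0.0) == (flo > 0.0)) { lo = tau; flo = sz; }
    else hi = tau;
    if (hi - lo <= 1e-13 * dt) return tau;  // Sz jumps across zero here: tau is exact
    // interpolate through <= 4 points nearest the current bracket
    std::vector<std::pair<double, double>> sel = pts;
    std::sort(sel.begin(), sel.end());
    if (sel.size() > 4) {
      double mid = 0.5 * (lo + hi);
      std::sort(sel.begin(), sel.end(),
                [mid](const std::pair<double, double>& a, const std::pair<double, double>& b) {
                  return std::fabs(a.first - mid) < std::fabs(b.first - mid);
                });
      sel.resize(4);
      std::sort(sel.begin(), sel.end());
    }
    Interp ip;
    ip.fit(sel);
    double cand = interp_root(ip, lo, hi, flo);
    if (!(cand > lo && cand < hi) || !std::isfinite(cand)) cand = 0.5 * (lo + hi);
    // safeguard: a root estimate glued to a bracket edge stalls the search
    double width = hi - lo;
    if (cand - lo < 0.05 * width || hi - cand < 0.05 * width) cand = 0.5 * (lo + hi);
    tau = cand;
  }
  at_tau = st0;
  step_standard(sim, at_tau, tau, variant, false, 0.0, nullptr);
  stop("hop-time root search did not converge in %d iterations (|Sz| = %.3e, xi = %.3e)",
       sim.max_root_iters, std::fabs(at_tau.S[2]), sim.xi);
  return tau; // unreachable
}

static void step_rev_pc(const Sim& sim, State& st, double dt, double t_start,
                        HopLog* hops, int depth) {
  int variant = sim.method - 4; // 5,6,7 -> 1 (nacs avg), 2 (atdc), 3 (ld)
  if (depth > 6)
    stop("piecewise-continuous step: recursive subdivision exceeded depth 6");
  // hemisphere already inconsistent at the start of the step (can happen when
  // the previous step ended inside the xi band): hop at the current geometry
  if ((st.S[2] != 0.0) && ((st.S[2] > 0.0) != (st.active == 1)) &&
      std::fabs(st.S[2]) > sim.xi) {
    HopResult hr = rescale_or_reflect(sim.md, st.p.data(), st.S, st.active, st.el);
    if (hops) hops->add(t_start, hr.accepted, st.el.gap, hr.dp_norm, 0);
  }
  State& trial = scratch_state(3 * depth);
  trial = st;
  bool crossed = step_standard(sim, trial, dt, variant, false, 0.0, nullptr);
  if (!crossed) { st = trial; return; }
  int iters = 0;
  State& at_tau = scratch_state(3 * depth + 1);
  double tau = find_tau(sim, st, dt, variant, trial.S[2], at_tau, iters);
  HopResult hr = rescale_or_reflect(sim.md, at_tau.p.data(), at_tau.S,
                                    at_tau.active, at_tau.el);
  if (hops) hops->add(t_start + tau, hr.accepted, at_tau.el.gap, hr.dp_norm, iters);
  double rem = dt - tau;
  State& s2 = scratch_state(3 * depth + 2);
  s2 = at_tau;
  step_standard(sim, s2, rem, variant, false, 0.0, nullptr);
  bool again = (s2.S[2] != 0.0) && ((s2.S[2] > 0.0) != (s2.active == 1)) &&
    std::fabs(s2.S[2]) > sim.xi;
  if (!again) { st = s2; return; }
  // rare second crossing inside the remainder: recursively halve it
  st = at_tau;
  step_rev_pc(sim, st, 0.5 * rem, t_start + tau, hops, depth + 1);
  step_rev_pc(sim, st, 0.5 * rem, t_start + tau + 0.5 * rem, hops, depth + 1);
}

// ---------------------------------------------------------------------------
// One full step of the chosen method (possibly subdivided for variable dt)
// ---------------------------------------------------------------------------

static void do_step(const Sim& sim, State& st, double dt, double t_start, HopLog* hops) {
  switch (sim.method) {
  case 0: case 1: case 2: case 3:
    step_standard(sim, st, dt, sim.method, true, t_start + dt, hops);
    break;
  case 4:
    step_rev_nacs(sim, st, dt, t_start, hops);
    break;
  default:
    step_rev_pc(sim, st, dt, t_start, hops, 0);
  }
}

static void do_step_adaptive(const Sim& sim, State& st, double dt, double t_start,
                             HopLog* hops, double e_tol, int depth,
                             std::vector<double>* leaf_dt) {
  if (e_tol <= 0.0 || depth >= 24) {
    do_step(sim, st, dt, t_start, hops);
    if (leaf_dt) leaf_dt->push_back(dt);
    return;
  }
  State& backup = scratch_state(24 + depth);
  backup = st;
  size_t nh = hops ? hops->t.size() : 0;
  double e0 = energy_of(sim.md, st);
  do_step(sim, st, dt, t_start, hops);
  if (std::fabs(energy_of(sim.md, st) - e0) <= e_tol) {
    if (leaf_dt) leaf_dt->push_back(dt);
    return;
  }
  st = backup;  // undo and bisect (dynamics are deterministic)
  if (hops) {
    hops->t.resize(nh); hops->kind.resize(nh); hops->gap.resize(nh);
    hops->dp.resize(nh); hops->iters.resize(nh);
  }
  do_step_adaptive(sim, st, 0.5 * dt, t_start, hops, e_tol, depth + 1, leaf_dt);
  do_step_adaptive(sim, st, 0.5 * dt, t_start + 0.5 * dt, hops, e_tol, depth + 1, leaf_dt);
}

// ---------------------------------------------------------------------------
// Exported interface
// ---------------------------------------------------------------------------

static int method_code(const std::string& m) {
  if (m == "asym-nacs") return 0;
  if (m == "nonrev-nacs") return 1;
  if (m == "nonrev-atdc") return 2;
  if (m == "nonrev-ld") return 3;
  if (m == "rev-nacs") return 4;
  if (m == "rev-pc-nacs") return 5;
  if (m == "rev-pc-atdc") return 6;
  if (m == "rev-pc-ld") return 7;
  stop("unknown method '%s'", m.c_str());
  return -1;
}

// [[Rcpp::export]]
List cpp_eval_diab(List model, NumericVector q) {
  Model md = parse_model(model);
  if ((int) q.size() != md.F) stop("q has length %d but the model has %d degrees of freedom",
                                   (int) q.size(), md.F);
  Diab de;
  eval_diab(md, q.begin(), de);
  NumericMatrix H(2, 2);
  H(0, 0) = de.h11; H(1, 1) = de.h22; H(0, 1) = H(1, 0) = de.h12;
  NumericMatrix dH(md.F, 3);
  for (int j = 0; j < md.F; ++j) {
    dH(j, 0) = de.d11[j]; dH(j, 1) = de.d22[j]; dH(j, 2) = de.d12[j];
  }
  colnames(dH) = CharacterVector::create("d11", "d22", "d12");
  return List::create(Named("H") = H, Named("dH") = dH);
}

// [[Rcpp::export]]
List cpp_adiabatize(List model, NumericVector q, Rcpp::Nullable<NumericMatrix> U_ref) {
  Model md = parse_model(model);
  if ((int) q.size() != md.F) stop("q has length %d but the model has %d degrees of freedom",
                                   (int) q.size(), md.F);
  Elec el;
  if (U_ref.isNotNull()) {
    NumericMatrix ur(U_ref);
    double uref[4] = { ur(0, 0), ur(1, 0), ur(0, 1), ur(1, 1) };
    eval_elec(md, q.begin(), uref, el);
  } else {
    eval_elec(md, q.begin(), nullptr, el);
  }
  NumericMatrix U(2, 2);
  U(0, 0) = el.U[0]; U(1, 0) = el.U[1]; U(0, 1) = el.U[2]; U(1, 1) = el.U[3];
  return List::create(
    Named("V0") = el.V0, Named("V1") = el.V1, Named("gap") = el.gap,
    Named("F0") = NumericVector(el.F0.begin(), el.F0.end()),
    Named("F1") = NumericVector(el.F1.begin(), el.F1.end()),
    Named("d") = NumericVector(el.d.begin(), el.d.end()),
    Named("U") = U);
}

// [[Rcpp::export]]
List cpp_overlap(NumericMatrix U_prev, NumericMatrix U_next, double dt, double swap_tol) {
  double U0[4] = { U_prev(0, 0), U_prev(1, 0), U_prev(0, 1), U_prev(1, 1) };
  double U1[4] = { U_next(0, 0), U_next(1, 0), U_next(0, 1), U_next(1, 1) };
  double buf[8];
  double chi = overlap_chi(U0, U1, buf, swap_tol);
  NumericMatrix O(2, 2), Oraw(2, 2);
  O(0, 0) = buf[0]; O(1, 0) = buf[1]; O(0, 1) = buf[2]; O(1, 1) = buf[3];
  Oraw(0, 0) = buf[4]; Oraw(1, 0) = buf[5]; Oraw(0, 1) = buf[6]; Oraw(1, 1) = buf[7];
  return List::create(Named("O_raw") = Oraw, Named("O") = O,
                      Named("chi_wf") = chi, Named("dt") = dt);
}

// [[Rcpp::export]]
NumericVector cpp_rotate(NumericVector S, NumericVector omega, double dt) {
  double s[3] = { S[0], S[1], S[2] };
  double w[3] = { omega[0], omega[1], omega[2] };
  rotate_spin(s, w, dt);
  return NumericVector::create(s[0], s[1], s[2]);
}

// [[Rcpp::export]]
List cpp_rescale_or_reflect(List model, NumericVector q, NumericVector p,
                            NumericVector S, int active) {
  Model md = parse_model(model);
  Elec el;
  eval_elec(md, q.begin(), nullptr, el);
  std::vector<double> pp(p.begin(), p.end());
  double s[3] = { S[0], S[1], S[2] };
  int act = active;
  HopResult hr = rescale_or_reflect(md, pp.data(), s, act, el);
  return List::create(
    Named("p") = NumericVector(pp.begin(), pp.end()),
    Named("S") = NumericVector::create(s[0], s[1], s[2]),
    Named("active") = act,
    Named("kind") = std::string(hr.accepted ? "accepted" : "frustrated"),
    Named("gap") = el.gap, Named("dp_norm") = hr.dp_norm);
}

// [[Rcpp::export]]
List cpp_propagate(List model, NumericVector q0, NumericVector p0, NumericVector S0,
                   std::string method, double dt, int nsteps, int record_every,
                   double xi, int max_root_iters, double e_tol, double t0,
                   double swap_tol) {
  if (dt <= 0.0) stop("cpp_propagate requires dt > 0 (backward runs flip p and Sy)");
  if (record_every < 1) record_every = 1;
  Sim sim;
  sim.md = parse_model(model);
  sim.xi = xi;
  sim.swap_tol = swap_tol;
  sim.max_root_iters = max_root_iters;
  sim.method = method_code(method);
  const Model& md = sim.md;
  if ((int) q0.size() != md.F || (int) p0.size() != md.F)
    stop("q0/p0 must have length %d (model degrees of freedom)", md.F);

  State st;
  st.q.assign(q0.begin(), q0.end());
  st.p.assign(p0.begin(), p0.end());
  st.S[0] = S0[0]; st.S[1] = S0[1]; st.S[2] = S0[2];
  double nS = std::sqrt(st.S[0]*st.S[0] + st.S[1]*st.S[1] + st.S[2]*st.S[2]);
  if (std::fabs(nS - 1.0) > 1e-8)
    stop("initial spin vector must have unit norm (got %.8f)", nS);
  st.active = st.S[2] > 0.0 ? 1 : 0;
  eval_elec(md, st.q.data(), nullptr, st.el);

  int nrec = nsteps / record_every + 1 + (nsteps % record_every != 0 ? 1 : 0);
  NumericVector t_out(nrec), E_out(nrec), theta_out(nrec);
  NumericMatrix Q(nrec, md.F), P(nrec, md.F), Sp(nrec, 3);
  IntegerVector act_out(nrec);
  HopLog hops;
  std::vector<double> leaf_dt;
  bool variable = e_tol > 0.0;

  int irec = 0;
  auto record = [&](int step) {
    t_out[irec] = t0 + step * dt;
    for (int j = 0; j < md.F; ++j) { Q(irec, j) = st.q[j]; P(irec, j) = st.p[j]; }
    Sp(irec, 0) = st.S[0]; Sp(irec, 1) = st.S[1]; Sp(irec, 2) = st.S[2];
    act_out[irec] = st.active;
    E_out[irec] = energy_of(md, st);
    theta_out[irec] = std::atan2(st.el.U[1], st.el.U[0]);
    ++irec;
  };
  record(0);
  for (int k = 0; k < nsteps; ++k) {
    double t_start = t0 + k * dt;
    if (variable)
      do_step_adaptive(sim, st, dt, t_start, &hops, e_tol, 0, &leaf_dt);
    else
      do_step(sim, st, dt, t_start, &hops);
    if ((k + 1) % record_every == 0 || k + 1 == nsteps) record(k + 1);
  }

  List hop_list = List::create(
    Named("t") = NumericVector(hops.t.begin(), hops.t.end()),
    Named("kind") = IntegerVector(hops.kind.begin(), hops.kind.end()),
    Named("gap") = NumericVector(hops.gap.begin(), hops.gap.end()),
    Named("dp_norm") = NumericVector(hops.dp.begin(), hops.dp.end()),
    Named("root_iters") = IntegerVector(hops.iters.begin(), hops.iters.end()));
  return List::create(
    Named("t") = t_out, Named("q") = Q, Named("p") = P, Named("S") = Sp,
    Named("active") = act_out, Named("energy") = E_out, Named("theta") = theta_out,
    Named("hops") = hop_list,
    Named("step_sizes") = NumericVector(leaf_dt.begin(), leaf_dt.end()));
}
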