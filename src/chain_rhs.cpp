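#include <Rcpp.h>
using namespace Rcpp;

// Right-hand sides of the chain-link swimmer equations of motion.
// State layout (length 6N): x, y, theta, vx, vy, omega, each of length N.
// Axes: x axial, y transverse, theta counterclockwise from +x.
//
// model 0: nonlinear Newton-Euler chain with penalty joint springs.
// model 1: leading-order (small-theta) equations; transverse/rotational
//          dynamics are linear and drive the axial equation through the
//          (CN - CT) * v * theta cross term.  Optional external transverse
//          flow enters through relative-velocity drag.

namespace {

// 5-point Gauss-Legendre nodes/weights on [-1, 1]
const double GX[5] = {-0.9061798459386640, -0.5384693101056831, 0.0,
                      0.5384693101056831, 0.9061798459386640};
const double GW[5] = {0.2369268850561891, 0.4786286704993665,
                      0.5688888888888889, 0.4786286704993665,
                      0.2369268850561891};

struct Parms {
  int N, model, dragv, act;
  double ell, m, I, k, cj, EI, delta;
  double rho, r, Cf, Ct;        // taylor
  double CN, CT;                // linear drag
  double B, lam, f;             // traveling wave
  double g0, g1, g2, g3, gtau, gT, gL;  // gait cubic amp + phase params
  double ramp_t;
  bool flow_on;
  double Vf, lamf, ff, flowdir;
  NumericMatrix tab;            // tabulated kappa0 (n_t x N-1)
  double tab_period;
  bool has_tab;
};

Parms read_parms(const List& P) {
  Parms p;
  p.N = as<int>(P["N"]);
  p.model = as<int>(P["model"]);
  p.dragv = as<int>(P["dragv"]);
  p.act = as<int>(P["act"]);
  p.ell = as<double>(P["ell"]);
  p.m = as<double>(P["m"]);
  p.I = as<double>(P["I"]);
  p.k = as<double>(P["k"]);
  p.cj = as<double>(P["cj"]);
  p.EI = as<double>(P["EI"]);
  p.delta = as<double>(P["delta"]);
  p.rho = as<double>(P["rho"]);
  p.r = as<double>(P["r"]);
  p.Cf = as<double>(P["Cf"]);
  p.Ct = as<double>(P["Ct"]);
  p.CN = as<double>(P["CN"]);
  p.CT = as<double>(P["CT"]);
  p.B = as<double>(P["B"]);
  p.lam = as<double>(P["lam"]);
  p.f = as<double>(P["f"]);
  p.g0 = as<double>(P["g0"]);
  p.g1 = as<double>(P["g1"]);
  p.g2 = as<double>(P["g2"]);
  p.g3 = as<double>(P["g3"]);
  p.gtau = as<double>(P["gtau"]);
  p.gT = as<double>(P["gT"]);
  p.gL = as<double>(P["gL"]);
  p.ramp_t = as<double>(P["ramp_t"]);
  p.flow_on = as<bool>(P["flow_on"]);
  p.Vf = as<double>(P["Vf"]);
  p.lamf = as<double>(P["lamf"]);
  p.ff = as<double>(P["ff"]);
  p.flowdir = as<double>(P["flowdir"]);
  p.has_tab = as<bool>(P["has_tab"]);
  if (p.has_tab) {
    p.tab = as<NumericMatrix>(P["tab"]);
    p.tab_period = as<double>(P["tab_period"]);
  } else {
    p.tab_period = 1.0;
  }
  return p;
}

// preferred curvature at arclength station s and time t
double kappa0_at(const Parms& p, double s, double t, int joint) {
  double ramp = 1.0;
  if (p.ramp_t > 0 && t < p.ramp_t)
    ramp = 0.5 - 0.5 * std::cos(M_PI * t / p.ramp_t);
  switch (p.act) {
  case 1: {  // backward traveling wave h = B sin(2 pi (x/lam - f t))
    double ph = 2.0 * M_PI * (s / p.lam - p.f * t);
    return -ramp * p.B * std::pow(2.0 * M_PI / p.lam, 2) * std::sin(ph);
  }
  case 2: {  // gait family: cubic amplitude (1/cm) * traveling phase
    double amp = p.g0 + s * (p.g1 + s * (p.g2 + s * p.g3));
    return ramp * amp * std::sin(2.0 * M_PI * (t / p.gT - p.gtau * s / p.gL));
  }
  case 3: {  // tabulated periodic program
    int nt = p.tab.nrow();
    double tp = t / p.tab_period;
    double phase = tp - std::floor(tp);
    double pos = phase * nt;
    int i0 = (int)std::floor(pos);
    double w = pos - i0;
    i0 = i0 % nt;
    int i1 = (i0 + 1) % nt;
    return ramp * ((1.0 - w) * p.tab(i0, joint) + w * p.tab(i1, joint));
  }
  default:
    return 0.0;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector chain_rhs_cpp(double t, NumericVector y, List P) {
  Parms p = read_parms(P);
  const int N = p.N;
  const double ell = p.ell, h2 = 0.5 * p.ell;
  const double* x = y.begin();
  const double* yy = x + N;
  const double* th = x + 2 * N;
  const double* vx = x + 3 * N;
  const double* vy = x + 4 * N;
  const double* om = x + 5 * N;

  NumericVector dy(6 * N);
  double* dx = dy.begin();
  double* dyv = dx + N;
  double* dth = dx + 2 * N;
  double* dvx = dx + 3 * N;
  double* dvy = dx + 4 * N;
  double* dom = dx + 5 * N;

  for (int i = 0; i < 6 * N; ++i)
    if (!std::isfinite(y[i])) stop("non-finite state in RHS");

  // kinematics
  for (int i = 0; i < N; ++i) {
    dx[i] = vx[i];
    dyv[i] = vy[i];
    dth[i] = om[i];
  }

  // joint muscle/elastic moments, j = 0..N-2 at station (j+1)*ell
  std::vector<double> M(N - 1);
  for (int j = 0; j < N - 1; ++j) {
    double kap = (th[j + 1] - th[j]) / ell;
    double kdot = (om[j + 1] - om[j]) / ell;
    double k0 = kappa0_at(p, (j + 1) * ell, t, j);
    M[j] = p.EI * (k0 - kap) - p.delta * kdot;
  }

  if (p.model == 0) {  // ---- nonlinear penalty-method chain ----
    std::vector<double> c(N), s(N);
    for (int i = 0; i < N; ++i) { c[i] = std::cos(th[i]); s[i] = std::sin(th[i]); }
    std::vector<double> Fjx(N - 1), Fjy(N - 1);
    for (int j = 0; j < N - 1; ++j) {
      double gx = x[j + 1] - x[j] - h2 * (c[j] + c[j + 1]);
      double gy = yy[j + 1] - yy[j] - h2 * (s[j] + s[j + 1]);
      // gap-rate damper in parallel with the penalty spring
      double gxd = vx[j + 1] - vx[j] + h2 * (s[j] * om[j] + s[j + 1] * om[j + 1]);
      double gyd = vy[j + 1] - vy[j] - h2 * (c[j] * om[j] + c[j + 1] * om[j + 1]);
      Fjx[j] = p.k * gx + p.cj * gxd;
      Fjy[j] = p.k * gy + p.cj * gyd;
    }
    for (int i = 0; i < N; ++i) {
      double vT = vx[i] * c[i] + vy[i] * s[i];
      double vN = -vx[i] * s[i] + vy[i] * c[i];
      double FT, FN, MZ;
      if (p.dragv == 0) {  // Taylor: quadratic, distributed along link
        double cN = 0.5 * p.rho * 2.0 * p.r * p.Cf;
        double cT = 0.5 * p.rho * 2.0 * p.r * p.Ct;
        FT = -cT * std::fabs(vT) * vT * ell;
        FN = 0.0; MZ = 0.0;
        for (int q = 0; q < 5; ++q) {
          double sq = h2 * GX[q], wq = h2 * GW[q];
          double vloc = vN + om[i] * sq;
          double fn = -cN * std::fabs(vloc) * vloc;
          FN += wq * fn;
          MZ += wq * fn * sq;
        }
      } else {             // linear (Lighthill) drag in the link frame
        FT = -p.CT * vT * ell;
        FN = -p.CN * vN * ell;
        MZ = -p.CN * ell * ell * ell / 12.0 * om[i];
      }
      double Fx = FT * c[i] - FN * s[i];
      double Fy = FT * s[i] + FN * c[i];
      double jr_x = (i < N - 1) ? Fjx[i] : 0.0;   // joint at right end
      double jr_y = (i < N - 1) ? Fjy[i] : 0.0;
      double jl_x = (i > 0) ? Fjx[i - 1] : 0.0;   // joint at left end
      double jl_y = (i > 0) ? Fjy[i - 1] : 0.0;
      double Mr = (i < N - 1) ? M[i] : 0.0;
      double Ml = (i > 0) ? M[i - 1] : 0.0;
      dvx[i] = (Fx + jr_x - jl_x) / p.m;
      dvy[i] = (Fy + jr_y - jl_y) / p.m;
      dom[i] = (h2 * (c[i] * (jr_y + jl_y) - s[i] * (jr_x + jl_x))
                + (-Mr + Ml) + MZ) / p.I;
    }
  } else {  // ---- leading-order equations ----
    const double cr = p.CN * ell * ell * ell / 12.0;
    std::vector<double> Fjx(N - 1), Fjy(N - 1);
    for (int j = 0; j < N - 1; ++j) {
      // axial gap keeps the O(theta^2) geometric contraction: u is O(theta^2)
      double gx = x[j + 1] - x[j] - ell
        + (ell / 4.0) * (th[j] * th[j] + th[j + 1] * th[j + 1]);
      double gy = yy[j + 1] - yy[j] - h2 * (th[j] + th[j + 1]);
      double gxd = vx[j + 1] - vx[j]
        + (ell / 2.0) * (th[j] * om[j] + th[j + 1] * om[j + 1]);
      double gyd = vy[j + 1] - vy[j] - h2 * (om[j] + om[j + 1]);
      Fjx[j] = p.k * gx + p.cj * gxd;
      Fjy[j] = p.k * gy + p.cj * gyd;
    }
    for (int i = 0; i < N; ++i) {
      double vfbar = 0.0, mom1 = 0.0;
      if (p.flow_on) {
        double b = 2.0 * M_PI / p.lamf;
        double a = 2.0 * M_PI * (x[i] / p.lamf - p.flowdir * p.ff * t);
        double sb = std::sin(b * h2), cb = std::cos(b * h2);
        vfbar = p.Vf * 2.0 * std::sin(a) * sb / (b * ell);
        mom1 = p.Vf * 2.0 * std::cos(a) * (sb / (b * b) - h2 * cb / b);
      }
      double jr_x = (i < N - 1) ? Fjx[i] : 0.0;
      double jr_y = (i < N - 1) ? Fjy[i] : 0.0;
      double jl_x = (i > 0) ? Fjx[i - 1] : 0.0;
      double jl_y = (i > 0) ? Fjy[i - 1] : 0.0;
      double Mr = (i < N - 1) ? M[i] : 0.0;
      double Ml = (i > 0) ? M[i - 1] : 0.0;
      double vrel = vy[i] - vfbar;
      dvy[i] = (-p.CN * ell * vrel + jr_y - jl_y) / p.m;
      dvx[i] = (-p.CT * ell * vx[i] + (p.CN - p.CT) * ell * th[i] * vrel
                + jr_x - jl_x) / p.m;
      dom[i] = (-cr * om[i] + p.CN * mom1 + h2 * (jr_y + jl_y)
                + (-Mr + Ml)) / p.I;
    }
  }
  return dy;
}

// Analytic Jacobian d(rhs)/d(state) for both models; used by the implicit
// (BDF) integrator.  Flow-field position dependence is omitted (the
// Jacobian is a Newton preconditioner there, not the propagated dynamics).
// [[Rcpp::export]]
NumericMatrix chain_jac_cpp(double t, NumericVector y, List P) {
  Parms p = read_parms(P);
  const int N = p.N;
  const double ell = p.ell, h2 = 0.5 * p.ell;
  const double m = p.m, I = p.I, k = p.k, cj = p.cj;
  const int X = 0, Y = N, TH = 2 * N, VX = 3 * N, VY = 4 * N, OM = 5 * N;
  const double* x = y.begin();
  const double* th = x + TH;
  const double* vx = x + VX;
  const double* vy = x + VY;
  const double* om = x + OM;
  (void)x;
  NumericMatrix J(6 * N, 6 * N);

  for (int i = 0; i < N; ++i) {
    J(X + i, VX + i) = 1.0;
    J(Y + i, VY + i) = 1.0;
    J(TH + i, OM + i) = 1.0;
  }

  // muscle moment derivatives: M_j w.r.t. theta_j.. and omega_j..
  const double dM_th = p.EI / ell;     // dM_j/dtheta_j (and -... for j+1)
  const double dM_om = p.delta / ell;  // dM_j/domega_j

  // accumulate dM contributions into dom rows: link i gets (-M_i + M_{i-1})/I
  for (int j = 0; j < N - 1; ++j) {
    // -M_j enters row OM+j ; +M_j enters row OM+j+1
    J(OM + j, TH + j)     += -dM_th / I;
    J(OM + j, TH + j + 1) += +dM_th / I;
    J(OM + j, OM + j)     += -dM_om / I;
    J(OM + j, OM + j + 1) += +dM_om / I;
    J(OM + j + 1, TH + j)     += +dM_th / I;
    J(OM + j + 1, TH + j + 1) += -dM_th / I;
    J(OM + j + 1, OM + j)     += +dM_om / I;
    J(OM + j + 1, OM + j + 1) += -dM_om / I;
  }

  if (p.model == 1) {  // ---- leading order ----
    const double cr = p.CN * ell * ell * ell / 12.0;
    for (int i = 0; i < N; ++i) {
      J(VY + i, VY + i) += -p.CN * ell / m;
      J(VX + i, VX + i) += -p.CT * ell / m;
      J(VX + i, TH + i) += (p.CN - p.CT) * ell * vy[i] / m;
      J(VX + i, VY + i) += (p.CN - p.CT) * ell * th[i] / m;
      J(OM + i, OM + i) += -cr / I;
    }
    for (int j = 0; j < N - 1; ++j) {
      // dFjx_j / d(state): columns and values
      int cx[6] = {X + j, X + j + 1, TH + j, TH + j + 1, VX + j, VX + j + 1};
      double fx[6] = {-k, k,
                      k * (ell / 2) * th[j] + cj * (ell / 2) * om[j],
                      k * (ell / 2) * th[j + 1] + cj * (ell / 2) * om[j + 1],
                      -cj, cj};
      int cx2[2] = {OM + j, OM + j + 1};
      double fx2[2] = {cj * (ell / 2) * th[j], cj * (ell / 2) * th[j + 1]};
      // dFjy_j
      int cy[6] = {Y + j, Y + j + 1, TH + j, TH + j + 1, VY + j, VY + j + 1};
      double fy[6] = {-k, k, -k * h2, -k * h2, -cj, cj};
      int cy2[2] = {OM + j, OM + j + 1};
      double fy2[2] = {-cj * h2, -cj * h2};
      // Fjx enters dvx rows: +1/m for link j, -1/m for ... link j gets +Fjx_j
      // (right joint), link j+1 gets -Fjx_j (left joint)
      for (int q = 0; q < 6; ++q) {
        J(VX + j, cx[q]) += fx[q] / m;
        J(VX + j + 1, cx[q]) -= fx[q] / m;
      }
      for (int q = 0; q < 2; ++q) {
        J(VX + j, cx2[q]) += fx2[q] / m;
        J(VX + j + 1, cx2[q]) -= fx2[q] / m;
      }
      for (int q = 0; q < 6; ++q) {
        J(VY + j, cy[q]) += fy[q] / m;
        J(VY + j + 1, cy[q]) -= fy[q] / m;
        // spring moment: dom_i += h2 * (Fjy at both ends) / I
        J(OM + j, cy[q]) += h2 * fy[q] / I;
        J(OM + j + 1, cy[q]) += h2 * fy[q] / I;
      }
      for (int q = 0; q < 2; ++q) {
        J(VY + j, cy2[q]) += fy2[q] / m;
        J(VY + j + 1, cy2[q]) -= fy2[q] / m;
        J(OM + j, cy2[q]) += h2 * fy2[q] / I;
        J(OM + j + 1, cy2[q]) += h2 * fy2[q] / I;
      }
    }
  } else {  // ---- nonlinear ----
    std::vector<double> c(N), s(N);
    for (int i = 0; i < N; ++i) { c[i] = std::cos(th[i]); s[i] = std::sin(th[i]); }
    // joint forces (needed for the moment-arm theta derivatives)
    std::vector<double> Fjx(N - 1), Fjy(N - 1);
    for (int j = 0; j < N - 1; ++j) {
      double gx = y[X + j + 1] - y[X + j] - h2 * (c[j] + c[j + 1]);
      double gy = y[Y + j + 1] - y[Y + j] - h2 * (s[j] + s[j + 1]);
      double gxd = vx[j + 1] - vx[j] + h2 * (s[j] * om[j] + s[j + 1] * om[j + 1]);
      double gyd = vy[j + 1] - vy[j] - h2 * (c[j] * om[j] + c[j + 1] * om[j + 1]);
      Fjx[j] = k * gx + cj * gxd;
      Fjy[j] = k * gy + cj * gyd;
    }
    // drag derivatives per link
    for (int i = 0; i < N; ++i) {
      double vT = vx[i] * c[i] + vy[i] * s[i];
      double vN = -vx[i] * s[i] + vy[i] * c[i];
      double FT, FN, MZ, dFT, dFN, dFN_om, dMZ_vN, dMZ_om;
      if (p.dragv == 0) {
        double cN = 0.5 * p.rho * 2.0 * p.r * p.Cf;
        double cT = 0.5 * p.rho * 2.0 * p.r * p.Ct;
        FT = -cT * std::fabs(vT) * vT * ell;
        dFT = -2.0 * cT * std::fabs(vT) * ell;
        FN = 0.0; MZ = 0.0; dFN = 0.0; dFN_om = 0.0; dMZ_vN = 0.0; dMZ_om = 0.0;
        for (int q = 0; q < 5; ++q) {
          double sq = h2 * GX[q], wq = h2 * GW[q];
          double vloc = vN + om[i] * sq;
          double g = -2.0 * cN * std::fabs(vloc);
          FN += wq * (-cN * std::fabs(vloc) * vloc);
          MZ += wq * (-cN * std::fabs(vloc) * vloc) * sq;
          dFN += wq * g;
          dFN_om += wq * g * sq;
          dMZ_vN += wq * g * sq;
          dMZ_om += wq * g * sq * sq;
        }
      } else {
        FT = -p.CT * vT * ell;   dFT = -p.CT * ell;
        FN = -p.CN * vN * ell;   dFN = -p.CN * ell;
        MZ = -p.CN * ell * ell * ell / 12.0 * om[i];
        dFN_om = 0.0; dMZ_vN = 0.0;
        dMZ_om = -p.CN * ell * ell * ell / 12.0;
      }
      double ci = c[i], si = s[i];
      // dvT/d(vx,vy,theta) = (ci, si, vN); dvN/d = (-si, ci, -vT)
      // Fx = FT*ci - FN*si ; Fy = FT*si + FN*ci
      double dFx_vx = dFT * ci * ci + dFN * si * si;
      double dFx_vy = dFT * ci * si - dFN * si * ci;
      double dFy_vx = dFT * si * ci - dFN * ci * si;
      double dFy_vy = dFT * si * si + dFN * ci * ci;
      double dFx_th = dFT * vN * ci - dFN * (-vT) * si + (-FT * si - FN * ci);
      double dFy_th = dFT * vN * si + dFN * (-vT) * ci + (FT * ci - FN * si);
      double dFx_om = -dFN_om * si;
      double dFy_om = dFN_om * ci;
      J(VX + i, VX + i) += dFx_vx / m;
      J(VX + i, VY + i) += dFx_vy / m;
      J(VX + i, TH + i) += dFx_th / m;
      J(VX + i, OM + i) += dFx_om / m;
      J(VY + i, VX + i) += dFy_vx / m;
      J(VY + i, VY + i) += dFy_vy / m;
      J(VY + i, TH + i) += dFy_th / m;
      J(VY + i, OM + i) += dFy_om / m;
      J(OM + i, VX + i) += dMZ_vN * (-si) / I;
      J(OM + i, VY + i) += dMZ_vN * (ci) / I;
      J(OM + i, TH + i) += dMZ_vN * (-vT) / I;
      J(OM + i, OM + i) += dMZ_om / I;
    }
    // joint force derivatives and moment arms
    for (int j = 0; j < N - 1; ++j) {
      int col_x[2] = {X + j, X + j + 1};
      int col_y[2] = {Y + j, Y + j + 1};
      int col_t[2] = {TH + j, TH + j + 1};
      int col_vx[2] = {VX + j, VX + j + 1};
      int col_vy[2] = {VY + j, VY + j + 1};
      int col_o[2] = {OM + j, OM + j + 1};
      double dFjx_x[2] = {-k, k};
      double dFjx_t[2] = {k * h2 * s[j] + cj * h2 * c[j] * om[j],
                          k * h2 * s[j + 1] + cj * h2 * c[j + 1] * om[j + 1]};
      double dFjx_vx[2] = {-cj, cj};
      double dFjx_o[2] = {cj * h2 * s[j], cj * h2 * s[j + 1]};
      double dFjy_y[2] = {-k, k};
      double dFjy_t[2] = {-k * h2 * c[j] + cj * h2 * s[j] * om[j],
                          -k * h2 * c[j + 1] + cj * h2 * s[j + 1] * om[j + 1]};
      double dFjy_vy[2] = {-cj, cj};
      double dFjy_o[2] = {-cj * h2 * c[j], -cj * h2 * c[j + 1]};
      // rows affected: vx/vy of links j (+) and j+1 (-); om of both links
      for (int q = 0; q < 2; ++q) {
        // translational
        J(VX + j, col_x[q]) += dFjx_x[q] / m;
        J(VX + j + 1, col_x[q]) -= dFjx_x[q] / m;
        J(VX + j, col_t[q]) += dFjx_t[q] / m;
        J(VX + j + 1, col_t[q]) -= dFjx_t[q] / m;
        J(VX + j, col_vx[q]) += dFjx_vx[q] / m;
        J(VX + j + 1, col_vx[q]) -= dFjx_vx[q] / m;
        J(VX + j, col_o[q]) += dFjx_o[q] / m;
        J(VX + j + 1, col_o[q]) -= dFjx_o[q] / m;
        J(VY + j, col_y[q]) += dFjy_y[q] / m;
        J(VY + j + 1, col_y[q]) -= dFjy_y[q] / m;
        J(VY + j, col_t[q]) += dFjy_t[q] / m;
        J(VY + j + 1, col_t[q]) -= dFjy_t[q] / m;
        J(VY + j, col_vy[q]) += dFjy_vy[q] / m;
        J(VY + j + 1, col_vy[q]) -= dFjy_vy[q] / m;
        J(VY + j, col_o[q]) += dFjy_o[q] / m;
        J(VY + j + 1, col_o[q]) -= dFjy_o[q] / m;
        // rotational: dom_i = h2*(c_i*(sum Fjy) - s_i*(sum Fjx))/I for both
        // links sharing joint j
        for (int li = 0; li < 2; ++li) {
          int row = OM + j + li;
          double cl = c[j + li], sl = s[j + li];
          J(row, col_y[q]) += h2 * cl * dFjy_y[q] / I;
          J(row, col_t[q]) += h2 * (cl * dFjy_t[q] - sl * dFjx_t[q]) / I;
          J(row, col_x[q]) += h2 * (-sl) * dFjx_x[q] / I;
          J(row, col_vy[q]) += h2 * cl * dFjy_vy[q] / I;
          J(row, col_vx[q]) += h2 * (-sl) * dFjx_vx[q] / I;
          J(row, col_o[q]) += h2 * (cl * dFjy_o[q] - sl * dFjx_o[q]) / I;
        }
      }
      // direct theta_i dependence of the moment arm trig factors
      for (int li = 0; li < 2; ++li) {
        int i = j + li;
        // this joint contributes Fjy[j], Fjx[j] to link i's arm sums
        J(OM + i, TH + i) += h2 * (-s[i] * Fjy[j] - c[i] * Fjx[j]) / I;
      }
    }
  }
  return J;
}
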