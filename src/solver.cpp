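// Two-step (Richtmyer) Lax-Wendroff solver for the 1D cross-sectionally
// averaged blood flow equations on a bifurcating vessel tree.
//
//   dA/dt + dQ/dx = 0
//   dQ/dt + d/dx[ (g+2)/(g+1) Q^2/A + B(A) ] = -2 pi mu (g+2)/rho * Q/A
//
// with the linear-elastic tube law P(A) = (4/3) f (sqrt(A/Adia) - 1) + Pdia,
// f = Eh/r0 constant per segment, which admits the exact pressure-flux
// potential B(A) = (4 f / (9 rho)) A^{3/2} / sqrt(Adia).
//
// Characteristic closure: with c(A) = c0 (A/Adia)^{1/4}, c0 = sqrt(2f/(3rho)),
// the Riemann invariants are W± = u ± 4c. Boundary nodes are closed by the
// outgoing invariant (linearly interpolated at the characteristic foot, with
// the friction source added along the path) plus the physical condition:
// prescribed inlet flow, junction flow conservation + pressure continuity,
// or the implicit-Euler RCR (Windkessel) relation.
//
// Units: CGS throughout (cm, s, dyn/cm2; Q in mL/s).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Vessel {
  int n;
  double dx, f, Adia, Pdia, c0;
  int child1, child2;  // vessel indices, -1 if terminal
  int wk;              // windkessel row index, -1 if internal
  std::vector<double> A, Q;       // current state
  std::vector<double> An, Qn;     // next state
  std::vector<double> F2, S2;     // node fluxes / sources
  std::vector<double> Ah, Qh;     // half-step states (n-1)
  std::vector<double> Pmax, Pmin, Amax, Amin;  // per-node cycle extrema
};

struct Solver {
  std::vector<Vessel> v;
  int root;
  double rho, mu, gam, qcoef, fric;
  // windkessel parameters per terminal row
  std::vector<double> Rp, Rd, Cc, Pout, Pc;
  // inflow: dense periodic table over [0, T)
  std::vector<double> qin;
  double T;
  double max_jun_res = 0.0;
  double inflow_vol = 0.0;
  std::vector<double> outlet_vol;

  double pres(const Vessel& s, double A) const {
    return (4.0 / 3.0) * s.f * (std::sqrt(A / s.Adia) - 1.0) + s.Pdia;
  }
  double dpda(const Vessel& s, double A) const {
    return (2.0 / 3.0) * s.f / std::sqrt(A * s.Adia);
  }
  double wspeed(const Vessel& s, double A) const {
    return s.c0 * std::pow(A / s.Adia, 0.25);
  }
  double flux2(const Vessel& s, double A, double Q) const {
    return qcoef * Q * Q / A +
           (4.0 * s.f / (9.0 * rho)) * A * std::sqrt(A) / std::sqrt(s.Adia);
  }
  double src2(double A, double Q) const { return -fric * Q / A; }

  double inflow_at(double t) const {
    double tau = t - T * std::floor(t / T);  // avoids fmod (glibc >= 2.38 symbol)
    double pos = tau / T * qin.size();
    int i = (int)pos;
    double w = pos - i;
    int j = (i + 1) % (int)qin.size();
    if (i >= (int)qin.size()) i = 0;
    return (1.0 - w) * qin[i] + w * qin[j];
  }

  // outgoing (+) invariant of segment s at its outlet, foot-interpolated
  double w_plus_star(const Vessel& s, double dt) const {
    int M = s.n - 1;
    double uM = s.Q[M] / s.A[M], cM = wspeed(s, s.A[M]);
    double th = (uM + cM) * dt / s.dx;
    if (th < 0) th = 0;
    if (th > 1) th = 1;
    double Af = s.A[M] - th * (s.A[M] - s.A[M - 1]);
    double Qf = s.Q[M] - th * (s.Q[M] - s.Q[M - 1]);
    double uf = Qf / Af;
    return uf + 4.0 * wspeed(s, Af) - dt * fric * uf / Af;
  }
  // outgoing (-) invariant of segment s at its inlet
  double w_minus_star(const Vessel& s, double dt) const {
    double u0 = s.Q[0] / s.A[0], c0v = wspeed(s, s.A[0]);
    double th = (c0v - u0) * dt / s.dx;
    if (th < 0) th = 0;
    if (th > 1) th = 1;
    double Af = s.A[0] + th * (s.A[1] - s.A[0]);
    double Qf = s.Q[0] + th * (s.Q[1] - s.Q[0]);
    double uf = Qf / Af;
    return uf - 4.0 * wspeed(s, Af) - dt * fric * uf / Af;
  }

  // solve k x k linear system in place (partial pivoting); b -> solution
  static bool lsolve(int k, double* J, double* b) {
    for (int col = 0; col < k; ++col) {
      int piv = col;
      for (int r = col + 1; r < k; ++r)
        if (std::fabs(J[r * k + col]) > std::fabs(J[piv * k + col])) piv = r;
      if (std::fabs(J[piv * k + col]) < 1e-300) return false;
      if (piv != col) {
        for (int c2 = 0; c2 < k; ++c2) std::swap(J[col * k + c2], J[piv * k + c2]);
        std::swap(b[col], b[piv]);
      }
      for (int r = col + 1; r < k; ++r) {
        double m = J[r * k + col] / J[col * k + col];
        for (int c2 = col; c2 < k; ++c2) J[r * k + c2] -= m * J[col * k + c2];
        b[r] -= m * b[col];
      }
    }
    for (int r = k - 1; r >= 0; --r) {
      double sum = b[r];
      for (int c2 = r + 1; c2 < k; ++c2) sum -= J[r * k + c2] * b[c2];
      b[r] = sum / J[r * k + r];
    }
    return true;
  }

  // inlet of root: prescribed Q, solve A from the (-) invariant
  bool inlet_bc(double t_new, double dt) {
    Vessel& s = v[root];
    double W2 = w_minus_star(s, dt);
    double Qb = inflow_at(t_new);
    double A = s.A[0];
    for (int it = 0; it < 60; ++it) {
      double c = wspeed(s, A);
      double r = Qb / A - 4.0 * c - W2;
      double dr = -Qb / (A * A) - c / A;
      double step = r / dr;
      double Anew = A - step;
      if (Anew <= 0) Anew = 0.5 * A;
      A = Anew;
      if (std::fabs(r) < 1e-12 * (std::fabs(W2) + 1.0)) break;
    }
    if (!(A > 0) || !std::isfinite(A)) return false;
    s.An[0] = A;
    s.Qn[0] = Qb;
    return true;
  }

  // terminal outlet: (+) invariant + implicit RCR
  bool outlet_bc(int iv, double dt) {
    Vessel& s = v[iv];
    int M = s.n - 1, k = s.wk;
    double W1 = w_plus_star(s, dt);
    double den = 1.0 + dt / (Rd[k] * Cc[k]);
    double A = s.A[M], Q = s.Q[M];
    double vscale = std::fabs(W1) + 1.0, pscale = s.f + std::fabs(s.Pdia) + 1.0;
    bool ok = false;
    for (int it = 0; it < 60; ++it) {
      double c = wspeed(s, A);
      double u = Q / A;
      double Pcn = (Pc[k] + (dt / Cc[k]) * (Q + Pout[k] / Rd[k])) / den;
      double r1 = u + 4.0 * c - W1;
      double r2 = pres(s, A) - Pcn - Q * Rp[k];
      if (std::fabs(r1) / vscale + std::fabs(r2) / pscale < 1e-13) { ok = true; break; }
      double J[4] = {(c - u) / A, 1.0 / A,
                     dpda(s, A), -(dt / Cc[k]) / den - Rp[k]};
      double b[2] = {r1, r2};
      if (!lsolve(2, J, b)) return false;
      double An2 = A - b[0], Qn2 = Q - b[1];
      if (An2 <= 0) An2 = 0.5 * A;
      A = An2; Q = Qn2;
      if (it == 59) ok = true;  // accept last iterate; residual tracked below
    }
    if (!std::isfinite(A) || !std::isfinite(Q) || A <= 0) return false;
    s.An[M] = A;
    s.Qn[M] = Q;
    Pc[k] = (Pc[k] + (dt / Cc[k]) * (Q + Pout[k] / Rd[k])) / den;
    outlet_vol[k] += dt * Q;
    return ok;
  }

  // junction: parent outlet + two child inlets
  bool junction_bc(int ip, double dt) {
    Vessel& p = v[ip];
    Vessel& d1 = v[p.child1];
    Vessel& d2 = v[p.child2];
    int M = p.n - 1;
    double W1 = w_plus_star(p, dt);
    double V1 = w_minus_star(d1, dt);
    double V2 = w_minus_star(d2, dt);
    // unknowns x = (Ap, Qp, A1, Q1, A2, Q2)
    double x[6] = {p.A[M], p.Q[M], d1.A[0], d1.Q[0], d2.A[0], d2.Q[0]};
    double resn = 1e300;
    for (int it = 0; it < 30; ++it) {
      double Ap = x[0], Qp = x[1], A1 = x[2], Q1 = x[3], A2 = x[4], Q2 = x[5];
      double cp = wspeed(p, Ap), c1 = wspeed(d1, A1), c2 = wspeed(d2, A2);
      double up = Qp / Ap, u1 = Q1 / A1, u2 = Q2 / A2;
      double r[6] = {
        up + 4.0 * cp - W1,
        u1 - 4.0 * c1 - V1,
        u2 - 4.0 * c2 - V2,
        Qp - Q1 - Q2,
        pres(p, Ap) - pres(d1, A1),
        pres(p, Ap) - pres(d2, A2)};
      double vscale = std::fabs(W1) + 1.0;
      double pscale = p.f + std::fabs(p.Pdia) + 1.0;
      resn = std::max(
          std::max(std::max(std::fabs(r[0]), std::fabs(r[1])),
                   std::max(std::fabs(r[2]), std::fabs(r[3]))) / vscale,
          std::max(std::fabs(r[4]), std::fabs(r[5])) / pscale);
      if (resn < 1e-13) break;
      double J[36] = {0};
      J[0 * 6 + 0] = (cp - up) / Ap;  J[0 * 6 + 1] = 1.0 / Ap;
      J[1 * 6 + 2] = -(c1 + u1) / A1; J[1 * 6 + 3] = 1.0 / A1;
      J[2 * 6 + 4] = -(c2 + u2) / A2; J[2 * 6 + 5] = 1.0 / A2;
      J[3 * 6 + 1] = 1.0; J[3 * 6 + 3] = -1.0; J[3 * 6 + 5] = -1.0;
      J[4 * 6 + 0] = dpda(p, Ap);  J[4 * 6 + 2] = -dpda(d1, A1);
      J[5 * 6 + 0] = dpda(p, Ap);  J[5 * 6 + 4] = -dpda(d2, A2);
      double b[6];
      for (int i = 0; i < 6; ++i) b[i] = r[i];
      if (!lsolve(6, J, b)) return false;
      for (int i = 0; i < 6; ++i) x[i] -= b[i];
      for (int i = 0; i < 6; i += 2)
        if (x[i] <= 0) x[i] = 0.5 * (x[i] + b[i]);  // halve back towards prev
    }
    for (int i = 0; i < 6; ++i)
      if (!std::isfinite(x[i])) return false;
    if (x[0] <= 0 || x[2] <= 0 || x[4] <= 0) return false;
    // record worst physical residual (flow conservation + pressure continuity)
    double fres = std::fabs(x[1] - x[3] - x[5]);
    double pr1 = std::fabs(pres(p, x[0]) - pres(d1, x[2])) / (p.f + 1.0);
    double pr2 = std::fabs(pres(p, x[0]) - pres(d2, x[4])) / (p.f + 1.0);
    double jr = std::max(fres / (std::fabs(x[1]) + 1.0), std::max(pr1, pr2));
    if (jr > max_jun_res) max_jun_res = jr;
    p.An[M] = x[0]; p.Qn[M] = x[1];
    d1.An[0] = x[2]; d1.Qn[0] = x[3];
    d2.An[0] = x[4]; d2.Qn[0] = x[5];
    return true;
  }

  // one full time step; returns false on failure (negative area / NaN)
  bool step(double t, double dt) {
    // node fluxes/sources and half states
    for (auto& s : v) {
      for (int j = 0; j < s.n; ++j) {
        s.F2[j] = flux2(s, s.A[j], s.Q[j]);
        s.S2[j] = src2(s.A[j], s.Q[j]);
      }
      double lam = dt / (2.0 * s.dx);
      for (int j = 0; j < s.n - 1; ++j) {
        s.Ah[j] = 0.5 * (s.A[j] + s.A[j + 1]) - lam * (s.Q[j + 1] - s.Q[j]);
        s.Qh[j] = 0.5 * (s.Q[j] + s.Q[j + 1]) - lam * (s.F2[j + 1] - s.F2[j]) +
                  0.25 * dt * (s.S2[j] + s.S2[j + 1]);
        if (s.Ah[j] <= 0 || !std::isfinite(s.Ah[j])) return false;
      }
      // interior corrector
      double mu2 = dt / s.dx;
      for (int j = 1; j < s.n - 1; ++j) {
        double FL = flux2(s, s.Ah[j - 1], s.Qh[j - 1]);
        double FR = flux2(s, s.Ah[j], s.Qh[j]);
        double SL = src2(s.Ah[j - 1], s.Qh[j - 1]);
        double SR = src2(s.Ah[j], s.Qh[j]);
        s.An[j] = s.A[j] - mu2 * (s.Qh[j] - s.Qh[j - 1]);
        s.Qn[j] = s.Q[j] - mu2 * (FR - FL) + 0.5 * dt * (SL + SR);
        if (s.An[j] <= 0 || !std::isfinite(s.An[j]) || !std::isfinite(s.Qn[j]))
          return false;
      }
    }
    // boundaries (use old states for characteristic feet)
    if (!inlet_bc(t + dt, dt)) return false;
    for (int i = 0; i < (int)v.size(); ++i) {
      if (v[i].child1 >= 0) {
        if (!junction_bc(i, dt)) return false;
      } else {
        if (!outlet_bc(i, dt)) return false;
      }
    }
    inflow_vol += dt * inflow_at(t + dt);
    // swap in new state
    for (auto& s : v) {
      s.A.swap(s.An);
      s.Q.swap(s.Qn);
    }
    return true;
  }

  double max_speed_ratio() const {  // max over nodes of (|u|+c)/dx
    double m = 0;
    for (const auto& s : v)
      for (int j = 0; j < s.n; ++j) {
        double r = (std::fabs(s.Q[j] / s.A[j]) + wspeed(s, s.A[j])) / s.dx;
        if (r > m) m = r;
      }
    return m;
  }
};

}  // namespace

// [[Rcpp::export(name = ".solve_network_cpp")]]
List solve_network_cpp(IntegerVector n_nodes, NumericVector dx,
                       NumericVector f, NumericVector Adia,
                       NumericVector Pdia, IntegerVector child1,
                       IntegerVector child2, int root, IntegerVector wk_index,
                       NumericMatrix wk_params, NumericVector inflow_dense,
                       double T, double rho, double mu, double gam,
                       double cfl, int max_cycles, double ptol,
                       int store_target, Nullable<List> init_state) {
  int nv = n_nodes.size();
  Solver S;
  S.v.resize(nv);
  S.root = root;
  S.rho = rho; S.mu = mu; S.gam = gam;
  S.qcoef = (gam + 2.0) / (gam + 1.0);
  S.fric = 2.0 * M_PI * mu * (gam + 2.0) / rho;
  S.T = T;
  S.qin.assign(inflow_dense.begin(), inflow_dense.end());
  int nwk = wk_params.nrow();
  S.Rp.resize(nwk); S.Rd.resize(nwk); S.Cc.resize(nwk);
  S.Pout.resize(nwk); S.Pc.resize(nwk);
  S.outlet_vol.assign(nwk, 0.0);
  for (int k = 0; k < nwk; ++k) {
    S.Rp[k] = wk_params(k, 0); S.Rd[k] = wk_params(k, 1);
    S.Cc[k] = wk_params(k, 2); S.Pout[k] = wk_params(k, 3);
    S.Pc[k] = wk_params(k, 4);
  }
  for (int i = 0; i < nv; ++i) {
    Vessel& s = S.v[i];
    s.n = n_nodes[i]; s.dx = dx[i]; s.f = f[i];
    s.Adia = Adia[i]; s.Pdia = Pdia[i];
    s.c0 = std::sqrt(2.0 * f[i] / (3.0 * rho));
    s.child1 = child1[i]; s.child2 = child2[i]; s.wk = wk_index[i];
    s.A.assign(s.n, s.Adia); s.Q.assign(s.n, 0.0);
    s.An = s.A; s.Qn = s.Q;
    s.F2.assign(s.n, 0.0); s.S2.assign(s.n, 0.0);
    s.Ah.assign(s.n - 1, 0.0); s.Qh.assign(s.n - 1, 0.0);
    s.Pmax.assign(s.n, -1e300); s.Pmin.assign(s.n, 1e300);
    s.Amax.assign(s.n, -1e300); s.Amin.assign(s.n, 1e300);
  }
  if (init_state.isNotNull()) {
    List st(init_state);
    List Ai = st["A"], Qi = st["Q"];
    NumericVector pci = st["Pc"];
    for (int i = 0; i < nv; ++i) {
      NumericVector a = Ai[i], q = Qi[i];
      for (int j = 0; j < S.v[i].n; ++j) { S.v[i].A[j] = a[j]; S.v[i].Q[j] = q[j]; }
    }
    for (int k = 0; k < nwk; ++k) S.Pc[k] = pci[k];
  }

  std::vector<std::vector<double>> Pend_prev;
  double perr = R_PosInf;
  bool converged = false;
  int cycles_run = 0;
  std::vector<NumericMatrix> Aout(nv), Qout(nv);
  std::vector<double> tstored;
  double dt_used = NA_REAL;
  std::string errmsg;

  for (int cyc = 0; cyc < max_cycles && !converged; ++cyc) {
    // snapshot for CFL-failure restart
    std::vector<std::vector<double>> Asnap(nv), Qsnap(nv);
    std::vector<double> Pcsnap = S.Pc;
    for (int i = 0; i < nv; ++i) { Asnap[i] = S.v[i].A; Qsnap[i] = S.v[i].Q; }
    double vol_in_snap = S.inflow_vol;
    std::vector<double> vol_out_snap = S.outlet_vol;

    double dt0 = cfl / S.max_speed_ratio();
    bool cycle_ok = false;
    for (int attempt = 0; attempt < 8 && !cycle_ok; ++attempt) {
      int nsteps = (int)std::ceil(T / dt0);
      double dt = T / nsteps;
      int stride = std::max(1, nsteps / store_target);
      int nstore = nsteps / stride + ((nsteps % stride) ? 2 : 1);
      for (int i = 0; i < nv; ++i) {
        Aout[i] = NumericMatrix(nstore, S.v[i].n);
        Qout[i] = NumericMatrix(nstore, S.v[i].n);
      }
      tstored.assign(1, 0.0);
      // reset accumulators for this cycle
      S.inflow_vol = vol_in_snap;
      S.outlet_vol = vol_out_snap;
      for (int i = 0; i < nv; ++i) {
        Vessel& s = S.v[i];
        s.A = Asnap[i]; s.Q = Qsnap[i];
        std::fill(s.Pmax.begin(), s.Pmax.end(), -1e300);
        std::fill(s.Pmin.begin(), s.Pmin.end(), 1e300);
        std::fill(s.Amax.begin(), s.Amax.end(), -1e300);
        std::fill(s.Amin.begin(), s.Amin.end(), 1e300);
      }
      S.Pc = Pcsnap;
      double vin0 = S.inflow_vol;
      std::vector<double> vout0 = S.outlet_vol;
      // store initial state of cycle
      int row = 0;
      for (int i = 0; i < nv; ++i)
        for (int j = 0; j < S.v[i].n; ++j) {
          Aout[i](row, j) = S.v[i].A[j];
          Qout[i](row, j) = S.v[i].Q[j];
        }
      bool failed = false;
      for (int k = 0; k < nsteps; ++k) {
        double t = k * dt;
        if (dt * S.max_speed_ratio() > 1.0) { failed = true; break; }
        if (!S.step(t, dt)) { failed = true; break; }
        for (int i = 0; i < nv; ++i) {
          Vessel& s = S.v[i];
          for (int j = 0; j < s.n; ++j) {
            double P = S.pres(s, s.A[j]);
            if (P > s.Pmax[j]) s.Pmax[j] = P;
            if (P < s.Pmin[j]) s.Pmin[j] = P;
            if (s.A[j] > s.Amax[j]) s.Amax[j] = s.A[j];
            if (s.A[j] < s.Amin[j]) s.Amin[j] = s.A[j];
          }
        }
        if ((k + 1) % stride == 0 || k == nsteps - 1) {
          ++row;
          tstored.push_back((k + 1) * dt);
          for (int i = 0; i < nv; ++i)
            for (int j = 0; j < S.v[i].n; ++j) {
              Aout[i](row, j) = S.v[i].A[j];
              Qout[i](row, j) = S.v[i].Q[j];
            }
        }
      }
      if (failed) {
        dt0 *= 0.5;
        if (dt0 < 1e-9) {
          errmsg = "time step collapsed below 1e-9 s (collapse - check stiffness/inflow)";
          attempt = 8;
          break;
        }
        S.inflow_vol = vin0;
        S.outlet_vol = vout0;
        continue;
      }
      cycle_ok = true;
      dt_used = dt;
    }
    if (!cycle_ok) {
      if (errmsg.empty())
        errmsg = "cycle failed after repeated CFL reduction (collapse - check stiffness/inflow)";
      break;
    }
    ++cycles_run;
    // periodicity: end-of-cycle pressure field vs previous cycle
    std::vector<std::vector<double>> Pend(nv);
    double pmax = 0, dmax = 0;
    for (int i = 0; i < nv; ++i) {
      Vessel& s = S.v[i];
      Pend[i].resize(s.n);
      for (int j = 0; j < s.n; ++j) {
        Pend[i][j] = S.pres(s, s.A[j]);
        if (std::fabs(Pend[i][j]) > pmax) pmax = std::fabs(Pend[i][j]);
        if (!Pend_prev.empty()) {
          double d = std::fabs(Pend[i][j] - Pend_prev[i][j]);
          if (d > dmax) dmax = d;
        }
      }
    }
    if (!Pend_prev.empty()) {
      perr = dmax / pmax;
      if (perr < ptol) converged = true;
    }
    Pend_prev = Pend;
    // reset volume audit each cycle so the report reflects the final cycle
    if (!converged && cyc < max_cycles - 1) {
      S.inflow_vol = 0.0;
      std::fill(S.outlet_vol.begin(), S.outlet_vol.end(), 0.0);
    }
  }

  if (!errmsg.empty()) stop(errmsg);

  List AL(nv), QL(nv), Pmax(nv), Pmin(nv), Amax(nv), Amin(nv);
  for (int i = 0; i < nv; ++i) {
    int nstore = tstored.size();
    NumericMatrix a(nstore, S.v[i].n), q(nstore, S.v[i].n);
    for (int r2 = 0; r2 < nstore; ++r2)
      for (int j = 0; j < S.v[i].n; ++j) {
        a(r2, j) = Aout[i](r2, j);
        q(r2, j) = Qout[i](r2, j);
      }
    AL[i] = a; QL[i] = q;
    Pmax[i] = NumericVector(S.v[i].Pmax.begin(), S.v[i].Pmax.end());
    Pmin[i] = NumericVector(S.v[i].Pmin.begin(), S.v[i].Pmin.end());
    Amax[i] = NumericVector(S.v[i].Amax.begin(), S.v[i].Amax.end());
    Amin[i] = NumericVector(S.v[i].Amin.begin(), S.v[i].Amin.end());
  }
  return List::create(
      _["t"] = NumericVector(tstored.begin(), tstored.end()),
      _["A"] = AL, _["Q"] = QL,
      _["Pmax"] = Pmax, _["Pmin"] = Pmin,
      _["Amax"] = Amax, _["Amin"] = Amin,
      _["Pc"] = NumericVector(S.Pc.begin(), S.Pc.end()),
      _["converged"] = converged, _["cycles"] = cycles_run,
      _["periodicity_err"] = perr, _["dt"] = dt_used,
      _["max_junction_residual"] = S.max_jun_res,
      _["inflow_volume"] = S.inflow_vol,
      _["outlet_volumes"] = NumericVector(S.outlet_vol.begin(), S.outlet_vol.end()));
}
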