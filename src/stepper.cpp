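// Time-stepping core for the four-field Boyden-chamber chemotaxis model.
//
// Dimensionless system on the filter (x in [0,1], nodes shared with the
// global ligand grid):
//   n_t   = -dK/dx,            K = -D_n n_x + chi n rr_x - mu n rd_x
//   c_t   = D_c c_xx + kd1 Gr n rr - ka1 c n Gr (1+(beta-1) rr)
//                    + kd2 Gd n rd - ka2 c n Gd (1+(delta-1) rd)
//   rr_t  = -(K/n) rr_x + ka1 c (1+(beta-1) rr) - (kd1+ki1) rr
//   rd_t  = -(K/n) rd_x + ka2 c (1+(delta-1) rd) - (kd2+ki2) rd
// wells: c_t = D_c c_xx.  Boundary rows for n are the reservoir-exchange
// ODEs n_t = -K/L at x=0 and +K/L at x=1; rr, rd carry zero-gradient
// ghosts at the filter faces; c has no-flux (mirror) ghosts at the chamber
// ends and lives on one continuous grid across the interfaces.
//
// Spatial discretization: central differences (one-sided second-order for
// the flux gradients at the filter faces).  Steppers: forward Euler, and
// an IMEX scheme with Crank-Nicolson ligand diffusion (Rannacher backward
// Euler startup to damp the ringing excited by the discontinuous initial
// ligand profile) and explicit advection/reaction.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double NEPS = 1e-12;   // cell-density floor for rho advection

struct Par {
  double Dn, Dc, chi, mu, ka1, ka2, kd1, kd2, ki1, ki2, Gr, Gd, beta, delta, L;
};

struct Grid {
  double h;
  int N;    // total nodes
  int i0;   // 0-based index of x = 0
  int i1;   // 0-based index of x = 1
  int nf;   // filter nodes = i1 - i0 + 1
};

typedef std::vector<double> vec;

static Par as_par(const NumericVector& p) {
  Par q;
  q.Dn = p["D_n"]; q.Dc = p["D_c"]; q.chi = p["chi"]; q.mu = p["mu"];
  q.ka1 = p["k_a1"]; q.ka2 = p["k_a2"]; q.kd1 = p["k_d1"]; q.kd2 = p["k_d2"];
  q.ki1 = p["k_i1"]; q.ki2 = p["k_i2"]; q.Gr = p["Gamma_r"]; q.Gd = p["Gamma_d"];
  q.beta = p["beta"]; q.delta = p["delta"]; q.L = p["L"];
  return q;
}

static Grid as_grid(const List& g) {
  Grid q;
  q.h = as<double>(g["h"]);
  q.N = as<int>(g["n_total"]);
  q.i0 = as<int>(g["i0"]) - 1;  // R is 1-based
  q.i1 = as<int>(g["i1"]) - 1;
  q.nf = q.i1 - q.i0 + 1;
  return q;
}

// gradient on filter nodes, one-sided second order at the faces
static void grad_face(const vec& f, double h, vec& g) {
  int m = (int)f.size();
  g[0] = (-3.0 * f[0] + 4.0 * f[1] - f[2]) / (2.0 * h);
  for (int i = 1; i < m - 1; ++i) g[i] = (f[i + 1] - f[i - 1]) / (2.0 * h);
  g[m - 1] = (3.0 * f[m - 1] - 4.0 * f[m - 2] + f[m - 3]) / (2.0 * h);
}

// gradient with zero-gradient mirror ghosts at the faces (rho fields)
static void grad_ghost(const vec& f, double h, vec& g) {
  int m = (int)f.size();
  g[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) g[i] = (f[i + 1] - f[i - 1]) / (2.0 * h);
  g[m - 1] = 0.0;
}

// mirror-ghost Laplacian stencil (times h^2) on the full chamber grid
static void lap_mirror(const vec& c, vec& s) {
  int N = (int)c.size();
  s[0] = 2.0 * (c[1] - c[0]);
  for (int j = 1; j < N - 1; ++j) s[j] = c[j + 1] - 2.0 * c[j] + c[j - 1];
  s[N - 1] = 2.0 * (c[N - 2] - c[N - 1]);
}

static void flux_Kn(const Par& p, const Grid& g, const vec& n, const vec& rr,
                    const vec& rd, vec& gn, vec& grr, vec& grd, vec& K) {
  grad_face(n, g.h, gn);
  grad_face(rr, g.h, grr);
  grad_face(rd, g.h, grd);
  for (int i = 0; i < g.nf; ++i)
    K[i] = -p.Dn * gn[i] + p.chi * n[i] * grr[i] - p.mu * n[i] * grd[i];
}

// full-system right-hand side; include_cdiff toggles the D_c c_xx term so
// the IMEX stepper can treat it implicitly
static void rhs_full(const Par& p, const Grid& g,
                     const vec& n, const vec& c, const vec& rr, const vec& rd,
                     vec& K, vec& gn, vec& grr, vec& grd,
                     vec& grr0, vec& grd0, vec& lap,
                     vec& dn, vec& dc, vec& drr, vec& drd,
                     bool include_cdiff, int adv) {
  const int m = g.nf;
  const double h = g.h, h2 = g.h * g.h;
  flux_Kn(p, g, n, rr, rd, gn, grr, grd, K);

  dn[0] = -K[0] / p.L;
  dn[m - 1] = K[m - 1] / p.L;
  if (adv == 0) {
    for (int i = 1; i < m - 1; ++i) dn[i] = -(K[i + 1] - K[i - 1]) / (2.0 * h);
  } else {
    // first-order upwind fallback: central diffusion plus donor-cell
    // advection at the chemotactic velocity chi rr_x - mu rd_x
    for (int i = 1; i < m - 1; ++i) {
      const double vl = 0.5 * ((p.chi * grr[i - 1] - p.mu * grd[i - 1]) +
                               (p.chi * grr[i] - p.mu * grd[i]));
      const double vr = 0.5 * ((p.chi * grr[i] - p.mu * grd[i]) +
                               (p.chi * grr[i + 1] - p.mu * grd[i + 1]));
      const double Fl = vl > 0 ? vl * n[i - 1] : vl * n[i];
      const double Fr = vr > 0 ? vr * n[i] : vr * n[i + 1];
      dn[i] = p.Dn * (n[i + 1] - 2.0 * n[i] + n[i - 1]) / h2 - (Fr - Fl) / h;
    }
  }

  if (include_cdiff) {
    lap_mirror(c, lap);
    for (int j = 0; j < g.N; ++j) dc[j] = p.Dc * lap[j] / h2;
  } else {
    std::fill(dc.begin(), dc.end(), 0.0);
  }

  grad_ghost(rr, h, grr0);
  grad_ghost(rd, h, grd0);
  for (int i = 0; i < m; ++i) {
    const double cf = c[g.i0 + i];
    const double A = 1.0 + (p.beta - 1.0) * rr[i];
    const double B = 1.0 + (p.delta - 1.0) * rd[i];
    dc[g.i0 + i] += p.kd1 * p.Gr * n[i] * rr[i] - p.ka1 * cf * n[i] * p.Gr * A
                  + p.kd2 * p.Gd * n[i] * rd[i] - p.ka2 * cf * n[i] * p.Gd * B;
    double advr = 0.0, advd = 0.0;
    if (n[i] >= NEPS) {
      const double vel = K[i] / n[i];
      if (adv == 0) {
        advr = vel * grr0[i];
        advd = vel * grd0[i];
      } else if (i > 0 && i < m - 1) {
        advr = vel * (vel > 0 ? (rr[i] - rr[i - 1]) / h
                              : (rr[i + 1] - rr[i]) / h);
        advd = vel * (vel > 0 ? (rd[i] - rd[i - 1]) / h
                              : (rd[i + 1] - rd[i]) / h);
      }
    }
    drr[i] = -advr + p.ka1 * cf * A - (p.kd1 + p.ki1) * rr[i];
    drd[i] = -advd + p.ka2 * cf * B - (p.kd2 + p.ki2) * rd[i];
  }
}

// tangent (forward-sensitivity) right-hand side: J * s + dF/dp_j, with the
// same stencils and boundary-row linearization as the primal system.
// pj indexes (chi, mu, beta, delta, k_a2, k_d2, k_i2, Gamma_d) as 0..7.
static void rhs_tangent(const Par& p, const Grid& g, int pj,
                        const vec& n, const vec& c, const vec& rr, const vec& rd,
                        const vec& K, const vec& grr, const vec& grd,
                        const vec& grr0, const vec& grd0,
                        const vec& sn, const vec& sc, const vec& srr, const vec& srd,
                        vec& gsn, vec& gsrr, vec& gsrd,
                        vec& gsrr0, vec& gsrd0, vec& lap, vec& dK,
                        vec& dsn, vec& dsc, vec& dsrr, vec& dsrd,
                        bool include_cdiff) {
  const int m = g.nf;
  const double h = g.h, h2 = g.h * g.h;

  grad_face(sn, h, gsn);
  grad_face(srr, h, gsrr);
  grad_face(srd, h, gsrd);
  for (int i = 0; i < m; ++i) {
    dK[i] = -p.Dn * gsn[i]
          + p.chi * (sn[i] * grr[i] + n[i] * gsrr[i])
          - p.mu * (sn[i] * grd[i] + n[i] * gsrd[i]);
    if (pj == 0) dK[i] += n[i] * grr[i];
    if (pj == 1) dK[i] -= n[i] * grd[i];
  }

  dsn[0] = -dK[0] / p.L;
  dsn[m - 1] = dK[m - 1] / p.L;
  for (int i = 1; i < m - 1; ++i) dsn[i] = -(dK[i + 1] - dK[i - 1]) / (2.0 * h);

  if (include_cdiff) {
    lap_mirror(sc, lap);
    for (int j = 0; j < g.N; ++j) dsc[j] = p.Dc * lap[j] / h2;
  } else {
    std::fill(dsc.begin(), dsc.end(), 0.0);
  }

  grad_ghost(srr, h, gsrr0);
  grad_ghost(srd, h, gsrd0);
  for (int i = 0; i < m; ++i) {
    const int j = g.i0 + i;
    const double cf = c[j], scf = sc[j];
    const double A = 1.0 + (p.beta - 1.0) * rr[i];
    const double B = 1.0 + (p.delta - 1.0) * rd[i];

    double t = p.kd1 * p.Gr * (sn[i] * rr[i] + n[i] * srr[i])
             - p.ka1 * p.Gr * (scf * n[i] * A + cf * sn[i] * A
                               + cf * n[i] * (p.beta - 1.0) * srr[i])
             + p.kd2 * p.Gd * (sn[i] * rd[i] + n[i] * srd[i])
             - p.ka2 * p.Gd * (scf * n[i] * B + cf * sn[i] * B
                               + cf * n[i] * (p.delta - 1.0) * srd[i]);
    if (pj == 2) t += -p.ka1 * cf * n[i] * p.Gr * rr[i];
    if (pj == 3) t += -p.ka2 * cf * n[i] * p.Gd * rd[i];
    if (pj == 4) t += -cf * n[i] * p.Gd * B;
    if (pj == 5) t += p.Gd * n[i] * rd[i];
    if (pj == 7) t += p.kd2 * n[i] * rd[i] - p.ka2 * cf * n[i] * B;
    dsc[j] += t;

    double advr = 0.0, advd = 0.0;
    if (n[i] >= NEPS) {
      const double v = K[i] / n[i];
      const double dv = dK[i] / n[i] - K[i] * sn[i] / (n[i] * n[i]);
      advr = dv * grr0[i] + v * gsrr0[i];
      advd = dv * grd0[i] + v * gsrd0[i];
    }
    dsrr[i] = -advr + p.ka1 * (scf * A + cf * (p.beta - 1.0) * srr[i])
            - (p.kd1 + p.ki1) * srr[i];
    if (pj == 2) dsrr[i] += p.ka1 * cf * rr[i];

    dsrd[i] = -advd + p.ka2 * (scf * B + cf * (p.delta - 1.0) * srd[i])
            - (p.kd2 + p.ki2) * srd[i];
    if (pj == 3) dsrd[i] += p.ka2 * cf * rd[i];
    if (pj == 4) dsrd[i] += cf * B;
    if (pj == 5) dsrd[i] -= rd[i];
    if (pj == 6) dsrd[i] -= rd[i];
  }
}

// Thomas solve of (I - lam*S) x = b where S is the mirror-ghost Laplacian
// stencil (diag -2 everywhere, off-diagonal 1, doubled couplings in the
// first and last rows).  cw is a work vector.
static void cn_solve(double lam, vec& b, vec& cw) {
  int N = (int)b.size();
  const double diag = 1.0 + 2.0 * lam;
  // forward sweep
  cw[0] = -2.0 * lam / diag;
  b[0] = b[0] / diag;
  for (int j = 1; j < N; ++j) {
    double sub = (j == N - 1) ? -2.0 * lam : -lam;
    double sup = -lam;
    double den = diag - sub * cw[j - 1];
    cw[j] = sup / den;
    b[j] = (b[j] - sub * b[j - 1]) / den;
  }
  for (int j = N - 2; j >= 0; --j) b[j] -= cw[j] * b[j + 1];
}

struct ClipStats { long clipped; double worst; const char* worst_field; };

// clip tiny negatives to zero; track the most negative value seen and the
// field it occurred in.  A matching tangent vector (may be null) is zeroed
// where the primal is clipped, consistent with differentiating the clipped
// map.
static void clip_field(vec& y, vec* s, ClipStats& st, const char* field) {
  for (size_t i = 0; i < y.size(); ++i) {
    if (y[i] < 0.0) {
      if (y[i] < st.worst) { st.worst = y[i]; st.worst_field = field; }
      y[i] = 0.0;
      if (s) (*s)[i] = 0.0;
      st.clipped++;
    }
  }
}

// [[Rcpp::export]]
List cpp_advance(NumericVector n_, NumericVector c_, NumericVector rr_,
                 NumericVector rd_, NumericVector sn_, NumericVector sc_,
                 NumericVector srr_, NumericVector srd_, int pj,
                 NumericVector par, List gridinfo, double dt, int nsteps,
                 int step0, std::string scheme, int startup_steps,
                 double abort_tol, int adv) {
  Par p = as_par(par);
  Grid g = as_grid(gridinfo);
  const int m = g.nf, N = g.N;
  const bool sens = pj >= 0;
  const bool imex = (scheme == "imex");

  vec n(n_.begin(), n_.end()), c(c_.begin(), c_.end());
  vec rr(rr_.begin(), rr_.end()), rd(rd_.begin(), rd_.end());
  vec sn(sn_.begin(), sn_.end()), sc(sc_.begin(), sc_.end());
  vec srr(srr_.begin(), srr_.end()), srd(srd_.begin(), srd_.end());

  vec K(m), gn(m), grr(m), grd(m), grr0(m), grd0(m), lap(N);
  vec dn(m), dc(N), drr(m), drd(m);
  vec gsn(m), gsrr(m), gsrd(m), gsrr0(m), gsrd0(m), dK(m), lap2(N);
  vec dsn(m), dsc(N), dsrr(m), dsrd(m);
  vec b(N), b2(N), cw(N);

  ClipStats st; st.clipped = 0; st.worst = 0.0; st.worst_field = "";

  for (int step = 0; step < nsteps; ++step) {
    const bool cdiff_explicit = !imex;
    rhs_full(p, g, n, c, rr, rd, K, gn, grr, grd, grr0, grd0, lap,
             dn, dc, drr, drd, cdiff_explicit, adv);
    if (sens)
      rhs_tangent(p, g, pj, n, c, rr, rd, K, grr, grd, grr0, grd0,
                  sn, sc, srr, srd, gsn, gsrr, gsrd, gsrr0, gsrd0,
                  lap2, dK, dsn, dsc, dsrr, dsrd, cdiff_explicit);

    if (imex) {
      // theta-scheme for ligand diffusion: backward Euler during the
      // Rannacher startup, Crank-Nicolson afterwards
      const bool be = (step0 + step) < startup_steps;
      const double theta = be ? 1.0 : 0.5;
      const double lam_im = theta * dt * p.Dc / (g.h * g.h);
      const double lam_ex = (1.0 - theta) * dt * p.Dc / (g.h * g.h);
      lap_mirror(c, lap);
      for (int j = 0; j < N; ++j)
        b[j] = c[j] + lam_ex * lap[j] + dt * dc[j];
      cn_solve(lam_im, b, cw);
      if (sens) {
        lap_mirror(sc, lap2);
        for (int j = 0; j < N; ++j)
          b2[j] = sc[j] + lam_ex * lap2[j] + dt * dsc[j];
        cn_solve(lam_im, b2, cw);
      }
      for (int j = 0; j < N; ++j) c[j] = b[j];
      if (sens) for (int j = 0; j < N; ++j) sc[j] = b2[j];
    } else {
      for (int j = 0; j < N; ++j) c[j] += dt * dc[j];
      if (sens) for (int j = 0; j < N; ++j) sc[j] += dt * dsc[j];
    }
    for (int i = 0; i < m; ++i) {
      n[i] += dt * dn[i];
      rr[i] += dt * drr[i];
      rd[i] += dt * drd[i];
    }
    if (sens) {
      for (int i = 0; i < m; ++i) {
        sn[i] += dt * dsn[i];
        srr[i] += dt * dsrr[i];
        srd[i] += dt * dsrd[i];
      }
    }

    clip_field(n, sens ? &sn : 0, st, "n");
    clip_field(c, sens ? &sc : 0, st, "c");
    clip_field(rr, sens ? &srr : 0, st, "rho_r");
    clip_field(rd, sens ? &srd : 0, st, "rho_d");
    if (st.worst < -abort_tol)
      stop("field %s dropped below -%g (worst %g) at step %d",
           st.worst_field, abort_tol, st.worst, step0 + step);

    if ((step & 1023) == 0) {
      for (int i = 0; i < m; ++i)
        if (!std::isfinite(n[i]) || !std::isfinite(rr[i]) || !std::isfinite(rd[i]))
          stop("non-finite field value at filter node %d, step %d", i, step0 + step);
      for (int j = 0; j < N; ++j)
        if (!std::isfinite(c[j]))
          stop("non-finite ligand value at node %d, step %d", j, step0 + step);
    }
  }

  return List::create(_["n"] = n, _["c"] = c, _["rho_r"] = rr, _["rho_d"] = rd,
                      _["sn"] = sn, _["sc"] = sc, _["srr"] = srr, _["srd"] = srd,
                      _["clipped"] = (double)st.clipped, _["worst"] = st.worst);
}

// -------------------------------------------------------------------------
// Reduced no-decoy system (three fields): an independent implementation of
// the collapsed model, kept separate from the full solver so the two can
// be cross-checked node for node.
// -------------------------------------------------------------------------

static void rhs_reduced(const Par& p, const Grid& g,
                        const vec& n, const vec& c, const vec& rr,
                        vec& K, vec& gn, vec& grr, vec& grr0, vec& lap,
                        vec& dn, vec& dc, vec& drr, bool include_cdiff,
                        int adv) {
  const int m = g.nf;
  const double h = g.h, h2 = g.h * g.h;
  grad_face(n, h, gn);
  grad_face(rr, h, grr);
  for (int i = 0; i < m; ++i) K[i] = -p.Dn * gn[i] + p.chi * n[i] * grr[i];

  dn[0] = -K[0] / p.L;
  dn[m - 1] = K[m - 1] / p.L;
  if (adv == 0) {
    for (int i = 1; i < m - 1; ++i) dn[i] = -(K[i + 1] - K[i - 1]) / (2.0 * h);
  } else {
    for (int i = 1; i < m - 1; ++i) {
      const double vl = 0.5 * (p.chi * grr[i - 1] + p.chi * grr[i]);
      const double vr = 0.5 * (p.chi * grr[i] + p.chi * grr[i + 1]);
      const double Fl = vl > 0 ? vl * n[i - 1] : vl * n[i];
      const double Fr = vr > 0 ? vr * n[i] : vr * n[i + 1];
      dn[i] = p.Dn * (n[i + 1] - 2.0 * n[i] + n[i - 1]) / h2 - (Fr - Fl) / h;
    }
  }

  if (include_cdiff) {
    lap_mirror(c, lap);
    for (int j = 0; j < g.N; ++j) dc[j] = p.Dc * lap[j] / h2;
  } else {
    std::fill(dc.begin(), dc.end(), 0.0);
  }

  grad_ghost(rr, h, grr0);
  for (int i = 0; i < m; ++i) {
    const double cf = c[g.i0 + i];
    const double A = 1.0 + (p.beta - 1.0) * rr[i];
    dc[g.i0 + i] += p.kd1 * p.Gr * n[i] * rr[i] - p.ka1 * cf * n[i] * p.Gr * A;
    double advr = 0.0;
    if (n[i] >= NEPS) {
      const double vel = K[i] / n[i];
      if (adv == 0) advr = vel * grr0[i];
      else if (i > 0 && i < m - 1)
        advr = vel * (vel > 0 ? (rr[i] - rr[i - 1]) / h
                              : (rr[i + 1] - rr[i]) / h);
    }
    drr[i] = -advr + p.ka1 * cf * A - (p.kd1 + p.ki1) * rr[i];
  }
}

// [[Rcpp::export]]
List cpp_advance_reduced(NumericVector n_, NumericVector c_, NumericVector rr_,
                         NumericVector par, List gridinfo, double dt,
                         int nsteps, int step0, std::string scheme,
                         int startup_steps, double abort_tol, int adv) {
  Par p = as_par(par);
  Grid g = as_grid(gridinfo);
  const int m = g.nf, N = g.N;
  const bool imex = (scheme == "imex");

  vec n(n_.begin(), n_.end()), c(c_.begin(), c_.end());
  vec rr(rr_.begin(), rr_.end());
  vec K(m), gn(m), grr(m), grr0(m), lap(N);
  vec dn(m), dc(N), drr(m), b(N), cw(N);
  ClipStats st; st.clipped = 0; st.worst = 0.0; st.worst_field = "";

  for (int step = 0; step < nsteps; ++step) {
    rhs_reduced(p, g, n, c, rr, K, gn, grr, grr0, lap, dn, dc, drr, !imex,
                adv);
    if (imex) {
      const bool be = (step0 + step) < startup_steps;
      const double theta = be ? 1.0 : 0.5;
      const double lam_im = theta * dt * p.Dc / (g.h * g.h);
      const double lam_ex = (1.0 - theta) * dt * p.Dc / (g.h * g.h);
      lap_mirror(c, lap);
      for (int j = 0; j < N; ++j) b[j] = c[j] + lam_ex * lap[j] + dt * dc[j];
      cn_solve(lam_im, b, cw);
      for (int j = 0; j < N; ++j) c[j] = b[j];
    } else {
      for (int j = 0; j < N; ++j) c[j] += dt * dc[j];
    }
    for (int i = 0; i < m; ++i) {
      n[i] += dt * dn[i];
      rr[i] += dt * drr[i];
    }
    clip_field(n, 0, st, "n");
    clip_field(c, 0, st, "c");
    clip_field(rr, 0, st, "rho_r");
    if (st.worst < -abort_tol)
      stop("field %s dropped below -%g (worst %g) at step %d",
           st.worst_field, abort_tol, st.worst, step0 + step);
  }

  return List::create(_["n"] = n, _["c"] = c, _["rho_r"] = rr,
                      _["clipped"] = (double)st.clipped, _["worst"] = st.worst);
}

// single right-hand-side evaluation of the full system, exposed for
// cross-checking the R reference implementation against the C++ kernel
// [[Rcpp::export]]
List cpp_rhs_full(NumericVector n_, NumericVector c_, NumericVector rr_,
                  NumericVector rd_, NumericVector par, List gridinfo) {
  Par p = as_par(par);
  Grid g = as_grid(gridinfo);
  const int m = g.nf, N = g.N;
  vec n(n_.begin(), n_.end()), c(c_.begin(), c_.end());
  vec rr(rr_.begin(), rr_.end()), rd(rd_.begin(), rd_.end());
  vec K(m), gn(m), grr(m), grd(m), grr0(m), grd0(m), lap(N);
  vec dn(m), dc(N), drr(m), drd(m);
  rhs_full(p, g, n, c, rr, rd, K, gn, grr, grd, grr0, grd0, lap,
           dn, dc, drr, drd, true, 0);
  return List::create(_["dn"] = dn, _["dc"] = dc, _["drho_r"] = drr,
                      _["drho_d"] = drd, _["K_n"] = K);
}
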