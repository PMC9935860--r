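// Depth-averaged shallow-water solver on a staggered rectangular grid with
// wetting/drying, vegetated Chezy friction, suspended-sediment transport
// (donor-cell advection with a positivity flux limiter, explicit diffusion,
// implicit settling), an implicit bivalve filtration sink on mound cells,
// and optional Partheniades-type erosion of mound deposits.
//
// Layout: cells (nr x nc), row 0 = seaward boundary. u faces between
// columns, (nr x (nc+1)); v faces between rows, ((nr+1) x nc). v > 0 flows
// landward (increasing row). The seaward boundary (v face row 0) is a
// prescribed water level; lateral and landward boundaries are closed walls
// unless a landward level series is supplied (flume tests).
//
// Two time integrators share all physics: an explicit scheme (gravity-wave
// CFL bound, point-implicit friction) and a directionally split
// semi-implicit scheme (each step advances the x- then the y-subsystem as a
// one-dimensional theta-scheme, sweep order alternating; the free surface
// is implicit so the step is bound by the advective Courant number).
// Upwind face depths (Stelling-type) keep a lake at rest exactly at rest.
// Continuity is in flux form; outgoing fluxes are scaled to the donor-cell
// volume, so depths stay non-negative and volume is conserved to round-off.
// Sediment mass moves with the same (limited) face volumes, so the
// sediment ledger closes against boundary fluxes exactly.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#ifdef __SSE2__
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
using namespace Rcpp;

static const double G = 9.81;
static const double KAPPA = 0.41;
static const double RHO_W = 1025.0;

static inline double baptist(double h, double n, double hv,
                             double cb, double cd) {
  if (n <= 0.0) return cb;
  double hveg = (h < hv) ? h : hv;
  double c = 1.0 / std::sqrt(1.0 / (cb * cb) + cd * n * hveg / (2.0 * G));
  if (h > hv) c += std::sqrt(G) / KAPPA * std::log(h / hv);
  return c;
}

struct BC {
  const double *lev; int n; double dt;
  double at(double t) const {
    double x = t / dt;
    int i = (int)std::floor(x);
    if (i < 0) return lev[0];
    if (i >= n - 1) return lev[n - 1];
    double f = x - i;
    return lev[i] * (1.0 - f) + lev[i + 1] * f;
  }
};

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix zb_, double dx, NumericVector dy_,
                  NumericMatrix veg_n_, NumericMatrix veg_hv_,
                  double cb, double cd,
                  NumericMatrix rho_mm_, double f_mm_si,
                  NumericVector eta_bc, NumericVector eta_bc_land,
                  double bc_dt,
                  double duration, double dt,
                  double ws, double rho_dry, double c_bc,
                  double diff_k, double visc, double h_dry,
                  bool adv_on, int sed_stride, bool sediment_on,
                  bool erosion_on, double tau_ce, double m_erod,
                  NumericMatrix eta0_, NumericMatrix u0_, NumericMatrix v0_,
                  NumericMatrix conc0_,
                  int hydro_scheme, double theta) {
#ifdef __SSE2__
  // flush denormals: slack-water velocities decay exponentially through the
  // friction division and would otherwise stall the FPU
  unsigned int csr_saved = _mm_getcsr();
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
  const int nr = zb_.nrow(), nc = zb_.ncol();
  const int NU = nc + 1;
  const double V_SNAP = 1e-12;  // velocities below this are still water
  auto C = [&](int j, int i) { return j * nc + i; };
  auto U = [&](int j, int i) { return j * NU + i; };
  auto V = [&](int j, int i) { return j * nc + i; };

  std::vector<double> zb(nr * nc), vegn(nr * nc), veghv(nr * nc),
      rhomm(nr * nc), area(nr * nc);
  std::vector<double> dy(nr);
  for (int j = 0; j < nr; ++j) dy[j] = dy_[j];
  for (int j = 0; j < nr; ++j)
    for (int i = 0; i < nc; ++i) {
      zb[C(j, i)] = zb_(j, i);
      vegn[C(j, i)] = veg_n_(j, i);
      veghv[C(j, i)] = veg_hv_(j, i);
      rhomm[C(j, i)] = rho_mm_(j, i);
      area[C(j, i)] = dx * dy[j];
    }

  BC bc{eta_bc.begin(), (int)eta_bc.size(), bc_dt};
  bool land_open = eta_bc_land.size() > 0;
  BC bcl{eta_bc_land.begin(), (int)eta_bc_land.size(), bc_dt};

  std::vector<double> eta(nr * nc), u(nr * NU, 0.0), v((nr + 1) * nc, 0.0),
      mass(nr * nc, 0.0);
  double bc0 = bc.at(0.0);
  for (int j = 0; j < nr; ++j)
    for (int i = 0; i < nc; ++i) {
      double e = (eta0_.nrow() == nr) ? eta0_(j, i) : std::max(zb[C(j, i)], bc0);
      eta[C(j, i)] = std::max(e, zb[C(j, i)]);
    }
  if (u0_.nrow() == nr)
    for (int j = 0; j < nr; ++j)
      for (int i = 0; i < NU; ++i) u[U(j, i)] = u0_(j, i);
  if (v0_.nrow() == nr + 1)
    for (int j = 0; j <= nr; ++j)
      for (int i = 0; i < nc; ++i) v[V(j, i)] = v0_(j, i);
  if (conc0_.nrow() == nr)
    for (int j = 0; j < nr; ++j)
      for (int i = 0; i < nc; ++i)
        mass[C(j, i)] = conc0_(j, i) *
          std::max(eta[C(j, i)] - zb[C(j, i)], 0.0) * area[C(j, i)];

  std::vector<double> chez(nr * nc, cb);
  std::vector<double> dz_set(nr * nc, 0.0), dz_filt(nr * nc, 0.0),
      dz_ero(nr * nc, 0.0);
  // accumulated face volumes between sediment steps (m^3, signed)
  std::vector<double> wu(nr * NU, 0.0), wv((nr + 1) * nc, 0.0);
  std::vector<double> un(nr * NU, 0.0), vn((nr + 1) * nc, 0.0);
  std::vector<double> qu(nr * NU, 0.0), qv((nr + 1) * nc, 0.0);
  std::vector<double> lam(nr * nc, 1.0);

  double vol_in = 0.0, vol_out = 0.0, sed_in = 0.0, sed_out = 0.0;
  double clamp_mass = 0.0, clamp_vol = 0.0;
  double vol0 = 0.0, mass0 = 0.0;
  for (int k = 0; k < nr * nc; ++k) {
    vol0 += std::max(eta[k] - zb[k], 0.0) * area[k];
    mass0 += mass[k];
  }
  double max_vol_resid = 0.0, max_mass_resid = 0.0;

  const int nsteps = (int)std::ceil(duration / dt);
  const int fr_stride = 20;    // friction cache refresh
  const int act_stride = 20;   // active-row rescan
  int j_act = nr;              // rows [0, j_act) are active

  // face depth by upwind water level
  auto face_h = [&](double vel, double eL, double eR, double zf) {
    double e;
    if (vel > 1e-12) e = eL;
    else if (vel < -1e-12) e = eR;
    else e = (eL > eR) ? eL : eR;
    double h = e - zf;
    return (h > 0.0) ? h : 0.0;
  };

  // ADI scratch
  const int nmax = std::max(nr, nc) + 2;
  std::vector<double> th_a(nmax), th_b(nmax), th_c(nmax), th_r(nmax),
      th_x(nmax), th_cp(nmax);
  std::vector<double> al_u(nr * NU, 0.0), be_u(nr * NU, 0.0),
      hfu(nr * NU, 0.0);
  std::vector<double> al_v((nr + 1) * nc, 0.0), be_v((nr + 1) * nc, 0.0),
      hfv((nr + 1) * nc, 0.0);
  std::vector<double> etan(nr * nc, 0.0);

  // limiter + conservative continuity + budget + face-volume accumulation,
  // shared by the explicit step and each ADI half-step; consumes qu/qv and
  // zeroes them afterwards
  auto apply_fluxes = [&](double dtt, int j_act_loc) {
    for (int j = 0; j < j_act_loc; ++j)
      for (int i = 0; i < nc; ++i) {
        double out = 0.0;
        if (qv[V(j, i)] < 0.0) out -= qv[V(j, i)];
        if (qv[V(j + 1, i)] > 0.0) out += qv[V(j + 1, i)];
        if (qu[U(j, i)] < 0.0) out -= qu[U(j, i)];
        if (qu[U(j, i + 1)] > 0.0) out += qu[U(j, i + 1)];
        double volc = std::max(eta[C(j, i)] - zb[C(j, i)], 0.0) * area[C(j, i)];
        lam[C(j, i)] = (out * dtt > volc) ? volc / (out * dtt) : 1.0;
      }
    auto dl_v = [&](int j, int i) {
      double q = qv[V(j, i)];
      if (q > 0.0) return (j == 0) ? 1.0 : lam[C(j - 1, i)];
      if (q < 0.0) return (j == nr) ? 1.0 : lam[C(j, i)];
      return 1.0;
    };
    auto dl_u = [&](int j, int i) {
      double q = qu[U(j, i)];
      if (q > 0.0) return lam[C(j, i - 1)];
      if (q < 0.0) return lam[C(j, i)];
      return 1.0;
    };
    for (int j = 0; j < j_act_loc; ++j)
      for (int i = 0; i < nc; ++i) {
        double fin = dl_v(j, i) * qv[V(j, i)]
                   - dl_v(j + 1, i) * qv[V(j + 1, i)]
                   + dl_u(j, i) * qu[U(j, i)]
                   - dl_u(j, i + 1) * qu[U(j, i + 1)];
        double h = eta[C(j, i)] - zb[C(j, i)];
        if (h < 0.0) h = 0.0;
        double hn = h + dtt * fin / area[C(j, i)];
        if (hn < 0.0) { clamp_vol += -hn * area[C(j, i)]; hn = 0.0; }
        eta[C(j, i)] = zb[C(j, i)] + hn;
      }
    for (int i = 0; i < nc; ++i) {
      double f0 = dl_v(0, i) * qv[V(0, i)];
      if (f0 > 0.0) vol_in += f0 * dtt; else vol_out -= f0 * dtt;
      wv[V(0, i)] += f0 * dtt;
      if (land_open) {
        double fl = dl_v(nr, i) * qv[V(nr, i)];
        if (fl < 0.0) vol_in += -fl * dtt; else vol_out += fl * dtt;
        wv[V(nr, i)] += fl * dtt;
      }
    }
    for (int j = 0; j < j_act_loc; ++j) {
      for (int i = 1; i < nc; ++i)
        wu[U(j, i)] += dl_u(j, i) * qu[U(j, i)] * dtt;
      for (int i = 0; i < nc; ++i)
        if (j >= 1) wv[V(j, i)] += dl_v(j, i) * qv[V(j, i)] * dtt;
    }
    std::fill(qu.begin(), qu.end(), 0.0);
    std::fill(qv.begin(), qv.end(), 0.0);
  };

  auto thomas = [&](int n) {
    // solve tridiagonal (th_a, th_b, th_c) x = th_r into th_x
    th_cp[0] = th_c[0] / th_b[0];
    th_x[0] = th_r[0] / th_b[0];
    for (int k = 1; k < n; ++k) {
      double m = 1.0 / (th_b[k] - th_a[k] * th_cp[k - 1]);
      th_cp[k] = th_c[k] * m;
      th_x[k] = (th_r[k] - th_a[k] * th_x[k - 1]) * m;
    }
    for (int k = n - 2; k >= 0; --k) th_x[k] -= th_cp[k] * th_x[k + 1];
  };

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;
    double eb = bc.at(t);
    double ebl = land_open ? bcl.at(t) : 0.0;

    if (step % act_stride == 0) {
      int jm = 1;
      for (int j = 0; j < nr; ++j)
        for (int i = 0; i < nc; ++i)
          if (eta[C(j, i)] - zb[C(j, i)] > h_dry) { jm = j + 1; break; }
      // scan is row-major; the inner break only skips the rest of the row,
      // so jm ends at the last row holding a wet cell
      j_act = std::min(nr, jm + 3);
      if (land_open) j_act = nr;
    }

    if (step % fr_stride == 0) {
      for (int j = 0; j < j_act; ++j)
        for (int i = 0; i < nc; ++i) {
          double h = eta[C(j, i)] - zb[C(j, i)];
          if (h > h_dry)
            chez[C(j, i)] = baptist(h, vegn[C(j, i)], veghv[C(j, i)], cb, cd);
          else
            chez[C(j, i)] = cb;
        }
    }

    if (hydro_scheme == 0) {
    // ---- momentum: v faces (j = 0 boundary, 1..nr-1 interior, nr landward)
    for (int j = 0; j <= nr; ++j) {
      if (j >= j_act + 1 && !(land_open && j >= nr)) {
        for (int i = 0; i < nc; ++i) vn[V(j, i)] = 0.0;
        continue;
      }
      for (int i = 0; i < nc; ++i) {
        double eL, eR, zL, zR, cL, cR, dist;
        if (j == 0) {              // seaward ghost: prescribed level
          eL = eb; zL = zb[C(0, i)]; cL = chez[C(0, i)];
          eR = eta[C(0, i)]; zR = zb[C(0, i)]; cR = chez[C(0, i)];
          dist = dy[0];
        } else if (j == nr) {      // landward ghost (open only in flume mode)
          if (!land_open) { vn[V(j, i)] = 0.0; continue; }
          eL = eta[C(nr - 1, i)]; zL = zb[C(nr - 1, i)]; cL = chez[C(nr - 1, i)];
          eR = ebl; zR = zb[C(nr - 1, i)]; cR = cL;
          dist = dy[nr - 1];
        } else {
          eL = eta[C(j - 1, i)]; zL = zb[C(j - 1, i)]; cL = chez[C(j - 1, i)];
          eR = eta[C(j, i)]; zR = zb[C(j, i)]; cR = chez[C(j, i)];
          dist = 0.5 * (dy[j - 1] + dy[j]);
        }
        double zf = (zL > zR) ? zL : zR;
        double vv = v[V(j, i)];
        double hf = face_h(vv, eL, eR, zf);
        if (hf <= h_dry) { vn[V(j, i)] = 0.0; continue; }
        double grad = -G * (eR - eL) / dist;
        double adv = 0.0;
        double uavg;
        {
          int ju = (j == 0) ? 0 : ((j >= nr) ? nr - 1 : j);
          int jl = (j == 0) ? 0 : j - 1;
          if (jl >= nr) jl = nr - 1;
          uavg = 0.25 * (u[U(jl, i)] + u[U(jl, i + 1)] +
                         u[U(ju, i)] + u[U(ju, i + 1)]);
        }
        if (adv_on && j > 0 && j < nr) {
          if (vv > 0.0 && j >= 1) {
            adv -= vv * (vv - v[V(j - 1, i)]) / dy[j - 1];
          } else if (vv < 0.0 && j + 1 <= nr) {
            adv -= vv * (v[V(j + 1, i)] - vv) / dy[j];
          }
          if (uavg > 0.0 && i >= 1) {
            adv -= uavg * (vv - v[V(j, i - 1)]) / dx;
          } else if (uavg < 0.0 && i + 1 < nc) {
            adv -= uavg * (v[V(j, i + 1)] - vv) / dx;
          }
        }
        double vis = 0.0;
        if (visc > 0.0 && j > 0 && j < nr) {
          double vl = (i >= 1) ? v[V(j, i - 1)] : vv;
          double vr = (i + 1 < nc) ? v[V(j, i + 1)] : vv;
          double vd = v[V(j - 1, i)], vu2 = v[V(j + 1, i)];
          vis = visc * ((vl - 2.0 * vv + vr) / (dx * dx) +
                        (vd - 2.0 * vv + vu2) / (dist * dist));
        }
        double cf = 0.5 * (cL + cR);
        double speed = std::sqrt(vv * vv + uavg * uavg);
        double vnew = (vv + dt * (grad + adv + vis)) /
                      (1.0 + dt * G * speed / (cf * cf * hf));
        if (vnew < V_SNAP && vnew > -V_SNAP) vnew = 0.0;
        vn[V(j, i)] = vnew;
        qv[V(j, i)] = vnew * face_h(vnew, eL, eR, zf) * dx;
      }
    }

    // ---- momentum: u faces (i = 0 and nc closed); inactive rows stay still
    for (int j = j_act; j < nr; ++j)
      for (int i = 0; i <= nc; ++i) un[U(j, i)] = 0.0;
    for (int j = 0; j < j_act; ++j) {
      u[U(j, 0)] = 0.0; u[U(j, nc)] = 0.0;
      un[U(j, 0)] = 0.0; un[U(j, nc)] = 0.0;
      for (int i = 1; i < nc; ++i) {
        double eL = eta[C(j, i - 1)], eR = eta[C(j, i)];
        double zf = std::max(zb[C(j, i - 1)], zb[C(j, i)]);
        double uu = u[U(j, i)];
        double hf = face_h(uu, eL, eR, zf);
        if (hf <= h_dry) { un[U(j, i)] = 0.0; continue; }
        double grad = -G * (eR - eL) / dx;
        double vavg;
        {
          double v1 = v[V(j, i - 1)], v2 = v[V(j, i)],
                 v3 = v[V(j + 1, i - 1)], v4 = v[V(j + 1, i)];
          vavg = 0.25 * (v1 + v2 + v3 + v4);
        }
        double adv = 0.0;
        if (adv_on) {
          if (uu > 0.0 && i >= 2) {
            adv -= uu * (uu - u[U(j, i - 1)]) / dx;
          } else if (uu < 0.0 && i + 1 < nc) {
            adv -= uu * (u[U(j, i + 1)] - uu) / dx;
          }
          if (vavg > 0.0 && j >= 1) {
            adv -= vavg * (uu - u[U(j - 1, i)]) / dy[j - 1];
          } else if (vavg < 0.0 && j + 1 < nr) {
            adv -= vavg * (u[U(j + 1, i)] - uu) / dy[j];
          }
        }
        double vis = 0.0;
        if (visc > 0.0) {
          double ul = (i >= 1) ? u[U(j, i - 1)] : uu;
          double ur = (i + 1 <= nc) ? u[U(j, i + 1)] : uu;
          double ud = (j >= 1) ? u[U(j - 1, i)] : uu;
          double uup = (j + 1 < nr) ? u[U(j + 1, i)] : uu;
          vis = visc * ((ul - 2.0 * uu + ur) / (dx * dx) +
                        (ud - 2.0 * uu + uup) / (dy[j] * dy[j]));
        }
        double cf = 0.5 * (chez[C(j, i - 1)] + chez[C(j, i)]);
        double speed = std::sqrt(uu * uu + vavg * vavg);
        double unew = (uu + dt * (grad + adv + vis)) /
                      (1.0 + dt * G * speed / (cf * cf * hf));
        if (unew < V_SNAP && unew > -V_SNAP) unew = 0.0;
        un[U(j, i)] = unew;
        qu[U(j, i)] = unew * face_h(unew, eL, eR, zf) * dy[j];
      }
    }

    apply_fluxes(dt, j_act);
    std::swap(u, un); std::swap(v, vn);
    } else {
      // ============ directionally split semi-implicit scheme ============
      // Each stage advances only its own direction's continuity + momentum
      // as a one-dimensional theta-scheme (theta >= 0.5: unconditionally
      // stable for the linearized subsystem); the transverse velocity is
      // held. Sweep order alternates between steps to symmetrize the
      // splitting error. The free surface is implicit, so the time step is
      // bound by the advective Courant number, not the gravity-wave one.
      double eb_new = bc.at(t + dt);
      double ebl_new = land_open ? bcl.at(t + dt) : 0.0;

      auto stage_x = [&](double dtt) {
        for (int j = 0; j < j_act; ++j) {
          al_u[U(j, 0)] = be_u[U(j, 0)] = hfu[U(j, 0)] = 0.0;
          al_u[U(j, nc)] = be_u[U(j, nc)] = hfu[U(j, nc)] = 0.0;
          for (int i = 1; i < nc; ++i) {
            double eL = eta[C(j, i - 1)], eR = eta[C(j, i)];
            double zf = std::max(zb[C(j, i - 1)], zb[C(j, i)]);
            double uu = u[U(j, i)];
            double hf = face_h(uu, eL, eR, zf);
            if (hf <= h_dry) {
              al_u[U(j, i)] = be_u[U(j, i)] = hfu[U(j, i)] = 0.0;
              u[U(j, i)] = 0.0;
              continue;
            }
            double vavg = 0.25 * (v[V(j, i - 1)] + v[V(j, i)] +
                                  v[V(j + 1, i - 1)] + v[V(j + 1, i)]);
            double adv = 0.0;
            if (adv_on) {
              if (uu > 0.0) adv -= uu * (uu - u[U(j, i - 1)]) / dx;
              else if (uu < 0.0) adv -= uu * (u[U(j, i + 1)] - uu) / dx;
              if (vavg > 0.0 && j >= 1) adv -= vavg * (uu - u[U(j - 1, i)]) / dy[j - 1];
              else if (vavg < 0.0 && j + 1 < nr) adv -= vavg * (u[U(j + 1, i)] - uu) / dy[j];
            }
            double vis = 0.0;
            if (visc > 0.0) {
              double ud = (j >= 1) ? u[U(j - 1, i)] : uu;
              double uup = (j + 1 < nr) ? u[U(j + 1, i)] : uu;
              vis = visc * ((u[U(j, i - 1)] - 2.0 * uu + u[U(j, i + 1)]) / (dx * dx) +
                            (ud - 2.0 * uu + uup) / (dy[j] * dy[j]));
            }
            double cf = 0.5 * (chez[C(j, i - 1)] + chez[C(j, i)]);
            double speed = std::sqrt(uu * uu + vavg * vavg);
            double D = 1.0 + dtt * G * speed / (cf * cf * hf);
            al_u[U(j, i)] = (uu + dtt * (-G * (1.0 - theta) * (eR - eL) / dx +
                                         adv + vis)) / D;
            be_u[U(j, i)] = dtt * G * theta / (dx * D);
            hfu[U(j, i)] = hf;
          }
          for (int i = 0; i < nc; ++i) {
            double gl = hfu[U(j, i)] * dy[j] * be_u[U(j, i)];
            double gr = hfu[U(j, i + 1)] * dy[j] * be_u[U(j, i + 1)];
            double q0l = hfu[U(j, i)] * dy[j] * al_u[U(j, i)];
            double q0r = hfu[U(j, i + 1)] * dy[j] * al_u[U(j, i + 1)];
            double r = dtt / area[C(j, i)];
            th_a[i] = -r * gl;
            th_c[i] = -r * gr;
            th_b[i] = 1.0 + r * (gl + gr);
            th_r[i] = eta[C(j, i)] + r * (q0l - q0r);
          }
          thomas(nc);
          for (int i = 0; i < nc; ++i) etan[C(j, i)] = th_x[i];
          for (int i = 1; i < nc; ++i) {
            if (hfu[U(j, i)] <= 0.0) continue;
            double unew = al_u[U(j, i)] +
                          be_u[U(j, i)] * (etan[C(j, i - 1)] - etan[C(j, i)]);
            if (unew < V_SNAP && unew > -V_SNAP) unew = 0.0;
            u[U(j, i)] = unew;
            qu[U(j, i)] = unew * hfu[U(j, i)] * dy[j];
          }
        }
        apply_fluxes(dtt, j_act);
      };

      auto stage_y = [&](double dtt, double ebv, double eblv) {
        int jtop = land_open ? nr : std::min(nr, j_act);
        for (int j = 0; j <= jtop; ++j) {
          for (int i = 0; i < nc; ++i) {
            double eL, eR, zL, zR, cL, cR, dist;
            bool ghostL = false, ghostR = false;
            if (j == 0) {
              eL = ebv; zL = zb[C(0, i)]; cL = chez[C(0, i)]; ghostL = true;
              eR = eta[C(0, i)]; zR = zb[C(0, i)]; cR = cL;
              dist = dy[0];
            } else if (j == nr) {
              if (!land_open) { al_v[V(j, i)] = be_v[V(j, i)] = hfv[V(j, i)] = 0.0; continue; }
              eL = eta[C(nr - 1, i)]; zL = zb[C(nr - 1, i)]; cL = chez[C(nr - 1, i)];
              eR = eblv; zR = zL; cR = cL; ghostR = true;
              dist = dy[nr - 1];
            } else {
              eL = eta[C(j - 1, i)]; zL = zb[C(j - 1, i)]; cL = chez[C(j - 1, i)];
              eR = eta[C(j, i)]; zR = zb[C(j, i)]; cR = chez[C(j, i)];
              dist = 0.5 * (dy[j - 1] + dy[j]);
            }
            double zf = (zL > zR) ? zL : zR;
            double vv = v[V(j, i)];
            double hf = face_h(vv, eL, eR, zf);
            if (hf <= h_dry) {
              al_v[V(j, i)] = be_v[V(j, i)] = hfv[V(j, i)] = 0.0;
              v[V(j, i)] = 0.0;
              continue;
            }
            double uavg;
            {
              int ju = (j == 0) ? 0 : ((j >= nr) ? nr - 1 : j);
              int jl = (j == 0) ? 0 : j - 1;
              if (jl >= nr) jl = nr - 1;
              uavg = 0.25 * (u[U(jl, i)] + u[U(jl, i + 1)] +
                             u[U(ju, i)] + u[U(ju, i + 1)]);
            }
            double adv = 0.0;
            if (adv_on && j > 0 && j < nr) {
              if (vv > 0.0) adv -= vv * (vv - v[V(j - 1, i)]) / dy[j - 1];
              else if (vv < 0.0) adv -= vv * (v[V(j + 1, i)] - vv) / dy[j];
              if (uavg > 0.0 && i >= 1) adv -= uavg * (vv - v[V(j, i - 1)]) / dx;
              else if (uavg < 0.0 && i + 1 < nc) adv -= uavg * (v[V(j, i + 1)] - vv) / dx;
            }
            double vis = 0.0;
            if (visc > 0.0 && j > 0 && j < nr) {
              double vl = (i >= 1) ? v[V(j, i - 1)] : vv;
              double vr = (i + 1 < nc) ? v[V(j, i + 1)] : vv;
              vis = visc * ((vl - 2.0 * vv + vr) / (dx * dx) +
                            (v[V(j - 1, i)] - 2.0 * vv + v[V(j + 1, i)]) /
                                (dist * dist));
            }
            double cf = 0.5 * (cL + cR);
            double speed = std::sqrt(vv * vv + uavg * uavg);
            double D = 1.0 + dtt * G * speed / (cf * cf * hf);
            double alpha = (vv + dtt * (-G * (1.0 - theta) * (eR - eL) / dist +
                                        adv + vis)) / D;
            double beta = dtt * G * theta / (dist * D);
            if (ghostL) alpha += beta * ebv;
            if (ghostR) alpha -= beta * eblv;
            al_v[V(j, i)] = alpha;
            be_v[V(j, i)] = beta;
            hfv[V(j, i)] = hf;
          }
        }
        for (int j = jtop + 1; j <= nr; ++j)
          for (int i = 0; i < nc; ++i)
            al_v[V(j, i)] = be_v[V(j, i)] = hfv[V(j, i)] = 0.0;
        for (int i = 0; i < nc; ++i) {
          int n = j_act;
          if (n == 0) continue;
          for (int j = 0; j < n; ++j) {
            double gl = hfv[V(j, i)] * dx * be_v[V(j, i)];
            double gr = hfv[V(j + 1, i)] * dx * be_v[V(j + 1, i)];
            double q0l = hfv[V(j, i)] * dx * al_v[V(j, i)];
            double q0r = hfv[V(j + 1, i)] * dx * al_v[V(j + 1, i)];
            double r = dtt / area[C(j, i)];
            th_a[j] = (j == 0) ? 0.0 : -r * gl;
            th_c[j] = (j + 1 == nr && land_open) ? 0.0 : -r * gr;
            th_b[j] = 1.0 + r * (gl + gr);
            th_r[j] = eta[C(j, i)] + r * (q0l - q0r);
          }
          thomas(n);
          for (int j = 0; j < n; ++j) etan[C(j, i)] = th_x[j];
          for (int j = 0; j <= nr; ++j) {
            if (hfv[V(j, i)] <= 0.0) continue;
            double el_new, er_new;
            if (j == 0) { el_new = 0.0; er_new = etan[C(0, i)]; }
            else if (j == nr) { el_new = etan[C(nr - 1, i)]; er_new = 0.0; }
            else {
              el_new = etan[C(j - 1, i)];
              er_new = (j <= n - 1) ? etan[C(j, i)] : eta[C(j, i)];
            }
            double vnew = al_v[V(j, i)] + be_v[V(j, i)] * (el_new - er_new);
            if (vnew < V_SNAP && vnew > -V_SNAP) vnew = 0.0;
            v[V(j, i)] = vnew;
            qv[V(j, i)] = vnew * hfv[V(j, i)] * dx;
          }
        }
        apply_fluxes(dtt, j_act);
      };

      if (step % 2 == 0) {
        stage_x(dt);
        stage_y(dt, eb_new, ebl_new);
      } else {
        stage_y(dt, eb_new, ebl_new);
        stage_x(dt);
      }
    }

    // ---- sediment transport every sed_stride hydro steps
    bool last = (step == nsteps - 1);
    if (sediment_on && ((step + 1) % sed_stride == 0 || last)) {
      double dts = dt * (1 + (step % sed_stride));
      // concentration of each cell now
      // advection with accumulated volumes; donor-cell, positivity-scaled
      std::vector<double> dm(nr * nc, 0.0);
      // donor outflow scaling
      for (int j = 0; j < nr; ++j)
        for (int i = 0; i < nc; ++i) {
          double wout = 0.0;
          if (wv[V(j, i)] < 0.0) wout -= wv[V(j, i)];
          if (wv[V(j + 1, i)] > 0.0) wout += wv[V(j + 1, i)];
          if (wu[U(j, i)] < 0.0) wout -= wu[U(j, i)];
          if (wu[U(j, i + 1)] > 0.0) wout += wu[U(j, i + 1)];
          double h = eta[C(j, i)] - zb[C(j, i)];
          // export from the pre-export volume: total exported mass
          // wout * cdon can then never exceed the mass held
          double volc = std::max(h, 0.0) * area[C(j, i)] + wout;
          double cdon = (wout > 1e-14 && volc > 1e-14)
                            ? mass[C(j, i)] / volc : 0.0;
          lam[C(j, i)] = cdon;  // reuse lam as donor concentration
        }
      auto move = [&](double w, int jd, int id, int jr, int ir, bool bdry_sea,
                      bool bdry_land) {
        if (w == 0.0) return;
        double cdon, dmass;
        if (bdry_sea) cdon = c_bc;               // flood inflow
        else cdon = lam[C(jd, id)];
        dmass = w * cdon;
        if (!bdry_sea) {
          if (dmass > mass[C(jd, id)]) dmass = mass[C(jd, id)];
          dm[C(jd, id)] -= dmass;
        } else sed_in += dmass;
        if (!bdry_land) dm[C(jr, ir)] += dmass;
        else sed_out += dmass;
      };
      for (int i = 0; i < nc; ++i) {
        double w0 = wv[V(0, i)];
        if (w0 > 0.0) move(w0, -1, -1, 0, i, true, false);
        else if (w0 < 0.0) move(-w0, 0, i, -1, -1, false, true);
        if (land_open) {
          double wl = wv[V(nr, i)];
          if (wl > 0.0) move(wl, nr - 1, i, -1, -1, false, true);
          else if (wl < 0.0) move(-wl, -1, -1, nr - 1, i, true, false);
        }
      }
      for (int j = 1; j < nr; ++j)
        for (int i = 0; i < nc; ++i) {
          double w = wv[V(j, i)];
          if (w > 0.0) move(w, j - 1, i, j, i, false, false);
          else if (w < 0.0) move(-w, j, i, j - 1, i, false, false);
        }
      for (int j = 0; j < nr; ++j)
        for (int i = 1; i < nc; ++i) {
          double w = wu[U(j, i)];
          if (w > 0.0) move(w, j, i - 1, j, i, false, false);
          else if (w < 0.0) move(-w, j, i, j, i - 1, false, false);
        }
      // apply advective mass changes
      for (int k = 0; k < nr * nc; ++k) {
        mass[k] += dm[k];
        if (mass[k] < 0.0) { clamp_mass += -mass[k]; mass[k] = 0.0; }
      }
      // horizontal diffusion (explicit, conservative, subcycled to its
      // stability limit); only wet-wet pairs exchange, through the
      // shallower of the two depths
      if (diff_k > 0.0) {
        double dymin = dy[0];
        for (int j = 1; j < nr; ++j) if (dy[j] < dymin) dymin = dy[j];
        int ndif = (int)std::ceil(diff_k * dts *
                                  (1.0 / (dx * dx) + 1.0 / (dymin * dymin)) /
                                  0.2);
        if (ndif < 1) ndif = 1;
        double dtd = dts / ndif;
        for (int it = 0; it < ndif; ++it) {
          std::fill(dm.begin(), dm.end(), 0.0);
          for (int j = 0; j < nr; ++j)
            for (int i = 0; i < nc; ++i) {
              double hL = eta[C(j, i)] - zb[C(j, i)];
              if (hL <= h_dry) continue;
              double cLc = mass[C(j, i)] / (hL * area[C(j, i)]);
              if (i + 1 < nc) {
                double hR = eta[C(j, i + 1)] - zb[C(j, i + 1)];
                if (hR > h_dry) {
                  double cRc = mass[C(j, i + 1)] / (hR * area[C(j, i + 1)]);
                  double hf = (hL < hR) ? hL : hR;
                  double f = diff_k * hf * (cRc - cLc) / dx * dy[j] * dtd;
                  dm[C(j, i)] += f; dm[C(j, i + 1)] -= f;
                }
              }
              if (j + 1 < nr) {
                double hR = eta[C(j + 1, i)] - zb[C(j + 1, i)];
                if (hR > h_dry) {
                  double cRc = mass[C(j + 1, i)] / (hR * area[C(j + 1, i)]);
                  double hf = (hL < hR) ? hL : hR;
                  double dist = 0.5 * (dy[j] + dy[j + 1]);
                  double f = diff_k * hf * (cRc - cLc) / dist * dx * dtd;
                  dm[C(j, i)] += f; dm[C(j + 1, i)] -= f;
                }
              }
            }
          for (int k = 0; k < nr * nc; ++k) {
            mass[k] += dm[k];
            if (mass[k] < 0.0) { clamp_mass += -mass[k]; mass[k] = 0.0; }
          }
        }
      }
      // settling (implicit), filtration (implicit), drying deposit, erosion
      for (int j = 0; j < nr; ++j)
        for (int i = 0; i < nc; ++i) {
          int k = C(j, i);
          double h = eta[k] - zb[k];
          if (h <= h_dry) {
            if (mass[k] > 0.0) {   // cell dried: strand the load on the bed
              dz_set[k] += mass[k] / (area[k] * rho_dry);
              mass[k] = 0.0;
            }
            continue;
          }
          double conc = mass[k] / (h * area[k]);
          if (ws > 0.0 && conc > 0.0) {
            double cs = conc / (1.0 + ws * dts / h);
            dz_set[k] += ws * cs * dts / rho_dry;
            conc = cs;
          }
          if (rhomm[k] > 0.0 && f_mm_si > 0.0 && conc > 0.0) {
            double cf2 = conc / (1.0 + rhomm[k] * f_mm_si * dts / h);
            dz_filt[k] += (conc - cf2) * h / rho_dry;
            conc = cf2;
          }
          if (erosion_on && rhomm[k] > 0.0) {
            double uc = 0.5 * (u[U(j, i)] + u[U(j, i + 1)]);
            double vc = 0.5 * (v[V(j, i)] + v[V(j + 1, i)]);
            double tau = RHO_W * G * (uc * uc + vc * vc) /
                         (chez[k] * chez[k]);
            if (tau > tau_ce) {
              double e = m_erod * (tau / tau_ce - 1.0) * dts;  // kg m^-2
              double avail = (dz_set[k] + dz_filt[k] + dz_ero[k]) * rho_dry;
              if (e > avail) e = (avail > 0.0) ? avail : 0.0;
              if (e > 0.0) {
                conc += e / h;
                dz_ero[k] -= e / rho_dry;
              }
            }
          }
          mass[k] = conc * h * area[k];
        }
      std::fill(wu.begin(), wu.end(), 0.0);
      std::fill(wv.begin(), wv.end(), 0.0);

      // ledgers
      double voln = 0.0, massn = 0.0, bedn = 0.0;
      for (int k = 0; k < nr * nc; ++k) {
        voln += std::max(eta[k] - zb[k], 0.0) * area[k];
        massn += mass[k];
        bedn += (dz_set[k] + dz_filt[k] + dz_ero[k]) * rho_dry * area[k];
      }
      double vres = std::fabs(voln - vol0 - (vol_in - vol_out) + clamp_vol) /
                    std::max(1.0, vol0 + vol_in);
      double mres = std::fabs(massn + bedn - mass0 - (sed_in - sed_out) -
                              clamp_mass) /
                    std::max(1e-12, mass0 + sed_in);
      if (vres > max_vol_resid) max_vol_resid = vres;
      if (mres > max_mass_resid) max_mass_resid = mres;
    }
  }

  NumericMatrix eta_out(nr, nc), conc_out(nr, nc), hset(nr, nc),
      hfil(nr, nc), hero(nr, nc);
  NumericMatrix u_out(nr, NU), v_out(nr + 1, nc);
  for (int j = 0; j < nr; ++j)
    for (int i = 0; i < nc; ++i) {
      eta_out(j, i) = eta[C(j, i)];
      double h = eta[C(j, i)] - zb[C(j, i)];
      conc_out(j, i) = (h > h_dry) ? mass[C(j, i)] / (h * area[C(j, i)]) : 0.0;
      hset(j, i) = dz_set[C(j, i)];
      hfil(j, i) = dz_filt[C(j, i)];
      hero(j, i) = dz_ero[C(j, i)];
    }
  for (int j = 0; j < nr; ++j)
    for (int i = 0; i < NU; ++i) u_out(j, i) = u[U(j, i)];
  for (int j = 0; j <= nr; ++j)
    for (int i = 0; i < nc; ++i) v_out(j, i) = v[V(j, i)];

  double suspended = 0.0;
  for (int k = 0; k < nr * nc; ++k) suspended += mass[k];

  List out = List::create(
      _["eta"] = eta_out, _["u"] = u_out, _["v"] = v_out,
      _["conc"] = conc_out,
      _["dz_settling"] = hset, _["dz_filtration"] = hfil,
      _["dz_erosion"] = hero,
      _["vol_in"] = vol_in, _["vol_out"] = vol_out,
      _["sed_in"] = sed_in, _["sed_out"] = sed_out,
      _["suspended_kg"] = suspended,
      _["max_vol_resid"] = max_vol_resid,
      _["max_mass_resid"] = max_mass_resid,
      _["clamp_mass_kg"] = clamp_mass, _["clamp_vol_m3"] = clamp_vol,
      _["n_steps"] = nsteps, _["dt"] = dt);
#ifdef __SSE2__
  _mm_setcsr(csr_saved);
#endif
  return out;
}
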