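// Core force kernels and the overdamped explicit-Euler integrator.
// Everything here works in reduced units: lengths in particle diameters
// (sigma), energies in epsilon, times in tau. The same kernels are exported
// individually to R (for unit and gradient tests) and used by the
// integrator, so there is a single implementation of every force term.

#include <Rcpp.h>
#include <cmath>
#include <array>
using namespace Rcpp;

static const double WCA_CUT = 1.1224620483089301;  // 2^(1/6)

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// WCA potential, truncated and shifted to vanish continuously at 2^(1/6) sigma
static inline double wca_energy(double r, double sigma, double eps) {
  if (r >= WCA_CUT * sigma) return 0.0;
  double sr6 = std::pow(sigma / r, 6.0);
  return 4.0 * eps * (sr6 * sr6 - sr6) + eps;
}

// magnitude of the repulsive WCA force (dU/dr with sign flipped)
static inline double wca_force_mag(double r, double sigma, double eps) {
  if (r >= WCA_CUT * sigma) return 0.0;
  double sr = sigma / r;
  double sr6 = std::pow(sr, 6.0);
  return 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r;
}

// Wall potential: WCA evaluated on d + sigma/2, where d is the distance from
// the particle center to the closest point of the wall. This is the
// interaction with a virtual particle half-embedded in the wall; it has the
// same contact stiffness as a particle-particle contact and vanishes for
// d > (2^(1/6) - 1/2) sigma.
static inline double wall_energy(double d, double sigma, double eps) {
  return wca_energy(d + 0.5 * sigma, sigma, eps);
}

static inline double wall_force_mag(double d, double sigma, double eps) {
  return wca_force_mag(d + 0.5 * sigma, sigma, eps);
}

// [[Rcpp::export]]
double cpp_wca_energy(double r, double sigma, double eps) {
  return wca_energy(r, sigma, eps);
}

// [[Rcpp::export]]
List cpp_wca_pair(NumericVector ri, NumericVector rj,
                  double sigma, double eps) {
  double rij[3] = {ri[0] - rj[0], ri[1] - rj[1], ri[2] - rj[2]};
  double r = norm3(rij);
  if (r <= 0.0) stop("coincident particle centers in WCA pair");
  double fmag = wca_force_mag(r, sigma, eps);
  NumericVector fi(3), fj(3);
  for (int k = 0; k < 3; ++k) {
    fi[k] = fmag * rij[k] / r;
    fj[k] = -fi[k];
  }
  return List::create(_["force_i"] = fi, _["force_j"] = fj,
                      _["energy"] = wca_energy(r, sigma, eps));
}

// [[Rcpp::export]]
double cpp_wall_energy(double d, double sigma, double eps) {
  return wall_energy(d, sigma, eps);
}

// [[Rcpp::export]]
double cpp_wall_force(double d, double sigma, double eps) {
  return wall_force_mag(d, sigma, eps);
}

// Point-dipole pair interaction. Moments mi, mj (reduced) sit at rmi, rmj.
// U = eps [ mi.mj / r^3 - 3 (mi.r)(mj.r) / r^5 ]  (distances in sigma = 1)
// Forces act on the dipole positions; torques are mu x B of the partner,
// taken about the dipole position (lever arms to the particle center are
// added by the caller).
// Below r_sat the kernel distance is saturated (magnitudes frozen at their
// r_sat values, directions kept): the dipole points sit at the cap
// centroids, well inside the particle surface, so separations below the cap
// size are outside the validity of the point-dipole approximation and the
// unsaturated 1/r^4 force would diverge faster than the center-to-center
// excluded volume can balance.
static inline void dipole_pair(const double* rmi, const double* rmj,
                               const double* mi, const double* mj,
                               double eps, double r_sat,
                               double* fi, double* ti, double* tj,
                               double* energy) {
  double rij[3] = {rmi[0] - rmj[0], rmi[1] - rmj[1], rmi[2] - rmj[2]};
  double r = norm3(rij);
  double rhat[3] = {rij[0] / r, rij[1] / r, rij[2] / r};
  double rt = r < r_sat ? r_sat : r;
  double r3 = rt * rt * rt;
  double r4 = r3 * rt;
  double mm = dot3(mi, mj);
  double mir = dot3(mi, rhat);
  double mjr = dot3(mj, rhat);
  *energy = eps * (mm - 3.0 * mir * mjr) / r3;
  // force on i = -dU/drmi
  for (int k = 0; k < 3; ++k) {
    fi[k] = eps * 3.0 / r4 *
      (mm * rhat[k] + mir * mj[k] + mjr * mi[k] - 5.0 * mir * mjr * rhat[k]);
  }
  // field of j at i (consistent with U = -mi . Bj): Bj = eps [3 rhat (mj.rhat) - mj] / r^3
  double Bj[3], Bi[3];
  for (int k = 0; k < 3; ++k) {
    Bj[k] = eps * (3.0 * rhat[k] * mjr - mj[k]) / r3;
    Bi[k] = eps * (3.0 * (-rhat[k]) * (-mir) - mi[k]) / r3;
  }
  cross3(mi, Bj, ti);
  cross3(mj, Bi, tj);
}

// [[Rcpp::export]]
List cpp_dipole_pair(NumericVector rmi, NumericVector rmj,
                     NumericVector mi, NumericVector mj, double eps,
                     double r_sat = 0.85) {
  double r[3] = {rmi[0] - rmj[0], rmi[1] - rmj[1], rmi[2] - rmj[2]};
  if (norm3(r) <= 0.0) stop("coincident dipole positions");
  double fi[3], ti[3], tj[3], energy;
  double a[3] = {rmi[0], rmi[1], rmi[2]};
  double b[3] = {rmj[0], rmj[1], rmj[2]};
  double mi_[3] = {mi[0], mi[1], mi[2]};
  double mj_[3] = {mj[0], mj[1], mj[2]};
  dipole_pair(a, b, mi_, mj_, eps, r_sat, fi, ti, tj, &energy);
  return List::create(
    _["force_i"] = NumericVector::create(fi[0], fi[1], fi[2]),
    _["force_j"] = NumericVector::create(-fi[0], -fi[1], -fi[2]),
    _["torque_i"] = NumericVector::create(ti[0], ti[1], ti[2]),
    _["torque_j"] = NumericVector::create(tj[0], tj[1], tj[2]),
    _["energy"] = energy);
}

// [[Rcpp::export]]
double cpp_dipole_energy(NumericVector rmi, NumericVector rmj,
                         NumericVector mi, NumericVector mj, double eps,
                         double r_sat = 0.85) {
  double fi[3], ti[3], tj[3], energy;
  double a[3] = {rmi[0], rmi[1], rmi[2]};
  double b[3] = {rmj[0], rmj[1], rmj[2]};
  double mi_[3] = {mi[0], mi[1], mi[2]};
  double mj_[3] = {mj[0], mj[1], mj[2]};
  dipole_pair(a, b, mi_, mj_, eps, r_sat, fi, ti, tj, &energy);
  return energy;
}

// Field program evaluation from the compiled segment table (reduced units,
// t in tau). Segment clocks start at their own t0. Columns: t0, t1, variant,
// B0, f, phase, e1(3), e2(3), e3(3), a1, a2.
static inline void field_eval(const double* segs, int nseg, double t,
                              double* B) {
  int row = nseg - 1;
  for (int i = 0; i < nseg; ++i) {
    if (t < segs[i * 17 + 1]) { row = i; break; }
  }
  const double* s = segs + row * 17;
  double tloc = t - s[0];
  int variant = (int)s[2];
  double B0 = s[3], f = s[4], phase = s[5];
  const double* e1 = s + 6;
  const double* e2 = s + 9;
  const double* e3 = s + 12;
  double a1 = s[15], a2 = s[16];
  double ang, th;
  switch (variant) {
  case 0:  // static
    for (int k = 0; k < 3; ++k) B[k] = B0 * e1[k];
    break;
  case 1:  // rotating
    ang = 2.0 * M_PI * f * tloc + phase;
    for (int k = 0; k < 3; ++k)
      B[k] = B0 * (e1[k] * std::cos(ang) + e2[k] * std::sin(ang));
    break;
  case 2:  // oscillating
    th = a1 + a2 * std::sin(2.0 * M_PI * f * tloc + phase);
    for (int k = 0; k < 3; ++k)
      B[k] = B0 * (e1[k] * std::cos(th) + e2[k] * std::sin(th));
    break;
  case 3:  // conical
    ang = 2.0 * M_PI * f * tloc + phase;
    for (int k = 0; k < 3; ++k)
      B[k] = B0 * (a1 * e3[k] +
                   a2 * (e1[k] * std::cos(ang) + e2[k] * std::sin(ang)));
    break;
  default:
    stop("unknown field variant code");
  }
}

// [[Rcpp::export]]
NumericVector cpp_field_eval(NumericMatrix segments, double t) {
  NumericMatrix st = transpose(segments);  // row-major access
  std::vector<double> segs(st.begin(), st.end());
  double B[3];
  field_eval(segs.data(), segments.nrow(), t, B);
  return NumericVector::create(B[0], B[1], B[2]);
}

struct WallDef {
  double c[3], n[3], e1[3], e2[3], h1, h2, lam_s, lam_d;
};

// Overdamped integrator. All inputs reduced: positions in sigma, times in
// tau, forces in eps/sigma. Parameters:
//   dt, n_steps, stride, gamma, gamma_r, m_star, s_off, Gc, Gm, bond_cut
// Returns frames of positions, orientations, dipole directions and field.
// [[Rcpp::export]]
List cpp_sim_run(NumericMatrix pos0, NumericMatrix u0, NumericMatrix mu0,
                 NumericMatrix walls, NumericMatrix segments, List params) {
  const int N = pos0.nrow();
  const double dt = as<double>(params["dt"]);
  const long n_steps = (long)as<double>(params["n_steps"]);
  const int stride = as<int>(params["stride"]);
  const double gamma = as<double>(params["gamma"]);
  const double gamma_r = as<double>(params["gamma_r"]);
  const double m_star = as<double>(params["m_star"]);
  const double s_off = as<double>(params["s_off"]);
  const double Gc = as<double>(params["Gc"]);
  const double Gm = as<double>(params["Gm"]);
  const double bond_cut = as<double>(params["bond_cut"]);
  double r_sat = params.containsElementNamed("r_sat") ?
    as<double>(params["r_sat"]) : 0.85;
  // bound the saturated dipole contact force at the excluded-volume scale:
  // strong moments (large caps) widen the regularization radius so that
  // 6 m*^2 / r_sat^4 never exceeds ~25 eps/sigma
  const double f_dip_max = params.containsElementNamed("f_dip_max") ?
    as<double>(params["f_dip_max"]) : 25.0;
  if (m_star > 0.0) {
    double r_need = std::pow(6.0 * m_star * m_star / f_dip_max, 0.25);
    if (r_need > r_sat) r_sat = r_need;
  }
  const double t0 = params.containsElementNamed("t0") ?
    as<double>(params["t0"]) : 0.0;
  const bool friction_on = params.containsElementNamed("friction_on") ?
    as<bool>(params["friction_on"]) : true;

  const double wall_range = WCA_CUT - 0.5;     // wall force cutoff on gap+R
  const double contact_radius = 0.5;           // friction lever arm, sigma/2
  const double max_disp = 0.5;                 // blow-up guard per step

  // copy state
  std::vector<double> rc(3 * N), u(3 * N), mu(3 * N);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < 3; ++k) {
      rc[3 * i + k] = pos0(i, k);
      u[3 * i + k] = u0(i, k);
      mu[3 * i + k] = mu0(i, k);
    }

  const int nw = walls.nrow();
  std::vector<WallDef> W(nw);
  for (int w = 0; w < nw; ++w) {
    for (int k = 0; k < 3; ++k) {
      W[w].c[k] = walls(w, k);
      W[w].n[k] = walls(w, 3 + k);
      W[w].e1[k] = walls(w, 6 + k);
      W[w].e2[k] = walls(w, 10 + k);
    }
    W[w].h1 = walls(w, 9);
    W[w].h2 = walls(w, 13);
    W[w].lam_s = walls(w, 14);
    W[w].lam_d = walls(w, 15);
  }

  NumericMatrix st = transpose(segments);
  std::vector<double> segs(st.begin(), st.end());
  const int nseg = segments.nrow();

  const long n_frames = n_steps / stride + 1;
  NumericVector out_pos(n_frames * N * 3), out_u(n_frames * N * 3),
    out_mu(n_frames * N * 3);
  NumericVector out_t(n_frames);
  NumericMatrix out_B(n_frames, 3);

  std::vector<double> F(3 * N), T(3 * N), rm(3 * N);
  std::vector<bool> in_chain(N);
  // per-particle wall contacts collected each step (normal + N + lambdas)
  std::vector<std::array<double, 6> > contacts;
  std::vector<int> contact_owner;

  long frame = 0;
  auto store_frame = [&](double t) {
    double B[3];
    field_eval(segs.data(), nseg, t, B);
    out_t[frame] = t;
    for (int k = 0; k < 3; ++k) out_B(frame, k) = B[k];
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) {
        long idx = frame + n_frames * ((long)i + (long)N * k);
        out_pos[idx] = rc[3 * i + k];
        out_u[idx] = u[3 * i + k];
        out_mu[idx] = mu[3 * i + k];
      }
    ++frame;
  };

  store_frame(t0);

  for (long step = 0; step < n_steps; ++step) {
    double t = t0 + step * dt;
    double B[3];
    field_eval(segs.data(), nseg, t, B);

    std::fill(F.begin(), F.end(), 0.0);
    std::fill(T.begin(), T.end(), 0.0);
    std::fill(in_chain.begin(), in_chain.end(), false);
    contacts.clear();
    contact_owner.clear();

    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k)
        rm[3 * i + k] = rc[3 * i + k] - s_off * u[3 * i + k];

    // body loads: center weight at rc (force only), cap weight at rm
    for (int i = 0; i < N; ++i) {
      F[3 * i + 2] -= Gc + Gm;
      double lever[3] = {-s_off * u[3 * i], -s_off * u[3 * i + 1],
                         -s_off * u[3 * i + 2]};
      double gvec[3] = {0.0, 0.0, -Gm};
      double tq[3];
      cross3(lever, gvec, tq);
      for (int k = 0; k < 3; ++k) T[3 * i + k] += tq[k];
      // external field torque on the dipole
      double m_i[3] = {m_star * mu[3 * i], m_star * mu[3 * i + 1],
                       m_star * mu[3 * i + 2]};
      double tb[3];
      cross3(m_i, B, tb);
      for (int k = 0; k < 3; ++k) T[3 * i + k] += tb[k];
    }

    // pair interactions
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double rij[3] = {rc[3 * i] - rc[3 * j], rc[3 * i + 1] - rc[3 * j + 1],
                         rc[3 * i + 2] - rc[3 * j + 2]};
        double r = norm3(rij);
        if (r <= 0.0) {
          stop("coincident centers of particles %d and %d at step %ld",
               i + 1, j + 1, step);
        }
        if (r < bond_cut) { in_chain[i] = true; in_chain[j] = true; }
        double fmag = wca_force_mag(r, 1.0, 1.0);
        if (fmag != 0.0) {
          for (int k = 0; k < 3; ++k) {
            double f = fmag * rij[k] / r;
            F[3 * i + k] += f;
            F[3 * j + k] -= f;
          }
        }
        // dipoles (skip if negligible)
        if (m_star > 0.0) {
          double m_i[3] = {m_star * mu[3 * i], m_star * mu[3 * i + 1],
                           m_star * mu[3 * i + 2]};
          double m_j[3] = {m_star * mu[3 * j], m_star * mu[3 * j + 1],
                           m_star * mu[3 * j + 2]};
          double fi[3], ti[3], tj[3], energy;
          dipole_pair(&rm[3 * i], &rm[3 * j], m_i, m_j, 1.0, r_sat,
                      fi, ti, tj, &energy);
          double li[3] = {-s_off * u[3 * i], -s_off * u[3 * i + 1],
                          -s_off * u[3 * i + 2]};
          double lj[3] = {-s_off * u[3 * j], -s_off * u[3 * j + 1],
                          -s_off * u[3 * j + 2]};
          double ai[3], aj[3];
          double fj[3] = {-fi[0], -fi[1], -fi[2]};
          cross3(li, fi, ai);
          cross3(lj, fj, aj);
          for (int k = 0; k < 3; ++k) {
            F[3 * i + k] += fi[k];
            F[3 * j + k] -= fi[k];
            T[3 * i + k] += ti[k] + ai[k];
            T[3 * j + k] += tj[k] + aj[k];
          }
        }
      }
    }

    // walls: closest-feature contact, WCA-type normal force
    for (int i = 0; i < N; ++i) {
      for (int w = 0; w < nw; ++w) {
        double rel[3] = {rc[3 * i] - W[w].c[0], rc[3 * i + 1] - W[w].c[1],
                         rc[3 * i + 2] - W[w].c[2]};
        double c1 = dot3(rel, W[w].e1);
        double c2 = dot3(rel, W[w].e2);
        double c1c = std::max(-W[w].h1, std::min(W[w].h1, c1));
        double c2c = std::max(-W[w].h2, std::min(W[w].h2, c2));
        double v[3];
        for (int k = 0; k < 3; ++k)
          v[k] = rel[k] - c1c * W[w].e1[k] - c2c * W[w].e2[k];
        double dist = norm3(v);
        // walls are thin and two-sided: the repulsion acts along the
        // vector from the closest wall point toward the particle center,
        // whichever side it is on; a center too close to the surface to
        // resolve the side aborts the run
        if (dist < 0.05) {
          stop("particle %d penetrated wall %d at step %ld "
               "(integration blow-up guard)", i + 1, w + 1, step);
        }
        if (dist < wall_range) {
          double nf = wall_force_mag(dist, 1.0, 1.0);
          std::array<double, 6> ct;
          for (int k = 0; k < 3; ++k) {
            double nk = v[k] / dist;
            F[3 * i + k] += nf * nk;
            ct[k] = nk;
          }
          ct[3] = nf;
          ct[4] = W[w].lam_s;
          ct[5] = W[w].lam_d;
          contacts.push_back(ct);
          contact_owner.push_back(i);
        }
      }
    }

    // Coulomb stick-slip friction for particles in chain contact
    if (friction_on) {
      for (size_t ci = 0; ci < contacts.size(); ++ci) {
        int i = contact_owner[ci];
        if (!in_chain[i]) continue;  // single particles roll, no friction
        const double* n = contacts[ci].data();
        double Nf = contacts[ci][3];
        double lam_s = contacts[ci][4];
        double lam_d = contacts[ci][5];
        if (Nf <= 0.0) continue;
        double fn = dot3(&F[3 * i], n);
        double Ft[3] = {F[3 * i] - fn * n[0], F[3 * i + 1] - fn * n[1],
                        F[3 * i + 2] - fn * n[2]};
        double ft = norm3(Ft);
        if (ft <= lam_s * Nf) {
          for (int k = 0; k < 3; ++k) F[3 * i + k] -= Ft[k];
        } else {
          double fk = lam_d * Nf / ft;
          for (int k = 0; k < 3; ++k) F[3 * i + k] -= fk * Ft[k];
        }
        double Tn = dot3(&T[3 * i], n);
        double cap_s = lam_s * Nf * contact_radius;
        double cap_d = lam_d * Nf * contact_radius;
        if (std::fabs(Tn) <= cap_s) {
          for (int k = 0; k < 3; ++k) T[3 * i + k] -= Tn * n[k];
        } else {
          double sgn = Tn > 0 ? 1.0 : -1.0;
          for (int k = 0; k < 3; ++k) T[3 * i + k] -= sgn * cap_d * n[k];
        }
      }
    }

    // Euler update
    for (int i = 0; i < N; ++i) {
      double dr[3];
      for (int k = 0; k < 3; ++k) dr[k] = dt / gamma * F[3 * i + k];
      double dnorm = norm3(dr);
      if (dnorm > max_disp) {
        stop("timestep too large: particle %d moved %.3f sigma in one step "
             "at step %ld (t = %.4f tau)", i + 1, dnorm, step, t);
      }
      for (int k = 0; k < 3; ++k) rc[3 * i + k] += dr[k];

      double w[3];
      for (int k = 0; k < 3; ++k) w[k] = dt / gamma_r * T[3 * i + k];
      double ang = norm3(w);
      if (ang > 0.0) {
        double axis[3] = {w[0] / ang, w[1] / ang, w[2] / ang};
        double ca = std::cos(ang), sa = std::sin(ang);
        double* vecs[2] = {&u[3 * i], &mu[3 * i]};
        for (int vv = 0; vv < 2; ++vv) {
          double* x = vecs[vv];
          double axv[3];
          cross3(axis, x, axv);
          double ad = dot3(axis, x);
          double nx[3];
          for (int k = 0; k < 3; ++k)
            nx[k] = x[k] * ca + axv[k] * sa + axis[k] * ad * (1.0 - ca);
          for (int k = 0; k < 3; ++k) x[k] = nx[k];
        }
      }
      // re-orthonormalize the body frame
      double un = norm3(&u[3 * i]);
      for (int k = 0; k < 3; ++k) u[3 * i + k] /= un;
      double proj = dot3(&mu[3 * i], &u[3 * i]);
      for (int k = 0; k < 3; ++k) mu[3 * i + k] -= proj * u[3 * i + k];
      double mn = norm3(&mu[3 * i]);
      for (int k = 0; k < 3; ++k) mu[3 * i + k] /= mn;
    }

    if ((step + 1) % stride == 0 && frame < n_frames) {
      store_frame(t0 + (step + 1) * dt);
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  out_pos.attr("dim") = IntegerVector::create(n_frames, N, 3);
  out_u.attr("dim") = IntegerVector::create(n_frames, N, 3);
  out_mu.attr("dim") = IntegerVector::create(n_frames, N, 3);
  return List::create(_["times"] = out_t, _["pos"] = out_pos,
                      _["u"] = out_u, _["mu"] = out_mu, _["field"] = out_B);
}
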