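#include "deltamd.h"
using namespace Rcpp;

struct MLPack {
  bool on;
  DescSpec spec;
  MLEval ev;
  double econst_per_mol, econst0;
};

// combined potential evaluation; returns potential energy
static double eval_forces(int level, const TLParams& p, const MLPack& ml,
                          const std::vector<double>& x, int n,
                          const std::vector<int>& elem,
                          const std::vector<int>& mol, int nmol,
                          double L, bool periodic,
                          const std::vector< std::vector<Neigh> >& nb,
                          std::vector<double>& F, double* W) {
  std::fill(F.begin(), F.end(), 0.0);
  std::fill(W, W + 9, 0.0);
  double E = 0.0;
  if (level != POT_NONE)
    E += tl_energy_forces(level, p, x, n, elem, mol, nmol, L, periodic, nb, F, W);
  if (ml.on) {
    E += ml.ev.eval(n, elem, nb, F, W);
    E += ml.econst0 + ml.econst_per_mol * nmol;
  }
  return E;
}

// [[Rcpp::export]]
List md_run_cpp(NumericMatrix pos, IntegerVector elem, NumericVector mass,
                IntegerVector mol, double L, std::string potential,
                List theory, Nullable<List> mlmodel,
                std::string ensemble, double dt_fs, int nsteps, int stride,
                double T, double tauT_fs, double P_bar, double tauP_fs,
                double kappa_per_bar, int seed,
                Nullable<NumericMatrix> vel0, bool remove_com) {
  int n = pos.nrow();
  TLParams p = parse_theory(theory);
  int level;
  if (potential == "LL") level = POT_LL;
  else if (potential == "HL") level = POT_HL;
  else if (potential == "none") level = POT_NONE;
  else if (potential == "composite") level = POT_LL;
  else stop("unknown potential '%s'", potential.c_str());

  MLPack ml; ml.on = false;
  ml.econst0 = 0.0; ml.econst_per_mol = 0.0;
  if (potential == "composite") {
    if (mlmodel.isNull()) stop("composite potential requires a trained delta model");
    List m(mlmodel);
    ml.on = true;
    ml.spec = parse_spec(m["spec"]);
    ml.ev.init(ml.spec, as<std::vector<double> >(m["vO"]),
               as<std::vector<double> >(m["vH"]));
    ml.econst0 = as<double>(m["econst0"]);
    ml.econst_per_mol = as<double>(m["econst_per_mol"]);
  }

  std::vector<double> x(3*n), v(3*n), m_(n);
  std::vector<int> el(elem.begin(), elem.end()), mo(n);
  int nmol = 0;
  for (int i = 0; i < n; ++i) {
    x[3*i] = pos(i,0); x[3*i+1] = pos(i,1); x[3*i+2] = pos(i,2);
    m_[i] = mass[i];
    mo[i] = mol[i] - 1; nmol = std::max(nmol, mol[i]);
  }

  double rmax = 0.0;
  if (level != POT_NONE)
    rmax = std::max(p.r_coul, std::max(p.r_lj, std::max(p.d_rc, p.r3)));
  if (ml.on) rmax = std::max(rmax, ml.spec.rc);
  double skin = 0.5;
  double rlist = (rmax > 0.0) ? rmax + skin : 0.0;
  if (rmax > 0.0 && L < 2.0 * rmax)
    stop("box edge %.3f A too small for twice the cutoff %.3f A", L, rmax);

  double dt = dt_fs / TIME_FS;
  double tauT = tauT_fs / TIME_FS, tauP = tauP_fs / TIME_FS;
  double P0 = P_bar * BAR_EVA3;
  double kappa = kappa_per_bar / BAR_EVA3; // A^3/eV relative compressibility

  RNG rng((std::uint64_t)seed * 2654435761u + 1234567u);

  // initial velocities (A/fs at the boundary, internal units inside)
  if (vel0.isNotNull()) {
    NumericMatrix v0(vel0);
    for (int i = 0; i < n; ++i) {
      v[3*i] = v0(i,0) * TIME_FS; v[3*i+1] = v0(i,1) * TIME_FS;
      v[3*i+2] = v0(i,2) * TIME_FS;
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(KB_EV * T / m_[i]);
      v[3*i] = s * rng.norm(); v[3*i+1] = s * rng.norm(); v[3*i+2] = s * rng.norm();
    }
  }
  if (remove_com) {
    double px = 0, py = 0, pz = 0, M = 0;
    for (int i = 0; i < n; ++i) {
      px += m_[i]*v[3*i]; py += m_[i]*v[3*i+1]; pz += m_[i]*v[3*i+2]; M += m_[i];
    }
    for (int i = 0; i < n; ++i) {
      v[3*i] -= px/M; v[3*i+1] -= py/M; v[3*i+2] -= pz/M;
    }
  }
  int ndf = remove_com ? 3*n - 3 : 3*n;

  bool do_T = (ensemble == "nvt" || ensemble == "npt");
  bool do_P = (ensemble == "npt");
  if (do_P && rlist == 0.0 && false) {} // ideal-gas NPT is allowed

  std::vector< std::vector<Neigh> > nb;
  std::vector<double> xb; // positions at last neighbour build
  auto rebuild = [&]() {
    if (rlist > 0.0) build_neighbours(x, n, L, true, rlist, nb);
    xb = x;
  };
  auto need_rebuild = [&]() -> bool {
    if (rlist == 0.0) return false;
    double lim = 0.25 * skin * skin; // (skin/2)^2
    for (int i = 0; i < 3*n; i += 3) {
      double dx = x[i]-xb[i], dy = x[i+1]-xb[i+1], dz = x[i+2]-xb[i+2];
      if (dx*dx + dy*dy + dz*dz > lim) return true;
    }
    return false;
  };
  rebuild();

  std::vector<double> F(3*n, 0.0);
  double W[9];
  double U = eval_forces(level, p, ml, x, n, el, mo, nmol, L, true, nb, F, W);
  for (int i = 0; i < 3*n; ++i)
    if (!std::isfinite(F[i])) stop("non-finite force at initialisation");

  double cons_acc = 0.0; // thermostat work accumulator

  int nrec = nsteps + 1;
  NumericVector s_t(nrec), s_T(nrec), s_K(nrec), s_U(nrec), s_E(nrec),
                s_cons(nrec), s_P(nrec), s_V(nrec), s_L(nrec);
  int nframes = nsteps / std::max(stride, 1) + 1;
  List frames(nframes);
  NumericVector frame_L(nframes), frame_t(nframes);
  int fidx = 0;

  auto kinetic = [&]() {
    double K = 0.0;
    for (int i = 0; i < n; ++i)
      K += 0.5 * m_[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    return K;
  };
  std::vector<double> cmx(nmol), cmy(nmol), cmz(nmol), cmm(nmol, 0.0);
  for (int i = 0; i < n; ++i) cmm[mo[i]] += m_[i];
  auto mol_centres = [&]() {
    std::fill(cmx.begin(), cmx.end(), 0.0);
    std::fill(cmy.begin(), cmy.end(), 0.0);
    std::fill(cmz.begin(), cmz.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      cmx[mo[i]] += m_[i]*x[3*i]; cmy[mo[i]] += m_[i]*x[3*i+1];
      cmz[mo[i]] += m_[i]*x[3*i+2];
    }
    for (int mq = 0; mq < nmol; ++mq) {
      cmx[mq] /= cmm[mq]; cmy[mq] /= cmm[mq]; cmz[mq] /= cmm[mq];
    }
  };
  // molecular (centre-of-mass) pressure: conjugate to molecular-centre
  // scaling; P = (2 K_mol + tr W_mol) / 3V with
  // tr W_mol = tr W_atomic - sum_i F_i . (r_i - R_mol(i))
  auto mol_pressure = [&]() {
    mol_centres();
    double Kmol = 0.0;
    std::vector<double> px(nmol, 0.0), py(nmol, 0.0), pz(nmol, 0.0);
    for (int i = 0; i < n; ++i) {
      px[mo[i]] += m_[i]*v[3*i]; py[mo[i]] += m_[i]*v[3*i+1];
      pz[mo[i]] += m_[i]*v[3*i+2];
    }
    for (int mq = 0; mq < nmol; ++mq)
      Kmol += 0.5 * (px[mq]*px[mq] + py[mq]*py[mq] + pz[mq]*pz[mq]) / cmm[mq];
    double trW = W[0] + W[4] + W[8];
    double corr = 0.0;
    for (int i = 0; i < n; ++i)
      corr += F[3*i]   * (x[3*i]   - cmx[mo[i]])
            + F[3*i+1] * (x[3*i+1] - cmy[mo[i]])
            + F[3*i+2] * (x[3*i+2] - cmz[mo[i]]);
    double V = L*L*L;
    return (2.0 * Kmol + trW - corr) / (3.0 * V);
  };
  auto record_series = [&](int step) {
    double K = kinetic();
    double V = L*L*L;
    double trW = W[0] + W[4] + W[8];
    s_t[step] = step * dt_fs;
    s_K[step] = K; s_U[step] = U; s_E[step] = K + U;
    s_T[step] = 2.0 * K / (ndf * KB_EV);
    s_cons[step] = K + U + cons_acc;
    s_P[step] = mol_pressure() / BAR_EVA3;
    s_V[step] = V; s_L[step] = L;
  };
  auto record_frame = [&](int step) {
    NumericMatrix fr(n, 3);
    for (int i = 0; i < n; ++i) {
      fr(i,0) = x[3*i]; fr(i,1) = x[3*i+1]; fr(i,2) = x[3*i+2];
    }
    frames[fidx] = fr; frame_L[fidx] = L; frame_t[fidx] = step * dt_fs;
    ++fidx;
  };

  record_series(0); record_frame(0);

  for (int step = 1; step <= nsteps; ++step) {
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / m_[i];
      v[3*i] += h*F[3*i]; v[3*i+1] += h*F[3*i+1]; v[3*i+2] += h*F[3*i+2];
    }
    for (int i = 0; i < 3*n; ++i) x[i] += dt * v[i];
    if (need_rebuild()) rebuild();
    else refresh_neighbours(x, L, true, nb);
    U = eval_forces(level, p, ml, x, n, el, mo, nmol, L, true, nb, F, W);
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt / m_[i];
      v[3*i] += h*F[3*i]; v[3*i+1] += h*F[3*i+1]; v[3*i+2] += h*F[3*i+2];
      if (!std::isfinite(v[3*i])) stop("non-finite state at step %d", step);
    }
    if (do_T) {
      // CSVR (canonical sampling through velocity rescaling)
      double K = kinetic();
      if (K > 0.0) {
        double c = std::exp(-dt / tauT);
        double Kbar = 0.5 * ndf * KB_EV * T;
        double r1 = rng.norm();
        double s = (ndf > 1) ? rng.chisq((double)(ndf - 1)) : 0.0;
        double Knew = K*c + Kbar/ndf*(1.0-c)*(r1*r1 + s)
                    + 2.0*r1*std::sqrt(K*Kbar/ndf*c*(1.0-c));
        if (Knew < 0.0) Knew = 0.0;
        double al = std::sqrt(Knew / K);
        for (int i = 0; i < 3*n; ++i) v[i] *= al;
        cons_acc -= (Knew - K);
      }
    }
    if (do_P) {
      // stochastic cell rescaling (isotropic, molecular-centre scaling)
      double V = L*L*L;
      double Pint = mol_pressure();
      if (!std::isfinite(Pint)) stop("non-finite pressure at step %d", step);
      double deps = kappa/tauP * (Pint - P0) * dt
                  + std::sqrt(2.0*KB_EV*T*kappa/(V*tauP)*dt) * rng.norm();
      double lamf = std::exp(deps / 3.0);
      // scale molecular centres of mass (mol_pressure() refreshed them)
      double sh = lamf - 1.0;
      for (int i = 0; i < n; ++i) {
        x[3*i]   += sh * cmx[mo[i]];
        x[3*i+1] += sh * cmy[mo[i]];
        x[3*i+2] += sh * cmz[mo[i]];
      }
      L *= lamf;
      double invl = 1.0 / lamf;
      for (int i = 0; i < 3*n; ++i) v[i] *= invl;
      if (rmax > 0.0 && L < 2.0 * rmax)
        stop("box collapsed below twice the interaction range at step %d", step);
    }
    record_series(step);
    if (stride > 0 && step % stride == 0) record_frame(step);
  }

  NumericMatrix xo(n, 3), vo(n, 3);
  for (int i = 0; i < n; ++i) {
    xo(i,0) = x[3*i]; xo(i,1) = x[3*i+1]; xo(i,2) = x[3*i+2];
    vo(i,0) = v[3*i] / TIME_FS; vo(i,1) = v[3*i+1] / TIME_FS;
    vo(i,2) = v[3*i+2] / TIME_FS;
  }
  if (fidx < nframes) {
    frames = frames[Range(0, fidx - 1)];
    frame_L = frame_L[Range(0, fidx - 1)];
    frame_t = frame_t[Range(0, fidx - 1)];
  }
  DataFrame series = DataFrame::create(
    _["t_fs"] = s_t, _["T_K"] = s_T, _["K_eV"] = s_K, _["U_eV"] = s_U,
    _["E_eV"] = s_E, _["conserved_eV"] = s_cons, _["P_bar"] = s_P,
    _["V_A3"] = s_V, _["L_A"] = s_L);
  return List::create(
    _["frames"] = frames, _["frame_L"] = frame_L, _["frame_t"] = frame_t,
    _["series"] = series, _["final_positions"] = xo,
    _["final_velocities"] = vo, _["final_L"] = L, _["seed"] = seed);
}
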