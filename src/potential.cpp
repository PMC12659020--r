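#include "deltamd.h"
using namespace Rcpp;

void build_neighbours(const std::vector<double>& x, int n, double L,
                      bool periodic, double rmax,
                      std::vector< std::vector<Neigh> >& nb) {
  nb.assign(n, std::vector<Neigh>());
  double r2max = rmax * rmax;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[3*j] - x[3*i];
      double dy = x[3*j+1] - x[3*i+1];
      double dz = x[3*j+2] - x[3*i+2];
      if (periodic) { dx = mic(dx, L); dy = mic(dy, L); dz = mic(dz, L); }
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < r2max) {
        double r = std::sqrt(r2);
        Neigh a; a.j = j; a.dx = dx; a.dy = dy; a.dz = dz; a.r = r;
        nb[i].push_back(a);
        Neigh b; b.j = i; b.dx = -dx; b.dy = -dy; b.dz = -dz; b.r = r;
        nb[j].push_back(b);
      }
    }
  }
}

void refresh_neighbours(const std::vector<double>& x, double L, bool periodic,
                        std::vector< std::vector<Neigh> >& nb) {
  int n = (int)nb.size();
  for (int i = 0; i < n; ++i) {
    for (size_t a = 0; a < nb[i].size(); ++a) {
      Neigh& nn = nb[i][a];
      double dx = x[3*nn.j] - x[3*i];
      double dy = x[3*nn.j+1] - x[3*i+1];
      double dz = x[3*nn.j+2] - x[3*i+2];
      if (periodic) { dx = mic(dx, L); dy = mic(dy, L); dz = mic(dz, L); }
      nn.dx = dx; nn.dy = dy; nn.dz = dz;
      nn.r = std::sqrt(dx*dx + dy*dy + dz*dz);
    }
  }
}

// accumulate virial W += rvec (x) fvec   (rvec = r_j - r_i, fvec = force on j)
static inline void add_virial(double* W, double dx, double dy, double dz,
                              double fx, double fy, double fz) {
  W[0] += dx*fx; W[1] += dx*fy; W[2] += dx*fz;
  W[3] += dy*fx; W[4] += dy*fy; W[5] += dy*fz;
  W[6] += dz*fx; W[7] += dz*fy; W[8] += dz*fz;
}

// smooth SW-style switch, s(r) = exp(gamma/(r - rc)) for r < rc, else 0
static inline double sw_s(double r, double rc, double gamma, double& ds) {
  if (r >= rc) { ds = 0.0; return 0.0; }
  double inv = 1.0 / (r - rc);
  double s = std::exp(gamma * inv);
  ds = -gamma * inv * inv * s;
  return s;
}

double tl_energy_forces(int level, const TLParams& p,
                        const std::vector<double>& x, int n,
                        const std::vector<int>& elem,
                        const std::vector<int>& mol, int nmol,
                        double L, bool periodic,
                        const std::vector< std::vector<Neigh> >& nb,
                        std::vector<double>& F, double* W) {
  double E = 0.0;
  if (level == POT_NONE) return 0.0;
  bool base  = (level == POT_LL || level == POT_HL);
  bool extra = (level == POT_HL || level == POT_DELTA);

  // --- intramolecular (shared by LL and HL; absent from the delta) ---
  if (base) {
    // per-molecule O and H indices
    std::vector<int> mO(nmol, -1);
    std::vector< std::vector<int> > mH(nmol);
    for (int i = 0; i < n; ++i) {
      if (elem[i] == 8) mO[mol[i]] = i; else mH[mol[i]].push_back(i);
    }
    for (int m = 0; m < nmol; ++m) {
      int io = mO[m];
      if (io < 0 || mH[m].empty()) continue; // monatomic species: no terms
      // bonds
      for (size_t h = 0; h < mH[m].size(); ++h) {
        int ih = mH[m][h];
        double dx = x[3*ih] - x[3*io], dy = x[3*ih+1] - x[3*io+1],
               dz = x[3*ih+2] - x[3*io+2];
        if (periodic) { dx = mic(dx, L); dy = mic(dy, L); dz = mic(dz, L); }
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        double dr = r - p.r0;
        E += 0.5 * p.k_bond * dr * dr;
        double fmag = -p.k_bond * dr / r;  // force on H along +d
        double fx = fmag*dx, fy = fmag*dy, fz = fmag*dz;
        F[3*ih] += fx; F[3*ih+1] += fy; F[3*ih+2] += fz;
        F[3*io] -= fx; F[3*io+1] -= fy; F[3*io+2] -= fz;
        add_virial(W, dx, dy, dz, fx, fy, fz);
      }
      // H-O-H angle
      if (mH[m].size() == 2) {
        int j = mH[m][0], k = mH[m][1];
        double ux = x[3*j] - x[3*io], uy = x[3*j+1] - x[3*io+1],
               uz = x[3*j+2] - x[3*io+2];
        double vx = x[3*k] - x[3*io], vy = x[3*k+1] - x[3*io+1],
               vz = x[3*k+2] - x[3*io+2];
        if (periodic) {
          ux = mic(ux, L); uy = mic(uy, L); uz = mic(uz, L);
          vx = mic(vx, L); vy = mic(vy, L); vz = mic(vz, L);
        }
        double ru = std::sqrt(ux*ux + uy*uy + uz*uz);
        double rv = std::sqrt(vx*vx + vy*vy + vz*vz);
        double ct = (ux*vx + uy*vy + uz*vz) / (ru * rv);
        ct = std::max(-1.0, std::min(1.0, ct));
        double th = std::acos(ct), st = std::sqrt(1.0 - ct*ct);
        if (st < 1e-8) st = 1e-8;
        double dth = th - p.theta0;
        E += 0.5 * p.k_angle * dth * dth;
        double dEdct = -p.k_angle * dth / st; // dE/dcos
        // grad of cos wrt j and k
        double gjx = vx/(ru*rv) - ct*ux/(ru*ru);
        double gjy = vy/(ru*rv) - ct*uy/(ru*ru);
        double gjz = vz/(ru*rv) - ct*uz/(ru*ru);
        double gkx = ux/(ru*rv) - ct*vx/(rv*rv);
        double gky = uy/(ru*rv) - ct*vy/(rv*rv);
        double gkz = uz/(ru*rv) - ct*vz/(rv*rv);
        double fjx = -dEdct*gjx, fjy = -dEdct*gjy, fjz = -dEdct*gjz;
        double fkx = -dEdct*gkx, fky = -dEdct*gky, fkz = -dEdct*gkz;
        F[3*j] += fjx; F[3*j+1] += fjy; F[3*j+2] += fjz;
        F[3*k] += fkx; F[3*k+1] += fky; F[3*k+2] += fkz;
        F[3*io] -= fjx + fkx; F[3*io+1] -= fjy + fky; F[3*io+2] -= fjz + fkz;
        add_virial(W, ux, uy, uz, fjx, fjy, fjz);
        add_virial(W, vx, vy, vz, fkx, fky, fkz);
      }
    }
  }

  // --- pairwise terms ---
  // DSF Coulomb shifts
  double erfcRc = std::erfc(p.alpha * p.r_coul);
  double shiftE = erfcRc / p.r_coul;
  double twoapi = 2.0 * p.alpha / std::sqrt(M_PI);
  double shiftF = erfcRc / (p.r_coul * p.r_coul)
                + twoapi * std::exp(-p.alpha*p.alpha*p.r_coul*p.r_coul) / p.r_coul;
  // shifted-force LJ reference values at cutoff
  double src6 = std::pow(p.sigma / p.r_lj, 6.0);
  double uRc  = 4.0 * p.eps * (src6*src6 - src6);
  double duRc = -24.0 * p.eps * (2.0*src6*src6 - src6) / p.r_lj;

  for (int i = 0; i < n; ++i) {
    const std::vector<Neigh>& ni = nb[i];
    for (size_t a = 0; a < ni.size(); ++a) {
      const Neigh& nn = ni[a];
      int j = nn.j;
      if (j < i) continue;              // each pair once
      if (mol[i] == mol[j]) continue;   // nonbonded is intermolecular only
      double r = nn.r;
      double fmag = 0.0;                // magnitude along +d (positive = repel)
      bool bothO = (elem[i] == 8 && elem[j] == 8);
      if (base && r < p.r_coul) {
        double qi = (elem[i] == 8) ? p.qO : p.qH;
        double qj = (elem[j] == 8) ? p.qO : p.qH;
        double qq = KE_COUL * qi * qj;
        double er = std::erfc(p.alpha * r);
        E += qq * (er / r - shiftE + shiftF * (r - p.r_coul));
        fmag += qq * (er/(r*r) + twoapi*std::exp(-p.alpha*p.alpha*r*r)/r - shiftF);
      }
      if (base && bothO && r < p.r_lj) {
        double sr6 = std::pow(p.sigma / r, 6.0);
        double u  = 4.0 * p.eps * (sr6*sr6 - sr6);
        double du = -24.0 * p.eps * (2.0*sr6*sr6 - sr6) / r;
        E += u - uRc - (r - p.r_lj) * duRc;
        fmag += -(du - duRc);
      }
      if (extra && bothO && r < p.d_rc && p.d_eps != 0.0) {
        // Gaussian attractive well on the first O-O shell, cosine-switched
        // to zero (with zero slope) at d_rc
        double g  = std::exp(-(r - p.d_sigma)*(r - p.d_sigma)
                             / (2.0 * p.d_width * p.d_width));
        double u  = -p.d_eps * g;
        double du = -u * (r - p.d_sigma) / (p.d_width * p.d_width);
        double S = 1.0, dS = 0.0;
        if (r >= p.d_ron) {
          double w = p.d_rc - p.d_ron, t = M_PI * (r - p.d_ron) / w;
          S = 0.5 * (1.0 + std::cos(t));
          dS = -0.5 * M_PI / w * std::sin(t);
        }
        E += u * S;
        fmag += -(du * S + u * dS);
      }
      if (fmag != 0.0) {
        double fx = fmag * nn.dx / r, fy = fmag * nn.dy / r, fz = fmag * nn.dz / r;
        F[3*j] += fx; F[3*j+1] += fy; F[3*j+2] += fz;
        F[3*i] -= fx; F[3*i+1] -= fy; F[3*i+2] -= fz;
        add_virial(W, nn.dx, nn.dy, nn.dz, fx, fy, fz);
      }
    }
  }

  // --- O-O-O three-body (HL extra) ---
  if (extra && p.lambda3 != 0.0) {
    for (int i = 0; i < n; ++i) {
      if (elem[i] != 8) continue;
      // O neighbours within r3
      std::vector<const Neigh*> on;
      for (size_t a = 0; a < nb[i].size(); ++a) {
        const Neigh& nn = nb[i][a];
        if (elem[nn.j] == 8 && nn.r < p.r3 && mol[nn.j] != mol[i]) on.push_back(&nn);
      }
      for (size_t a = 0; a < on.size(); ++a) {
        for (size_t b = a + 1; b < on.size(); ++b) {
          const Neigh* u = on[a]; const Neigh* v = on[b];
          double ru = u->r, rv = v->r;
          double ct = (u->dx*v->dx + u->dy*v->dy + u->dz*v->dz) / (ru * rv);
          double dsu, dsv;
          double su = sw_s(ru, p.r3, p.gamma3, dsu);
          double sv = sw_s(rv, p.r3, p.gamma3, dsv);
          double q = ct - p.cos0;
          double A = p.lambda3 * q * q;
          double dAdct = 2.0 * p.lambda3 * q;
          E += A * su * sv;
          // grad cos wrt j (=u->j) and k (=v->j)
          double gjx = v->dx/(ru*rv) - ct*u->dx/(ru*ru);
          double gjy = v->dy/(ru*rv) - ct*u->dy/(ru*ru);
          double gjz = v->dz/(ru*rv) - ct*u->dz/(ru*ru);
          double gkx = u->dx/(ru*rv) - ct*v->dx/(rv*rv);
          double gky = u->dy/(ru*rv) - ct*v->dy/(rv*rv);
          double gkz = u->dz/(ru*rv) - ct*v->dz/(rv*rv);
          double cj = dAdct * su * sv, cu = A * dsu * sv / ru;
          double ck = dAdct * su * sv, cv = A * su * dsv / rv;
          double fjx = -(cj*gjx + cu*u->dx), fjy = -(cj*gjy + cu*u->dy),
                 fjz = -(cj*gjz + cu*u->dz);
          double fkx = -(ck*gkx + cv*v->dx), fky = -(ck*gky + cv*v->dy),
                 fkz = -(ck*gkz + cv*v->dz);
          int jj = u->j, kk = v->j;
          F[3*jj] += fjx; F[3*jj+1] += fjy; F[3*jj+2] += fjz;
          F[3*kk] += fkx; F[3*kk+1] += fky; F[3*kk+2] += fkz;
          F[3*i]  -= fjx + fkx; F[3*i+1] -= fjy + fky; F[3*i+2] -= fjz + fkz;
          add_virial(W, u->dx, u->dy, u->dz, fjx, fjy, fjz);
          add_virial(W, v->dx, v->dy, v->dz, fkx, fky, fkz);
        }
      }
    }
  }
  return E;
}

// [[Rcpp::export]]
List tl_evaluate_cpp(NumericMatrix pos, IntegerVector elem, IntegerVector mol,
                     double L, bool periodic, List theory, int level) {
  int n = pos.nrow();
  TLParams p = parse_theory(theory);
  std::vector<double> x(3*n);
  for (int i = 0; i < n; ++i) {
    x[3*i] = pos(i,0); x[3*i+1] = pos(i,1); x[3*i+2] = pos(i,2);
  }
  std::vector<int> el(elem.begin(), elem.end());
  std::vector<int> mo(n);
  int nmol = 0;
  for (int i = 0; i < n; ++i) { mo[i] = mol[i] - 1; nmol = std::max(nmol, mol[i]); }
  double rmax = std::max(p.r_coul, std::max(p.r_lj, std::max(p.d_rc, p.r3)));
  if (periodic && L < 2.0 * rmax)
    stop("box edge %.3f A is smaller than twice the largest cutoff %.3f A", L, rmax);
  std::vector< std::vector<Neigh> > nb;
  build_neighbours(x, n, L, periodic, rmax, nb);
  std::vector<double> F(3*n, 0.0);
  double W[9] = {0,0,0,0,0,0,0,0,0};
  double E = tl_energy_forces(level, p, x, n, el, mo, nmol, L, periodic, nb, F, W);
  NumericMatrix Fm(n, 3), Wm(3, 3);
  for (int i = 0; i < n; ++i) {
    Fm(i,0) = F[3*i]; Fm(i,1) = F[3*i+1]; Fm(i,2) = F[3*i+2];
  }
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) Wm(a,b) = W[3*a+b];
  return List::create(_["energy"] = E, _["forces"] = Fm, _["virial"] = Wm);
}
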