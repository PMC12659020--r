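#pragma once
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <cstdint>

// Internal units: Angstrom, eV, amu.  The derived time unit is
// sqrt(amu A^2 / eV) = 10.1805057 fs; fs are converted at the boundary.
const double KB_EV   = 8.617333262e-5;        // eV / K
const double TIME_FS = 10.180505710774743;    // fs per internal time unit
const double BAR_EVA3 = 6.241509074460763e-7; // (eV/A^3) per bar
const double KE_COUL = 14.399645478425668;    // e^2/(4 pi eps0), eV*A

// ---------------------------------------------------------------------------
// Deterministic RNG: mt19937_64 stream with hand-rolled normal (Box-Muller)
// and gamma (Marsaglia-Tsang) transforms so trajectories are bitwise
// reproducible across platforms for a given seed.
struct RNG {
  std::mt19937_64 eng;
  bool has_g2; double g2;
  explicit RNG(std::uint64_t seed) : eng(seed), has_g2(false), g2(0.0) {}
  double unif() { // open (0,1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_g2) { has_g2 = false; return g2; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    g2 = r * std::sin(a); has_g2 = true;
    return r * std::cos(a);
  }
  double gamma(double a) {
    if (a < 1.0) return gamma(a + 1.0) * std::pow(unif(), 1.0 / a);
    double d = a - 1.0 / 3.0, c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do { x = norm(); v = 1.0 + c * x; } while (v <= 0.0);
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
  double chisq(double k) { return 2.0 * gamma(0.5 * k); }
};

// minimum image for a cubic box, component in [-L/2, L/2)
inline double mic(double d, double L) {
  return d - L * std::floor(d / L + 0.5);
}

// ---------------------------------------------------------------------------
// Two-level theory parameters.  LL = intramolecular + shifted-force LJ +
// damped shifted-force Coulomb.  HL = LL + a Gaussian attractive O-O pair
// well (switched off smoothly at d_rc) + Stillinger-Weber-style O-O-O
// three-body (smooth cutoff r3).  Every HL-LL term vanishes beyond 4 A.
struct TLParams {
  double k_bond, r0, k_angle, theta0;
  double qO, qH, alpha, r_coul;
  double eps, sigma, r_lj;
  double d_eps, d_sigma, d_width, d_ron, d_rc;
  double lambda3, cos0, r3, gamma3;
};

inline TLParams parse_theory(const Rcpp::List& th) {
  TLParams p;
  p.k_bond  = th["k_bond"];  p.r0     = th["r0"];
  p.k_angle = th["k_angle"]; p.theta0 = th["theta0"];
  p.qO = th["qO"]; p.qH = th["qH"];
  p.alpha = th["alpha"]; p.r_coul = th["r_coul"];
  p.eps = th["eps"]; p.sigma = th["sigma"]; p.r_lj = th["r_lj"];
  p.d_eps = th["d_eps"]; p.d_sigma = th["d_sigma"];
  p.d_width = th["d_width"];
  p.d_ron = th["d_ron"]; p.d_rc = th["d_rc"];
  p.lambda3 = th["lambda3"]; p.cos0 = th["cos0"];
  p.r3 = th["r3"]; p.gamma3 = th["gamma3"];
  return p;
}

// potential levels
enum PotLevel { POT_NONE = 0, POT_LL = 1, POT_HL = 2, POT_DELTA = 3 };

// Descriptor spec for the ML delta model (rotation-invariant atom-centred
// radial Gaussians + angular (1 + lam cos)^zeta channels, cosine cutoff).
struct DescSpec {
  double rc, width;
  std::vector<double> cen;          // radial grid centres
  std::vector<double> zeta, lam, eta; // angular combos (parallel vectors)
  int ncen() const { return (int)cen.size(); }
  int ncombo() const { return (int)zeta.size(); }
  int nfeat() const { return 2 * ncen() + 3 * ncombo(); }
};

inline DescSpec parse_spec(const Rcpp::List& s) {
  DescSpec d;
  d.rc = s["cutoff"]; d.width = s["width"];
  d.cen = Rcpp::as<std::vector<double> >(s["centers"]);
  d.zeta = Rcpp::as<std::vector<double> >(s["zeta"]);
  d.lam  = Rcpp::as<std::vector<double> >(s["lambda"]);
  d.eta  = Rcpp::as<std::vector<double> >(s["eta"]);
  return d;
}

// neighbour entry
struct Neigh { int j; double dx, dy, dz, r; };

// full neighbour table (all pairs within cutoff, both directions)
void build_neighbours(const std::vector<double>& x, int n, double L,
                      bool periodic, double rmax,
                      std::vector< std::vector<Neigh> >& nb);

// recompute cached displacement vectors from current positions
void refresh_neighbours(const std::vector<double>& x, double L, bool periodic,
                        std::vector< std::vector<Neigh> >& nb);

// two-level potential: energy/forces/virial accumulated into F (3n) and W (9)
double tl_energy_forces(int level, const TLParams& p,
                        const std::vector<double>& x, int n,
                        const std::vector<int>& elem,
                        const std::vector<int>& mol, int nmol,
                        double L, bool periodic,
                        const std::vector< std::vector<Neigh> >& nb,
                        std::vector<double>& F, double* W);

// ML delta model evaluator.  Weighted radial channels are collapsed into
// tabulated pair functions (cubic Hermite with analytic knot slopes, so the
// interpolated energy and force are exactly consistent); angular combos
// with integer zeta and |lambda| <= 1 are collapsed into per-channel
// polynomials in cos(theta).  init() once, then eval() per configuration.
struct MLEval {
  DescSpec d;
  std::vector<double> vO, vH;
  int ntab; double h;
  std::vector<double> tab[2][2], dtab[2][2]; // [centre 0=O,1=H][neigh 0=O,1=H]
  bool polyok; int deg;
  std::vector<double> S[2][3];  // per centre elem, pairclass: [eta][deg+1]
  void init(const DescSpec& spec, const std::vector<double>& wO,
            const std::vector<double>& wH);
  double eval(int n, const std::vector<int>& elem,
              const std::vector< std::vector<Neigh> >& nb,
              std::vector<double>& F, double* W) const;
};
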