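#include "deltamd.h"
using namespace Rcpp;

// cosine cutoff and derivative
static inline double fcut(double r, double rc) {
  return 0.5 * (1.0 + std::cos(M_PI * r / rc));
}
static inline double dfcut(double r, double rc) {
  return -0.5 * M_PI / rc * std::sin(M_PI * r / rc);
}

static inline int pairclass(int ej, int ek) {
  // O-O = 0, O-H = 1, H-H = 2
  int no = (ej == 8) + (ek == 8);
  return 2 - no;
}

// ---------------------------------------------------------------------------
// Per-atom feature vectors.  Layout (for each centre atom):
//   [radial to O neighbours: ncen] [radial to H: ncen]
//   [angular: channel (OO,OH,HH) x combo]
// [[Rcpp::export]]
NumericMatrix ml_featurize_cpp(NumericMatrix pos, IntegerVector elem,
                               double L, bool periodic, List spec) {
  DescSpec d = parse_spec(spec);
  int n = pos.nrow(), nc = d.ncen(), na = d.ncombo(), nf = d.nfeat();
  std::vector<double> x(3*n);
  for (int i = 0; i < n; ++i) {
    x[3*i] = pos(i,0); x[3*i+1] = pos(i,1); x[3*i+2] = pos(i,2);
  }
  std::vector<int> el(elem.begin(), elem.end());
  std::vector< std::vector<Neigh> > nb;
  build_neighbours(x, n, L, periodic, d.rc, nb);
  NumericMatrix G(n, nf);
  double w2 = d.width * d.width;
  for (int i = 0; i < n; ++i) {
    const std::vector<Neigh>& ni = nb[i];
    for (size_t a = 0; a < ni.size(); ++a) {
      double r = ni[a].r;
      double fc = fcut(r, d.rc);
      int off = (el[ni[a].j] == 8) ? 0 : nc;
      for (int m = 0; m < nc; ++m) {
        double dr = r - d.cen[m];
        G(i, off + m) += std::exp(-dr*dr / (2.0*w2)) * fc;
      }
    }
    // angular
    for (size_t a = 0; a < ni.size(); ++a) {
      for (size_t b = a + 1; b < ni.size(); ++b) {
        const Neigh& u = ni[a]; const Neigh& v = ni[b];
        double ru = u.r, rv = v.r;
        double ct = (u.dx*v.dx + u.dy*v.dy + u.dz*v.dz) / (ru * rv);
        ct = std::max(-1.0, std::min(1.0, ct));
        double ff = fcut(ru, d.rc) * fcut(rv, d.rc);
        int pc = pairclass(el[u.j], el[v.j]);
        for (int c = 0; c < na; ++c) {
          double base = std::pow(2.0, 1.0 - d.zeta[c])
                      * std::pow(1.0 + d.lam[c]*ct, d.zeta[c])
                      * std::exp(-d.eta[c]*(ru*ru + rv*rv)) * ff;
          G(i, 2*nc + pc*na + c) += base;
        }
      }
    }
  }
  return G;
}

// ---------------------------------------------------------------------------
// Fast evaluator: see MLEval in deltamd.h.

static double binom(int nn, int kk) {
  double r = 1.0;
  for (int i = 1; i <= kk; ++i) r = r * (nn - kk + i) / i;
  return r;
}

void MLEval::init(const DescSpec& spec, const std::vector<double>& wO,
                  const std::vector<double>& wH) {
  d = spec; vO = wO; vH = wH;
  int nc = d.ncen(), na = d.ncombo();
  // radial tables u_ef(r) = sum_m v_e[off_f + m] g_m(r) fc(r)
  ntab = 2048; h = d.rc / ntab;
  double w2 = d.width * d.width;
  for (int e = 0; e < 2; ++e) {
    const std::vector<double>& v = (e == 0) ? vO : vH;
    for (int f = 0; f < 2; ++f) {
      int off = (f == 0) ? 0 : nc;
      tab[e][f].assign(ntab + 1, 0.0);
      dtab[e][f].assign(ntab + 1, 0.0);
      for (int k = 0; k <= ntab; ++k) {
        double r = k * h;
        double fc = fcut(r, d.rc), dfc = dfcut(r, d.rc);
        if (k == ntab) { fc = 0.0; dfc = dfcut(r, d.rc); }
        double u = 0.0, du = 0.0;
        for (int m = 0; m < nc; ++m) {
          double dr = r - d.cen[m];
          double g = std::exp(-dr * dr / (2.0 * w2));
          u += v[off + m] * g * fc;
          du += v[off + m] * g * (-dr / w2 * fc + dfc);
        }
        tab[e][f][k] = u; dtab[e][f][k] = du;
      }
    }
  }
  // angular polynomials in cos(theta), when exactly representable
  polyok = true; deg = 0;
  for (int c = 0; c < na; ++c) {
    double z = d.zeta[c];
    if (std::fabs(z - std::floor(z + 0.5)) > 1e-9 || z < 0 || z > 12 ||
        std::fabs(d.lam[c]) > 1.0 + 1e-12) { polyok = false; break; }
    deg = std::max(deg, (int)std::floor(z + 0.5));
  }
  if (polyok) {
    // unique etas indexed as in eval()
    std::vector<double> etas;
    std::vector<int> eidx(na);
    for (int c = 0; c < na; ++c) {
      int k = -1;
      for (size_t q = 0; q < etas.size(); ++q)
        if (etas[q] == d.eta[c]) { k = (int)q; break; }
      if (k < 0) { etas.push_back(d.eta[c]); k = (int)etas.size() - 1; }
      eidx[c] = k;
    }
    int ne = (int)etas.size();
    for (int e = 0; e < 2; ++e) {
      const std::vector<double>& v = (e == 0) ? vO : vH;
      for (int pc = 0; pc < 3; ++pc) {
        S[e][pc].assign((size_t)ne * (deg + 1), 0.0);
        for (int c = 0; c < na; ++c) {
          double w = v[2 * nc + pc * na + c];
          if (w == 0.0) continue;
          int z = (int)std::floor(d.zeta[c] + 0.5);
          double pref = std::pow(2.0, 1.0 - d.zeta[c]);
          for (int k = 0; k <= z; ++k)
            S[e][pc][(size_t)eidx[c] * (deg + 1) + k] +=
              w * pref * binom(z, k) * std::pow(d.lam[c], k);
        }
      }
    }
  }
}

double MLEval::eval(int n, const std::vector<int>& elem,
                    const std::vector< std::vector<Neigh> >& nb,
                    std::vector<double>& F, double* W) const {
  int nc = d.ncen(), na = d.ncombo();
  double E = 0.0;
  // unique etas (same indexing as init)
  std::vector<double> etas; std::vector<int> eidx(na);
  for (int c = 0; c < na; ++c) {
    int k = -1;
    for (size_t q = 0; q < etas.size(); ++q)
      if (etas[q] == d.eta[c]) { k = (int)q; break; }
    if (k < 0) { etas.push_back(d.eta[c]); k = (int)etas.size() - 1; }
    eidx[c] = k;
  }
  int ne = (int)etas.size();
  std::vector<double> pref(na);
  for (int c = 0; c < na; ++c) pref[c] = std::pow(2.0, 1.0 - d.zeta[c]);

  std::vector<int> jid(n); std::vector<double> jr(n), jux(n), juy(n),
    juz(n), jdx(n), jdy(n), jdz(n), jinv(n), jA((size_t)n * ne),
    jdA((size_t)n * ne);
  for (int i = 0; i < n; ++i) {
    int ei = (elem[i] == 8) ? 0 : 1;
    const std::vector<double>& v = (ei == 0) ? vO : vH;
    const std::vector<Neigh>& ni = nb[i];
    int m = 0;
    for (size_t a = 0; a < ni.size(); ++a) {
      if (ni[a].r >= d.rc) continue;
      jid[m] = ni[a].j; jr[m] = ni[a].r;
      double inv = 1.0 / ni[a].r;
      jinv[m] = inv;
      jdx[m] = ni[a].dx; jdy[m] = ni[a].dy; jdz[m] = ni[a].dz;
      jux[m] = ni[a].dx * inv; juy[m] = ni[a].dy * inv;
      juz[m] = ni[a].dz * inv;
      ++m;
    }
    if (m == 0) continue;
    for (int a = 0; a < m; ++a) {
      double r = jr[a];
      double fc = fcut(r, d.rc), dfc = dfcut(r, d.rc);
      for (int q = 0; q < ne; ++q) {
        double ex = std::exp(-etas[q] * r * r);
        jA[a * ne + q] = ex * fc;
        jdA[a * ne + q] = ex * (-2.0 * etas[q] * r * fc + dfc);
      }
      // radial: tabulated pair function (cubic Hermite, consistent force)
      int f = (elem[jid[a]] == 8) ? 0 : 1;
      int k = (int)(r / h); if (k >= ntab) k = ntab - 1;
      double t = (r - k * h) / h;
      double u0 = tab[ei][f][k], u1 = tab[ei][f][k + 1];
      double m0 = dtab[ei][f][k], m1 = dtab[ei][f][k + 1];
      double t2 = t * t, t3 = t2 * t;
      double u = (2 * t3 - 3 * t2 + 1) * u0 + (t3 - 2 * t2 + t) * h * m0
               + (-2 * t3 + 3 * t2) * u1 + (t3 - t2) * h * m1;
      double dEdr = ((6 * t2 - 6 * t) * (u0 - u1)) / h
                  + (3 * t2 - 4 * t + 1) * m0 + (3 * t2 - 2 * t) * m1;
      E += u;
      if (dEdr != 0.0) {
        double fx = -dEdr * jux[a], fy = -dEdr * juy[a], fz = -dEdr * juz[a];
        int j = jid[a];
        F[3 * j] += fx; F[3 * j + 1] += fy; F[3 * j + 2] += fz;
        F[3 * i] -= fx; F[3 * i + 1] -= fy; F[3 * i + 2] -= fz;
        W[0] += jdx[a] * fx; W[1] += jdx[a] * fy; W[2] += jdx[a] * fz;
        W[3] += jdy[a] * fx; W[4] += jdy[a] * fy; W[5] += jdy[a] * fz;
        W[6] += jdz[a] * fx; W[7] += jdz[a] * fy; W[8] += jdz[a] * fz;
      }
    }
    // angular
    for (int a = 0; a < m; ++a) {
      double uxa = jux[a], uya = juy[a], uza = juz[a], inva = jinv[a];
      const double* Aa = &jA[(size_t)a * ne];
      const double* dAa = &jdA[(size_t)a * ne];
      int ea = elem[jid[a]];
      for (int b = a + 1; b < m; ++b) {
        double ct = uxa * jux[b] + uya * juy[b] + uza * juz[b];
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
        int pc = pairclass(ea, elem[jid[b]]);
        const double* Ab = &jA[(size_t)b * ne];
        const double* dAb = &jdA[(size_t)b * ne];
        double dEdct = 0.0, dEdru = 0.0, dEdrv = 0.0;
        if (polyok) {
          const std::vector<double>& P = S[ei][pc];
          for (int q = 0; q < ne; ++q) {
            const double* cf = &P[(size_t)q * (deg + 1)];
            double val = 0.0, der = 0.0;
            for (int k = deg; k >= 1; --k) {
              val = val * ct + cf[k];
              der = der * ct + k * cf[k];
            }
            val = val * ct + cf[0];
            double AaAb = Aa[q] * Ab[q];
            E += val * AaAb;
            dEdct += der * AaAb;
            dEdru += val * dAa[q] * Ab[q];
            dEdrv += val * Aa[q] * dAb[q];
          }
        } else {
          const std::vector<double>& v2 = v;
          for (int c = 0; c < na; ++c) {
            double w = v2[2 * nc + pc * na + c];
            if (w == 0.0) continue;
            double ang1 = 1.0 + d.lam[c] * ct;
            if (ang1 < 0.0) ang1 = 0.0;
            double angz = std::pow(ang1, d.zeta[c]);
            double dangz = d.zeta[c] * d.lam[c] *
              ((d.zeta[c] == 1.0) ? 1.0 : std::pow(ang1, d.zeta[c] - 1.0));
            int q = eidx[c];
            double wp = w * pref[c];
            double AaAb = Aa[q] * Ab[q];
            E += wp * angz * AaAb;
            dEdct += wp * dangz * AaAb;
            dEdru += wp * angz * dAa[q] * Ab[q];
            dEdrv += wp * angz * Aa[q] * dAb[q];
          }
        }
        if (dEdct == 0.0 && dEdru == 0.0 && dEdrv == 0.0) continue;
        double invb = jinv[b];
        double gjx = (jux[b] - ct * uxa) * inva;
        double gjy = (juy[b] - ct * uya) * inva;
        double gjz = (juz[b] - ct * uza) * inva;
        double gkx = (uxa - ct * jux[b]) * invb;
        double gky = (uya - ct * juy[b]) * invb;
        double gkz = (uza - ct * juz[b]) * invb;
        double fjx = -(dEdct * gjx + dEdru * uxa);
        double fjy = -(dEdct * gjy + dEdru * uya);
        double fjz = -(dEdct * gjz + dEdru * uza);
        double fkx = -(dEdct * gkx + dEdrv * jux[b]);
        double fky = -(dEdct * gky + dEdrv * juy[b]);
        double fkz = -(dEdct * gkz + dEdrv * juz[b]);
        int jj = jid[a], kk = jid[b];
        F[3 * jj] += fjx; F[3 * jj + 1] += fjy; F[3 * jj + 2] += fjz;
        F[3 * kk] += fkx; F[3 * kk + 1] += fky; F[3 * kk + 2] += fkz;
        F[3 * i] -= fjx + fkx; F[3 * i + 1] -= fjy + fky;
        F[3 * i + 2] -= fjz + fkz;
        W[0] += jdx[a] * fjx + jdx[b] * fkx; W[1] += jdx[a] * fjy + jdx[b] * fky;
        W[2] += jdx[a] * fjz + jdx[b] * fkz;
        W[3] += jdy[a] * fjx + jdy[b] * fkx; W[4] += jdy[a] * fjy + jdy[b] * fky;
        W[5] += jdy[a] * fjz + jdy[b] * fkz;
        W[6] += jdz[a] * fjx + jdz[b] * fkx; W[7] += jdz[a] * fjy + jdz[b] * fky;
        W[8] += jdz[a] * fjz + jdz[b] * fkz;
      }
    }
  }
  return E;
}

// [[Rcpp::export]]
List ml_evaluate_cpp(NumericMatrix pos, IntegerVector elem,
                     double L, bool periodic, List spec,
                     NumericVector vO, NumericVector vH, double econst) {
  DescSpec d = parse_spec(spec);
  int n = pos.nrow();
  std::vector<double> x(3*n);
  for (int i = 0; i < n; ++i) {
    x[3*i] = pos(i,0); x[3*i+1] = pos(i,1); x[3*i+2] = pos(i,2);
  }
  std::vector<int> el(elem.begin(), elem.end());
  std::vector< std::vector<Neigh> > nb;
  build_neighbours(x, n, L, periodic, d.rc, nb);
  std::vector<double> F(3*n, 0.0);
  double W[9] = {0,0,0,0,0,0,0,0,0};
  MLEval ev;
  ev.init(d, std::vector<double>(vO.begin(), vO.end()),
          std::vector<double>(vH.begin(), vH.end()));
  double E = ev.eval(n, el, nb, F, W) + econst;
  NumericMatrix Fm(n, 3), Wm(3, 3);
  for (int i = 0; i < n; ++i) {
    Fm(i,0) = F[3*i]; Fm(i,1) = F[3*i+1]; Fm(i,2) = F[3*i+2];
  }
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) Wm(a,b) = W[3*a+b];
  return List::create(_["energy"] = E, _["forces"] = Fm, _["virial"] = Wm);
}
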