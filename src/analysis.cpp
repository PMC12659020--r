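#include "deltamd.h"
using namespace Rcpp;

// Shell-count RDF accumulator with per-frame ideal-gas normalisation
// (NPT-safe: each frame is normalised with its own cell volume).
// pos_a / pos_b: lists of per-frame coordinate matrices of the two species
// (identical objects for a same-species RDF); Ls: per-frame cubic edges.
// [[Rcpp::export]]
NumericVector rdf_accum_cpp(List pos_a, List pos_b, NumericVector Ls,
                            bool same, double dr, int nbins) {
  int nf = pos_a.size();
  NumericVector g(nbins);
  std::vector<double> counts(nbins);
  for (int f = 0; f < nf; ++f) {
    NumericMatrix A = pos_a[f], B = pos_b[f];
    double L = Ls[f], V = L*L*L;
    int na = A.nrow(), nb = B.nrow();
    std::fill(counts.begin(), counts.end(), 0.0);
    for (int i = 0; i < na; ++i) {
      int j0 = same ? i + 1 : 0;
      for (int j = j0; j < nb; ++j) {
        double dx = mic(B(j,0) - A(i,0), L);
        double dy = mic(B(j,1) - A(i,1), L);
        double dz = mic(B(j,2) - A(i,2), L);
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        int b = (int)(r / dr);
        if (b >= 0 && b < nbins) counts[b] += same ? 2.0 : 1.0;
      }
    }
    // per-particle neighbour convention: a same-species ideal gas carries
    // na * (na/V) expected ordered pairs per shell, so the coordination
    // integral rho int 4 pi r^2 g dr counts neighbours per particle
    double npairs = same ? (double)na * na : (double)na * nb;
    for (int b = 0; b < nbins; ++b) {
      double r0 = b * dr, r1 = r0 + dr;
      double shell = 4.0 * M_PI / 3.0 * (r1*r1*r1 - r0*r0*r0);
      double ideal = npairs * shell / V;
      if (ideal > 0.0) g[b] += counts[b] / ideal;
    }
  }
  for (int b = 0; b < nbins; ++b) g[b] /= nf;
  return g;
}

// Mean squared displacement over multiple time origins.
// pos: list of nframes unwrapped coordinate matrices (one species),
// lags: integer frame lags; origin_stride: spacing between origins.
// [[Rcpp::export]]
NumericVector msd_cpp(List pos, IntegerVector lags, int origin_stride) {
  int nf = pos.size(), nl = lags.size();
  NumericVector msd(nl);
  for (int k = 0; k < nl; ++k) {
    int lag = lags[k];
    double acc = 0.0; long cnt = 0;
    for (int t0 = 0; t0 + lag < nf; t0 += origin_stride) {
      NumericMatrix A = pos[t0], B = pos[t0 + lag];
      int n = A.nrow();
      for (int i = 0; i < n; ++i) {
        double dx = B(i,0) - A(i,0), dy = B(i,1) - A(i,1), dz = B(i,2) - A(i,2);
        acc += dx*dx + dy*dy + dz*dz;
      }
      cnt += n;
    }
    msd[k] = (cnt > 0) ? acc / cnt : NA_REAL;
  }
  return msd;
}
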