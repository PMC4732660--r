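#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// State order throughout: A=0, C=1, G=2, T=3. Purines {A,G}, pyrimidines {C,T}.

static inline bool is_purine(int i) { return i == 0 || i == 2; }

// Mean instantaneous rate of the unnormalised HKY generator (q_ij = kappa*pi_j for
// transitions, pi_j for transversions). Branch lengths are in expected
// substitutions/site, so the generator is divided by this.
static double hky_mean_rate(double kappa, const double* pi) {
  double tv = pi[0] * pi[1] + pi[0] * pi[3] + pi[1] * pi[2] + pi[2] * pi[3];
  double ts = pi[0] * pi[2] + pi[1] * pi[3];
  return 2.0 * tv + 2.0 * kappa * ts;
}

// Closed-form HKY transition probabilities P(t), row-major 4x4 into P.
static void hky_pmat_fill(double t, double kappa, const double* pi, double* P) {
  double piR = pi[0] + pi[2];
  double piY = pi[1] + pi[3];
  double beta = 1.0 / hky_mean_rate(kappa, pi);
  double d = beta * t;
  double e1 = std::exp(-d);
  for (int j = 0; j < 4; ++j) {
    double grp = is_purine(j) ? piR : piY;
    double e2 = std::exp(-d * (1.0 + grp * (kappa - 1.0)));
    for (int i = 0; i < 4; ++i) {
      double p;
      if (i == j) {
        p = pi[j] + pi[j] * (1.0 - grp) / grp * e1 + (grp - pi[j]) / grp * e2;
      } else if (is_purine(i) == is_purine(j)) {
        p = pi[j] + pi[j] * (1.0 - grp) / grp * e1 - pi[j] / grp * e2;
      } else {
        p = pi[j] * (1.0 - e1);
      }
      P[4 * i + j] = p;
    }
  }
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix hky_pmat_cpp(double t, double kappa, NumericVector freqs) {
  NumericMatrix P(4, 4);
  double pi[4] = { freqs[0], freqs[1], freqs[2], freqs[3] };
  double buf[16];
  hky_pmat_fill(t, kappa, pi, buf);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) P(i, j) = buf[4 * i + j];
  return P;
}

// Felsenstein pruning over compressed site patterns.
//
// edge:      (parent, child) rows, 1-based ape node numbering (tips 1..ntip),
//            in postorder (every child row precedes the row using it as parent).
// blen:      expected substitutions/site per edge.
// tip_pat:   ntip x npat integer matrix of states 1..4 (row i = tip i).
// weights:   pattern multiplicities.
//
// [[Rcpp::export]]
double pruning_loglik_cpp(IntegerMatrix edge, NumericVector blen, int ntip,
                          IntegerMatrix tip_pat, NumericVector weights,
                          double kappa, NumericVector freqs) {
  const int nedge = edge.nrow();
  const int npat = tip_pat.ncol();
  const int nnode_total = ntip + ntip;  // >= ntip + (ntip - 1) internal + root slack
  double pi[4] = { freqs[0], freqs[1], freqs[2], freqs[3] };

  // partials[node][4 * s + x]; initialised lazily.
  std::vector< std::vector<double> > partial(nnode_total + 1);
  std::vector<char> seen(nnode_total + 1, 0);
  std::vector<double> logscale(npat, 0.0);

  double P[16];
  std::vector<double> contrib(4 * npat);

  int root = -1;
  for (int e = 0; e < nedge; ++e) {
    int par = edge(e, 0);
    int child = edge(e, 1);
    root = par;  // final postorder parent is the root
    hky_pmat_fill(blen[e], kappa, pi, P);

    if (child <= ntip) {
      for (int s = 0; s < npat; ++s) {
        int y = tip_pat(child - 1, s) - 1;
        for (int x = 0; x < 4; ++x) contrib[4 * s + x] = P[4 * x + y];
      }
    } else {
      std::vector<double>& Lc = partial[child];
      // rescale the internal child's partial once, as it is consumed
      for (int s = 0; s < npat; ++s) {
        double m = Lc[4 * s];
        for (int x = 1; x < 4; ++x) if (Lc[4 * s + x] > m) m = Lc[4 * s + x];
        if (m > 0 && m != 1.0) {
          for (int x = 0; x < 4; ++x) Lc[4 * s + x] /= m;
          logscale[s] += std::log(m);
        }
      }
      for (int s = 0; s < npat; ++s) {
        for (int x = 0; x < 4; ++x) {
          double acc = 0.0;
          for (int y = 0; y < 4; ++y) acc += P[4 * x + y] * Lc[4 * s + y];
          contrib[4 * s + x] = acc;
        }
      }
    }

    if (!seen[par]) {
      partial[par] = contrib;
      seen[par] = 1;
    } else {
      std::vector<double>& Lp = partial[par];
      for (int k = 0; k < 4 * npat; ++k) Lp[k] *= contrib[k];
    }
  }

  const std::vector<double>& Lr = partial[root];
  double ll = 0.0;
  for (int s = 0; s < npat; ++s) {
    double acc = 0.0;
    for (int x = 0; x < 4; ++x) acc += pi[x] * Lr[4 * s + x];
    ll += weights[s] * (std::log(acc) + logscale[s]);
  }
  return ll;
}
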