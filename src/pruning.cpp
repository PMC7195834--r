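#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// HKY85 transition probabilities, closed form.
// States are coded A=0, C=1, G=2, T=3. `t` is in expected substitutions
// per site (the rate matrix is normalised to unit mean rate).
static inline void hky_pmat(double t, double kappa, const double *pi,
                            double *P /* 4x4 row-major: P[i*4+j] */) {
  const double piA = pi[0], piC = pi[1], piG = pi[2], piT = pi[3];
  const double piR = piA + piG, piY = piC + piT;
  const double mu = 2.0 * (piA * piC + piA * piT + piC * piG + piG * piT) +
                    2.0 * kappa * (piA * piG + piC * piT);
  const double beta = 1.0 / mu;
  const double e2 = std::exp(-beta * t);
  const double eR = std::exp(-beta * t * (1.0 + piR * (kappa - 1.0)));
  const double eY = std::exp(-beta * t * (1.0 + piY * (kappa - 1.0)));
  for (int i = 0; i < 4; ++i) {
    const bool i_pur = (i == 0 || i == 2);
    for (int j = 0; j < 4; ++j) {
      const bool j_pur = (j == 0 || j == 2);
      const double pj = pi[j];
      const double PI = j_pur ? piR : piY;
      const double ej = j_pur ? eR : eY;
      double p;
      if (i == j) {
        p = pj + pj * (1.0 / PI - 1.0) * e2 + ((PI - pj) / PI) * ej;
      } else if (i_pur == j_pur) {
        p = pj + pj * (1.0 / PI - 1.0) * e2 - (pj / PI) * ej;
      } else {
        p = pj * (1.0 - e2);
      }
      P[i * 4 + j] = p;
    }
  }
}

// [[Rcpp::export(name = ".hky_pmat_cpp")]]
NumericMatrix hky_pmat_cpp(double t, double kappa, NumericVector basefreq) {
  double P[16];
  hky_pmat(t, kappa, basefreq.begin(), P);
  NumericMatrix out(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = P[i * 4 + j];
  return out;
}

// Felsenstein pruning log-likelihood under HKY (+ discrete-gamma via
// `rates`, equal category weights).
//
// edge: 2-column integer matrix (parent, child), 1-based ape node ids,
//       in ape postorder (every child's subtree edges precede its parent
//       edge). Root id = ntip + 1.
// patterns: ntip x npat integer matrix, states 0..3, negative = missing.
// weights: pattern multiplicities.
// edge_len: expected substitutions per site for each edge row.
// [[Rcpp::export(name = ".loglik_hky_cpp")]]
double loglik_hky_cpp(IntegerMatrix edge, NumericVector edge_len,
                      IntegerMatrix patterns, NumericVector weights,
                      double kappa, NumericVector basefreq,
                      NumericVector rates) {
  const int nedge = edge.nrow();
  const int ntip = patterns.nrow();
  const int npat = patterns.ncol();
  const int nnode_total = ntip + nedge / 2 + 1; // binary rooted tree
  const int ncat = rates.size();
  const double *pi = basefreq.begin();

  std::vector<double> sitelik(npat, 0.0);
  // partials[node][pattern][state]
  std::vector<double> partial((size_t)nnode_total * npat * 4);
  std::vector<double> logscale(npat);
  double P[16];

  for (int c = 0; c < ncat; ++c) {
    std::fill(partial.begin(), partial.end(), 1.0);
    std::fill(logscale.begin(), logscale.end(), 0.0);
    for (int tip = 0; tip < ntip; ++tip) {
      for (int s = 0; s < npat; ++s) {
        const int st = patterns(tip, s);
        if (st >= 0) {
          double *pp = &partial[((size_t)tip * npat + s) * 4];
          pp[0] = pp[1] = pp[2] = pp[3] = 0.0;
          pp[st] = 1.0;
        }
      }
    }
    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0) - 1;
      const int chi = edge(e, 1) - 1;
      hky_pmat(edge_len[e] * rates[c], kappa, pi, P);
      for (int s = 0; s < npat; ++s) {
        const double *cp = &partial[((size_t)chi * npat + s) * 4];
        double *pp = &partial[((size_t)par * npat + s) * 4];
        double v[4], mx = 0.0;
        for (int i = 0; i < 4; ++i) {
          double acc = 0.0;
          for (int j = 0; j < 4; ++j) acc += P[i * 4 + j] * cp[j];
          v[i] = acc;
          if (acc > mx) mx = acc;
        }
        if (mx <= 0.0) return R_NegInf;
        for (int i = 0; i < 4; ++i) pp[i] *= v[i] / mx;
        logscale[s] += std::log(mx);
      }
    }
    const size_t root = (size_t)ntip; // 0-based index of node ntip+1
    for (int s = 0; s < npat; ++s) {
      const double *rp = &partial[(root * npat + s) * 4];
      double lik = 0.0;
      for (int i = 0; i < 4; ++i) lik += pi[i] * rp[i];
      sitelik[s] += std::exp(std::log(lik) + logscale[s]) / ncat;
    }
  }
  double ll = 0.0;
  for (int s = 0; s < npat; ++s) {
    if (!(sitelik[s] > 0.0)) return R_NegInf;
    ll += weights[s] * std::log(sitelik[s]);
  }
  return ll;
}
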