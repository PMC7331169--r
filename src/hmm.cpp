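#include <Rcpp.h>
using namespace Rcpp;

// Single-pulse two-ancestry HMM over ancestry-informative markers.
// Haploid chain: between markers d bp apart ancestry persists with
// probability s = exp(-r * d * t); otherwise it is redrawn Bernoulli(m)
// toward donor.  The diploid dosage chain {0,1,2} is the lumped product
// of two independent, exchangeable haploid chains.

static inline void dosage_transition(double s, double m, double T[3][3]) {
  // haploid transition entries
  double p01 = (1.0 - s) * m;            // native -> donor
  double p00 = 1.0 - p01;
  double p11 = s + (1.0 - s) * m;        // donor -> donor
  double p10 = 1.0 - p11;
  T[0][0] = p00 * p00; T[0][1] = 2.0 * p00 * p01; T[0][2] = p01 * p01;
  T[1][0] = p10 * p00;
  T[1][1] = p10 * p01 + p11 * p00;
  T[1][2] = p11 * p01;
  T[2][0] = p10 * p10; T[2][1] = 2.0 * p11 * p10; T[2][2] = p11 * p11;
}

// Scaled forward pass; returns per-block log-likelihood contributions.
// emis: n x 3 emission likelihoods; d: distance to previous marker in bp,
// negative at the first marker of each chromosome (chain restart);
// block: 0-based block index per marker (contiguous).
// [[Rcpp::export(name = ".hmm_block_loglik")]]
NumericVector hmm_block_loglik(NumericMatrix emis, NumericVector d,
                               IntegerVector block, int n_blocks,
                               double m, double t, double r) {
  int n = emis.nrow();
  NumericVector ll(n_blocks);
  double pi0[3] = {(1 - m) * (1 - m), 2 * m * (1 - m), m * m};
  double alpha[3] = {0, 0, 0};
  double T[3][3];
  for (int i = 0; i < n; ++i) {
    double tmp[3];
    if (d[i] < 0) {
      for (int k = 0; k < 3; ++k) tmp[k] = pi0[k] * emis(i, k);
    } else {
      dosage_transition(std::exp(-r * d[i] * t), m, T);
      for (int k = 0; k < 3; ++k) {
        double acc = 0;
        for (int j = 0; j < 3; ++j) acc += alpha[j] * T[j][k];
        tmp[k] = acc * emis(i, k);
      }
    }
    double sc = tmp[0] + tmp[1] + tmp[2];
    if (!(sc > 0))
      stop("non-finite HMM likelihood at marker %d (zero emission?)", i + 1);
    for (int k = 0; k < 3; ++k) alpha[k] = tmp[k] / sc;
    ll[block[i]] += std::log(sc);
  }
  return ll;
}

// Forward-backward posterior decoding (scaled), chain restarts as above.
// [[Rcpp::export(name = ".hmm_posteriors")]]
NumericMatrix hmm_posteriors(NumericMatrix emis, NumericVector d,
                             double m, double t, double r) {
  int n = emis.nrow();
  NumericMatrix fwd(n, 3), post(n, 3);
  NumericVector scale(n);
  double pi0[3] = {(1 - m) * (1 - m), 2 * m * (1 - m), m * m};
  double T[3][3];
  for (int i = 0; i < n; ++i) {
    double tmp[3];
    if (d[i] < 0) {
      for (int k = 0; k < 3; ++k) tmp[k] = pi0[k] * emis(i, k);
    } else {
      dosage_transition(std::exp(-r * d[i] * t), m, T);
      for (int k = 0; k < 3; ++k) {
        double acc = 0;
        for (int j = 0; j < 3; ++j) acc += fwd(i - 1, j) * T[j][k];
        tmp[k] = acc * emis(i, k);
      }
    }
    double sc = tmp[0] + tmp[1] + tmp[2];
    if (!(sc > 0))
      stop("non-finite HMM likelihood at marker %d (zero emission?)", i + 1);
    scale[i] = sc;
    for (int k = 0; k < 3; ++k) fwd(i, k) = tmp[k] / sc;
  }
  double beta[3] = {1, 1, 1};
  for (int i = n - 1; i >= 0; --i) {
    double tot = 0;
    for (int k = 0; k < 3; ++k) {
      post(i, k) = fwd(i, k) * beta[k];
      tot += post(i, k);
    }
    for (int k = 0; k < 3; ++k) post(i, k) /= tot;
    if (i == 0) break;
    if (d[i] < 0) {                       // chain restart: reset beta
      beta[0] = beta[1] = beta[2] = 1;
    } else {
      dosage_transition(std::exp(-r * d[i] * t), m, T);
      double nb[3];
      for (int j = 0; j < 3; ++j) {
        double acc = 0;
        for (int k = 0; k < 3; ++k) acc += T[j][k] * emis(i, k) * beta[k];
        nb[j] = acc / scale[i];
      }
      for (int j = 0; j < 3; ++j) beta[j] = nb[j];
    }
  }
  return post;
}
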