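#include "pvl.h"
using namespace Rcpp;

// [[Rcpp::export]]
double pvl_loglik_cpp(IntegerVector deck, NumericVector net,
                      double A, double w, double a, double c, double scale) {
  return pvl_loglik_c(INTEGER(deck), REAL(net), deck.size(), A, w, a, c, scale);
}

// One-step-ahead choice probabilities conditioned on the observed history:
// row t holds the softmax probabilities for trial t given trials 1..t-1.
// [[Rcpp::export]]
NumericMatrix one_step_probs_cpp(IntegerVector deck, NumericVector net,
                                 double A, double w, double a, double c,
                                 double scale) {
  const int T = deck.size();
  NumericMatrix P(T, 4);
  double Ev[4] = {0.0, 0.0, 0.0, 0.0};
  const double theta = std::pow(3.0, c) - 1.0;
  for (int t = 0; t < T; ++t) {
    double m = Ev[0];
    for (int k = 1; k < 4; ++k) if (Ev[k] > m) m = Ev[k];
    double denom = 0.0, e[4];
    for (int k = 0; k < 4; ++k) { e[k] = std::exp(theta * (Ev[k] - m)); denom += e[k]; }
    for (int k = 0; k < 4; ++k) P(t, k) = e[k] / denom;
    const int k = deck[t] - 1;
    const double u = pvl_utility_c(net[t] / scale, A, w);
    Ev[k] += a * (u - Ev[k]);
  }
  return P;
}
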