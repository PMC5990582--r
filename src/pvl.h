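#ifndef IGTBAYES_PVL_H
#define IGTBAYES_PVL_H

#include <Rcpp.h>
#include <cmath>
#include <vector>

// Core PVL-Delta recursions shared by the likelihood, the one-step-ahead
// predictor and the samplers. Net outcomes are divided by `scale` before
// entering the prospect utility (keeps theta * Ev in a safe range at c = 5).

inline double pvl_utility_c(double x, double A, double w) {
  if (x == 0.0) return 0.0;  // both branches vanish at 0 (incl. the 0^0 case)
  return (x > 0.0) ? std::pow(x, A) : -w * std::pow(-x, A);
}

// Log-likelihood of an observed choice sequence under PVL-Delta.
// deck is 1-based; net is the raw net outcome W + L (L stored <= 0).
// Computed via log-sum-exp so it stays finite for all in-range parameters.
inline double pvl_loglik_c(const int* deck, const double* net, int T,
                           double A, double w, double a, double c,
                           double scale) {
  double Ev[4] = {0.0, 0.0, 0.0, 0.0};
  const double theta = std::pow(3.0, c) - 1.0;
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    double m = Ev[0];
    for (int k = 1; k < 4; ++k) if (Ev[k] > m) m = Ev[k];
    double denom = 0.0;
    for (int k = 0; k < 4; ++k) denom += std::exp(theta * (Ev[k] - m));
    const int k = deck[t] - 1;
    ll += theta * (Ev[k] - m) - std::log(denom);
    const double u = pvl_utility_c(net[t] / scale, A, w);
    Ev[k] += a * (u - Ev[k]);
  }
  return ll;
}

struct NatParams { double A, w, a, c; };

// Probit scale -> natural scale: A, a on [0,1]; w, c on [0,5].
inline NatParams probit_to_nat(const double* z) {
  NatParams p;
  p.A = R::pnorm(z[0], 0.0, 1.0, 1, 0);
  p.w = 5.0 * R::pnorm(z[1], 0.0, 1.0, 1, 0);
  p.a = R::pnorm(z[2], 0.0, 1.0, 1, 0);
  p.c = 5.0 * R::pnorm(z[3], 0.0, 1.0, 1, 0);
  return p;
}

inline double subject_loglik_probit(const std::vector<int>& deck,
                                    const std::vector<double>& net,
                                    const double* z, double scale) {
  NatParams p = probit_to_nat(z);
  return pvl_loglik_c(deck.data(), net.data(), (int)deck.size(),
                      p.A, p.w, p.a, p.c, scale);
}

#endif
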