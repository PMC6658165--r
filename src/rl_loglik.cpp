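#include <Rcpp.h>
using namespace Rcpp;

// Sequential negative log-likelihood of Rescorla-Wagner-type learners over
// the two choice objects. choiceB: 0 = A chosen, 1 = B chosen. variant:
// 0 standard (update chosen only), 1 stack (unchosen accumulates toward the
// reward ceiling at rate kappa), 2 reversal (unchosen updated toward the
// opposite outcome). evalMask marks trials entering the likelihood; value
// updates always run over the full sequence.
// [[Rcpp::export]]
double rlNegLogLik(NumericVector par, IntegerVector choiceB,
                   IntegerVector reward, int variant, LogicalVector evalMask) {
  double alpha = par[0], tau = par[1];
  double kappa = (par.size() > 2) ? par[2] : 0.0;
  double qA = 0.5, qB = 0.5, nll = 0.0;
  int n = choiceB.size();
  for (int i = 0; i < n; ++i) {
    double pA = 1.0 / (1.0 + std::exp(-tau * (qA - qB)));
    if (pA < 1e-12) pA = 1e-12;
    if (pA > 1.0 - 1e-12) pA = 1.0 - 1e-12;
    if (evalMask[i])
      nll -= (choiceB[i] == 0) ? std::log(pA) : std::log(1.0 - pA);
    double r = reward[i];
    if (choiceB[i] == 0) {
      qA += alpha * (r - qA);
      if (variant == 1) qB += kappa * (1.0 - qB);
      else if (variant == 2) qB += alpha * ((1.0 - r) - qB);
    } else {
      qB += alpha * (r - qB);
      if (variant == 1) qA += kappa * (1.0 - qA);
      else if (variant == 2) qA += alpha * ((1.0 - r) - qA);
    }
  }
  return nll;
}
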