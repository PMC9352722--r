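#include <Rcpp.h>
using namespace Rcpp;

// Log-space Viterbi decoding. logEmis is n x k (observation log-likelihood per
// state), logTrans k x k (rows = from), logInit length k. Ties are broken toward
// the lower state index, so callers order states with the conservative /
// null state first. Returns 1-based state path; the attained joint
// log-probability is attached as attribute "logp" for oracle comparisons.
// [[Rcpp::export]]
IntegerVector viterbi_decode_cpp(NumericMatrix logEmis, NumericMatrix logTrans,
                                 NumericVector logInit) {
  const int n = logEmis.nrow();
  const int k = logEmis.ncol();
  if (n == 0) stop("empty observation sequence");
  NumericMatrix delta(n, k);
  IntegerMatrix psi(n, k);
  for (int j = 0; j < k; ++j) delta(0, j) = logInit[j] + logEmis(0, j);
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < k; ++j) {
      double best = delta(t - 1, 0) + logTrans(0, j);
      int arg = 0;
      for (int i = 1; i < k; ++i) {
        double v = delta(t - 1, i) + logTrans(i, j);
        if (v > best) { best = v; arg = i; }   // strict >: ties keep lower index
      }
      delta(t, j) = best + logEmis(t, j);
      psi(t, j) = arg;
    }
  }
  int arg = 0;
  double best = delta(n - 1, 0);
  for (int j = 1; j < k; ++j)
    if (delta(n - 1, j) > best) { best = delta(n - 1, j); arg = j; }
  IntegerVector path(n);
  path[n - 1] = arg;
  for (int t = n - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < n; ++t) path[t] += 1;
  path.attr("logp") = best;
  return path;
}

// Scaled forward-backward pass for one observation sequence. emis is n x k of
// plain (non-log) emission likelihoods; trans k x k; init length k. Returns the
// sufficient statistics Baum-Welch needs: gamma (n x k posterior), xi_sum
// (k x k summed transition posteriors) and the sequence log-likelihood.
// [[Rcpp::export]]
List forward_backward_cpp(NumericMatrix emis, NumericMatrix trans,
                          NumericVector init) {
  const int n = emis.nrow();
  const int k = emis.ncol();
  if (n == 0) stop("empty observation sequence");
  NumericMatrix alpha(n, k), beta(n, k), gamma(n, k);
  NumericVector scale(n);
  double ll = 0.0;

  for (int j = 0; j < k; ++j) alpha(0, j) = init[j] * emis(0, j);
  double s = 0.0;
  for (int j = 0; j < k; ++j) s += alpha(0, j);
  if (s <= 0) stop("zero forward probability at position 1");
  scale[0] = s;
  for (int j = 0; j < k; ++j) alpha(0, j) /= s;
  for (int t = 1; t < n; ++t) {
    s = 0.0;
    for (int j = 0; j < k; ++j) {
      double a = 0.0;
      for (int i = 0; i < k; ++i) a += alpha(t - 1, i) * trans(i, j);
      a *= emis(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0) stop("zero forward probability (numerical underflow)");
    scale[t] = s;
    for (int j = 0; j < k; ++j) alpha(t, j) /= s;
  }
  for (int t = 0; t < n; ++t) ll += std::log(scale[t]);

  for (int j = 0; j < k; ++j) beta(n - 1, j) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    for (int i = 0; i < k; ++i) {
      double b = 0.0;
      for (int j = 0; j < k; ++j)
        b += trans(i, j) * emis(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / scale[t + 1];
    }
  }

  for (int t = 0; t < n; ++t) {
    double g = 0.0;
    for (int j = 0; j < k; ++j) { gamma(t, j) = alpha(t, j) * beta(t, j); g += gamma(t, j); }
    for (int j = 0; j < k; ++j) gamma(t, j) /= g;
  }

  NumericMatrix xi(k, k);
  for (int t = 0; t < n - 1; ++t) {
    double denom = 0.0;
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        denom += alpha(t, i) * trans(i, j) * emis(t + 1, j) * beta(t + 1, j);
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        xi(i, j) += alpha(t, i) * trans(i, j) * emis(t + 1, j) * beta(t + 1, j) / denom;
  }
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi, _["loglik"] = ll);
}
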