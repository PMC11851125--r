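#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Log-space CTC forward-backward over the blank-augmented state lattice.
// States s = 0..S-1 with S = 2L+1; even states are blank, odd state 2j+1 is
// label j. Class indices are 1-based on the R side; the blank is the LAST
// class (index K).

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// logp: T x K matrix of per-frame log-probabilities (rows sum to 1 after exp),
// label: classes in 1..K-1. Returns the negative log-likelihood; when
// want_grad, also the per-frame class posteriors gamma (T x K) so that the
// gradient w.r.t. logits is softmax(logits) - gamma; when want_states, the
// full T x S state posterior (used for per-base quality estimation).
// [[Rcpp::export(name = ".ctc_forward_cpp")]]
List ctc_forward_cpp(NumericMatrix logp, IntegerVector label,
                     bool want_grad = false, bool want_states = false) {
  const int T = logp.nrow(), K = logp.ncol();
  const int L = label.size();
  const int S = 2 * L + 1;
  const int blank = K;

  std::vector<int> lab(S);
  for (int s = 0; s < S; ++s) lab[s] = (s % 2 == 0) ? blank : label[s / 2];

  // minimal frames: every label frame plus a separating blank per repeat
  int repeats = 0;
  for (int j = 1; j < L; ++j) if (label[j] == label[j - 1]) ++repeats;
  bool feasible = (T >= L + repeats) && (T >= 1 || L == 0);
  if (T == 0) {
    // empty posteriorgram: only the empty label has probability 1
    double loss = (L == 0) ? 0.0 : R_PosInf;
    return List::create(_["loss"] = loss, _["feasible"] = (L == 0),
                        _["gamma"] = R_NilValue, _["state_post"] = R_NilValue);
  }
  if (!feasible) {
    return List::create(_["loss"] = R_PosInf, _["feasible"] = false,
                        _["gamma"] = R_NilValue, _["state_post"] = R_NilValue);
  }

  std::vector<double> alpha((size_t)T * S, R_NegInf);
  alpha[0] = logp(0, blank - 1);
  if (S > 1) alpha[1] = logp(0, lab[1] - 1);
  for (int t = 1; t < T; ++t) {
    const size_t off = (size_t)t * S, poff = (size_t)(t - 1) * S;
    for (int s = 0; s < S; ++s) {
      double a = alpha[poff + s];
      if (s >= 1) a = lse2(a, alpha[poff + s - 1]);
      if (s >= 2 && lab[s] != blank && lab[s] != lab[s - 2])
        a = lse2(a, alpha[poff + s - 2]);
      alpha[off + s] = (a == R_NegInf) ? R_NegInf : a + logp(t, lab[s] - 1);
    }
  }
  double logP = alpha[(size_t)(T - 1) * S + S - 1];
  if (S > 1) logP = lse2(logP, alpha[(size_t)(T - 1) * S + S - 2]);
  if (logP == R_NegInf)
    return List::create(_["loss"] = R_PosInf, _["feasible"] = false,
                        _["gamma"] = R_NilValue, _["state_post"] = R_NilValue);

  if (!want_grad && !want_states)
    return List::create(_["loss"] = -logP, _["feasible"] = true,
                        _["gamma"] = R_NilValue, _["state_post"] = R_NilValue);

  // beta includes the emission at time t (symmetric with alpha)
  std::vector<double> beta((size_t)T * S, R_NegInf);
  beta[(size_t)(T - 1) * S + S - 1] = logp(T - 1, lab[S - 1] - 1);
  if (S > 1) beta[(size_t)(T - 1) * S + S - 2] = logp(T - 1, lab[S - 2] - 1);
  for (int t = T - 2; t >= 0; --t) {
    const size_t off = (size_t)t * S, noff = (size_t)(t + 1) * S;
    for (int s = 0; s < S; ++s) {
      double b = beta[noff + s];
      if (s + 1 < S) b = lse2(b, beta[noff + s + 1]);
      if (s + 2 < S && lab[s + 2] != blank && lab[s + 2] != lab[s])
        b = lse2(b, beta[noff + s + 2]);
      beta[off + s] = (b == R_NegInf) ? R_NegInf : b + logp(t, lab[s] - 1);
    }
  }

  NumericMatrix gamma(T, K);
  NumericMatrix spost;
  if (want_states) spost = NumericMatrix(T, S);
  for (int t = 0; t < T; ++t) {
    const size_t off = (size_t)t * S;
    for (int s = 0; s < S; ++s) {
      double la = alpha[off + s], lb = beta[off + s];
      if (la == R_NegInf || lb == R_NegInf) continue;
      // alpha and beta both include logp(t, lab[s]); remove one copy
      double lg = la + lb - logp(t, lab[s] - 1) - logP;
      double g = std::exp(lg);
      gamma(t, lab[s] - 1) += g;
      if (want_states) spost(t, s) = g;
    }
  }
  return List::create(_["loss"] = -logP, _["feasible"] = true,
                      _["gamma"] = gamma,
                      _["state_post"] = want_states ? (SEXP)spost : R_NilValue);
}
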