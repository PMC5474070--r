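#include <Rcpp.h>
using namespace Rcpp;

// EWA likelihood kernels.
//
// The model replays the bout series in (day, seq) order. For bout t by
// actor j: individual choice probabilities are soft-max(lambda * A[j, ]);
// if the actor witnessed anything in its window (any finite logN) the
// social term S_i propto N_i^f * exp(sum_k beta_k * kappa_ki) over
// witnessed techniques is mixed in with weight gam_j; the realized
// technique's log-probability is recorded; then A[j, chosen] moves toward
// the realized pay-off at rate phi_j.
//
// Window counts and mean cue values depend only on the data and window
// width, so log(N) (=-Inf where N = 0) and kappa (n x K x 5, column-major)
// are precomputed in R. Because each bout's probability depends only on its
// actor's parameters and attraction state, the total log-likelihood
// factorizes over actors; the single-actor kernel below lets a sampler
// re-evaluate one individual's contribution when only that individual's
// varying effect moved.

static inline double bout_logprob(const double* Arow, int K, int c,
                                  double lambda, double gam, double f,
                                  const double* beta,
                                  const double* logN, const double* kappa,
                                  int n, int t, bool social,
                                  std::vector<double>& w) {
  // individual component: stable soft-max of lambda * A
  double m = -INFINITY;
  for (int i = 0; i < K; ++i) {
    w[i] = lambda * Arow[i];
    if (w[i] > m) m = w[i];
  }
  double tot = 0.0;
  for (int i = 0; i < K; ++i) { w[i] = std::exp(w[i] - m); tot += w[i]; }
  double p = w[c] / tot;

  if (social && gam > 0.0) {
    bool seen = false;
    double mw = -INFINITY;
    for (int i = 0; i < K; ++i) {
      double ln = logN[t + n * i];
      if (std::isfinite(ln)) {
        double B = 0.0;
        for (int k = 0; k < 5; ++k)
          B += beta[k] * kappa[t + n * (i + K * k)];
        w[K + i] = f * ln + B;
        if (w[K + i] > mw) mw = w[K + i];
        seen = true;
      } else {
        w[K + i] = -INFINITY;
      }
    }
    if (seen) {
      double stot = 0.0;
      for (int i = 0; i < K; ++i) {
        w[K + i] = (w[K + i] == -INFINITY) ? 0.0 : std::exp(w[K + i] - mw);
        stot += w[K + i];
      }
      p = (1.0 - gam) * p + gam * w[K + c] / stot;
    }
  }
  return std::log(p);
}

// Pointwise log-likelihood over all bouts. actor, tech: 1-based indices.
// A0: J x K initial attractions (copied). beta: J x 5.
// [[Rcpp::export]]
NumericVector ewa_loglik_cpp(IntegerVector actor, IntegerVector tech,
                             NumericVector payoff, NumericVector logN,
                             NumericVector kappa, NumericMatrix A0,
                             double lambda, NumericVector phi,
                             NumericVector gam, NumericVector f,
                             NumericMatrix beta, bool social) {
  const int n = actor.size();
  const int K = A0.ncol();
  NumericMatrix A = clone(A0);
  NumericVector ll(n);
  std::vector<double> w(2 * K);
  std::vector<double> betaj(5);

  for (int t = 0; t < n; ++t) {
    const int j = actor[t] - 1;
    const int c = tech[t] - 1;
    for (int k = 0; k < 5; ++k) betaj[k] = beta(j, k);
    // row pointer arithmetic: A is column-major with J rows
    std::vector<double> Arow(K);
    for (int i = 0; i < K; ++i) Arow[i] = A(j, i);
    ll[t] = bout_logprob(Arow.data(), K, c, lambda, gam[j], f[j],
                         betaj.data(), REAL(logN), REAL(kappa), n, t,
                         social, w);
    A(j, c) = (1.0 - phi[j]) * A(j, c) + phi[j] * payoff[t];
  }
  return ll;
}

// Summed log-likelihood of one actor's bouts. rows: 0-based indices into
// the full bout table (that actor's bouts, in time order). A0j: the actor's
// initial attraction row (length K). betaj: length 5.
// [[Rcpp::export]]
double ewa_loglik_actor_cpp(IntegerVector rows, IntegerVector tech,
                            NumericVector payoff, NumericVector logN,
                            NumericVector kappa, NumericVector A0j,
                            int n, double lambda, double phi_j,
                            double gam_j, double f_j, NumericVector betaj,
                            bool social) {
  const int K = A0j.size();
  std::vector<double> A(A0j.begin(), A0j.end());
  std::vector<double> w(2 * K);
  double total = 0.0;
  for (int r = 0; r < rows.size(); ++r) {
    const int t = rows[r];
    const int c = tech[t] - 1;
    total += bout_logprob(A.data(), K, c, lambda, gam_j, f_j,
                          REAL(betaj), REAL(logN), REAL(kappa), n, t,
                          social, w);
    A[c] = (1.0 - phi_j) * A[c] + phi_j * payoff[t];
  }
  return total;
}
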