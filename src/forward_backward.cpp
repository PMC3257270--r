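#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact forward-backward for a parsimonious higher-order HMM, run on the
// equivalent first-order chain over tuples of the min(t, r) most recent
// states.  Tuple codes put the most recent state in the lowest base-K
// digit, so a tuple code *is* the context code (0-based) of the transition
// leaving it.  Growing tuples handle positions t <= r: the transition into
// position t + 1 uses the height-min(t, r) matrix.
//
// dens: T x K emission densities (may be rescaled per row; scaling cancels
//       in posteriors and is accounted for by the caller in the log-lik).
// P:    list of K^k x K per-context transition probability matrices,
//       k = 1..r (expanded from the trees by the caller).
// Returns scaled-forward log-likelihood, per-position state posteriors,
// expected transition counts per order, and expected initial-state counts.

// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix dens, NumericVector pi, List P, int r,
            bool want_posteriors) {
  const int T = dens.nrow();
  const int K = dens.ncol();

  std::vector<NumericMatrix> Pk(r);
  for (int k = 0; k < r; ++k) Pk[k] = as<NumericMatrix>(P[k]);

  // space sizes per position
  std::vector<int> M(T);
  {
    long long m = 1;
    for (int t = 0; t < T; ++t) {
      if (t < r) m = (t == 0) ? K : m * K;
      M[t] = (int)m;
    }
  }
  const int Mr = M[T - 1];

  std::vector<std::vector<double> > alpha(T);
  std::vector<double> scale(T);

  // forward
  alpha[0].assign(M[0], 0.0);
  double s = 0.0;
  for (int j = 0; j < K; ++j) {
    double v = pi[j] * dens(0, j);
    alpha[0][j] = v;
    s += v;
  }
  if (!(s > 0.0)) stop("forward pass underflow at position 1");
  scale[0] = s;
  for (int j = 0; j < K; ++j) alpha[0][j] /= s;

  for (int t = 0; t < T - 1; ++t) {
    const int k = std::min(t + 1, r);            // matrix height used
    const NumericMatrix& Pm = Pk[k - 1];
    const int Mt = M[t], Mn = M[t + 1];
    const int modBase = (t + 1 < r) ? 0 : Mr / K; // u mod K^(r-1) divisor
    std::vector<double>& an = alpha[t + 1];
    an.assign(Mn, 0.0);
    for (int u = 0; u < Mt; ++u) {
      const double au = alpha[t][u];
      if (au == 0.0) continue;
      const int base = (t + 1 < r) ? u * K : (u % modBase) * K;
      for (int j = 0; j < K; ++j) {
        an[base + j] += au * Pm(u, j);
      }
    }
    double sn = 0.0;
    for (int v = 0; v < Mn; ++v) {
      an[v] *= dens(t + 1, v % K);
      sn += an[v];
    }
    if (!(sn > 0.0)) stop("forward pass underflow at position %d", t + 2);
    scale[t + 1] = sn;
    for (int v = 0; v < Mn; ++v) an[v] /= sn;
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(scale[t]);

  List out = List::create(_["loglik"] = loglik);
  if (!want_posteriors) return out;

  // backward (scaled: betahat_T = 1)
  std::vector<std::vector<double> > beta(T);
  beta[T - 1].assign(M[T - 1], 1.0);
  for (int t = T - 2; t >= 0; --t) {
    const int k = std::min(t + 1, r);
    const NumericMatrix& Pm = Pk[k - 1];
    const int Mt = M[t];
    const int modBase = (t + 1 < r) ? 0 : Mr / K;
    beta[t].assign(Mt, 0.0);
    const double inv_c = 1.0 / scale[t + 1];
    for (int u = 0; u < Mt; ++u) {
      const int base = (t + 1 < r) ? u * K : (u % modBase) * K;
      double acc = 0.0;
      for (int j = 0; j < K; ++j) {
        acc += Pm(u, j) * dens(t + 1, j) * beta[t + 1][base + j];
      }
      beta[t][u] = acc * inv_c;
    }
  }

  NumericMatrix gamma(T, K);
  for (int t = 0; t < T; ++t) {
    for (int u = 0; u < M[t]; ++u) {
      gamma(t, u % K) += alpha[t][u] * beta[t][u];
    }
  }

  List counts(r);
  for (int k = 1; k <= r; ++k) {
    int rows = 1;
    for (int i = 0; i < k; ++i) rows *= K;
    counts[k - 1] = NumericMatrix(rows, K);
  }
  for (int t = 0; t < T - 1; ++t) {
    const int k = std::min(t + 1, r);
    const NumericMatrix& Pm = Pk[k - 1];
    NumericMatrix Nk = as<NumericMatrix>(counts[k - 1]);
    const int Mt = M[t];
    const int modBase = (t + 1 < r) ? 0 : Mr / K;
    const double inv_c = 1.0 / scale[t + 1];
    for (int u = 0; u < Mt; ++u) {
      const double au = alpha[t][u];
      if (au == 0.0) continue;
      const int base = (t + 1 < r) ? u * K : (u % modBase) * K;
      for (int j = 0; j < K; ++j) {
        Nk(u, j) += au * Pm(u, j) * dens(t + 1, j) *
          beta[t + 1][base + j] * inv_c;
      }
    }
  }

  NumericVector init_counts(K);
  for (int j = 0; j < K; ++j) init_counts[j] = gamma(0, j);

  out["gamma"] = gamma;
  out["counts"] = counts;
  out["init_counts"] = init_counts;
  return out;
}

// Ancestral sampling of a hidden state path, using R's RNG stream so that
// set.seed() governs reproducibility.  Returns 1-based state indices.

// [[Rcpp::export(name = ".sample_states_cpp")]]
IntegerVector sample_states_cpp(int T, NumericVector pi, List P, int r, int K) {
  std::vector<NumericMatrix> Pk(r);
  for (int k = 0; k < r; ++k) Pk[k] = as<NumericMatrix>(P[k]);
  IntegerVector q(T);
  RNGScope scope;

  // context code over the min(t, r) most recent states, most recent in the
  // lowest digit
  long long ctx = 0, ctxSize = 1, cap = 1;
  for (int i = 0; i < r; ++i) cap *= K;

  for (int t = 0; t < T; ++t) {
    double u = unif_rand();
    int j = K - 1;
    if (t == 0 || r == 0) {
      double acc = 0.0;
      for (int i = 0; i < K; ++i) {
        acc += pi[i];
        if (u <= acc) { j = i; break; }
      }
    } else {
      int k = std::min(t, r);
      const NumericMatrix& Pm = Pk[k - 1];
      double acc = 0.0;
      for (int i = 0; i < K; ++i) {
        acc += Pm((int)ctx, i);
        if (u <= acc) { j = i; break; }
      }
    }
    q[t] = j + 1;
    if (r > 0) {
      if (ctxSize < cap) ctxSize *= K;
      ctx = (ctx * K + j) % ctxSize;
    }
  }
  return q;
}
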