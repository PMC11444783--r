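// Admixture-model Gibbs sampler for diploid multilocus genotypes.
// Uses R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

// draw from Dirichlet(alpha) into out[0..k)
static void rdirichlet(const std::vector<double>& alpha, std::vector<double>& out) {
  double s = 0.0;
  for (size_t i = 0; i < alpha.size(); ++i) {
    out[i] = R::rgamma(alpha[i], 1.0);
    s += out[i];
  }
  if (s <= 0.0) { // numeric underflow guard: fall back to uniform
    for (size_t i = 0; i < alpha.size(); ++i) out[i] = 1.0 / alpha.size();
    return;
  }
  for (size_t i = 0; i < alpha.size(); ++i) out[i] /= s;
}

static int sample_cat(const std::vector<double>& w, int K) {
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += w[k];
  double u = unif_rand() * s;
  double c = 0.0;
  for (int k = 0; k < K; ++k) {
    c += w[k];
    if (u <= c) return k;
  }
  return K - 1;
}

// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs(IntegerMatrix A1, IntegerMatrix A2,
                     IntegerVector n_alleles, int K,
                     int burn_in, int iters, double alpha_init) {
  const int n = A1.nrow(), L = A1.ncol();
  int Jmax = 0;
  for (int l = 0; l < L; ++l) Jmax = std::max(Jmax, n_alleles[l]);

  // state
  std::vector<int> z1(n * L, -1), z2(n * L, -1);
  std::vector<double> P(K * L * Jmax, 0.0);        // [k][l][j]
  std::vector<double> Q(n * K, 1.0 / K);
  double alpha = alpha_init;

  // init z uniformly at random over clusters
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      if (A1(i, l) == NA_INTEGER) continue;
      z1[i * L + l] = (int)(unif_rand() * K) % K;
      z2[i * L + l] = (int)(unif_rand() * K) % K;
    }

  NumericVector trace(iters);
  NumericMatrix Qsum(n, K);
  std::vector<double> Psum(K * L * Jmax, 0.0);
  NumericVector alpha_trace(iters);

  std::vector<double> dir_alpha(Jmax), dir_out(Jmax);
  std::vector<double> qa(K), qout(K), w(K);

  const int total = burn_in + iters;
  for (int sweep = 0; sweep < total; ++sweep) {
    // ---- update cluster allele frequencies P | z
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        const int J = n_alleles[l];
        for (int j = 0; j < J; ++j) dir_alpha[j] = 1.0;   // Dirichlet(1) prior
        for (int i = 0; i < n; ++i) {
          if (A1(i, l) == NA_INTEGER) continue;
          if (z1[i * L + l] == k) dir_alpha[A1(i, l) - 1] += 1.0;
          if (z2[i * L + l] == k) dir_alpha[A2(i, l) - 1] += 1.0;
        }
        std::vector<double> a(dir_alpha.begin(), dir_alpha.begin() + J);
        std::vector<double> o(J);
        rdirichlet(a, o);
        for (int j = 0; j < J; ++j) P[(k * L + l) * Jmax + j] = o[j];
      }

    // ---- update admixture proportions Q | z
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) qa[k] = alpha;
      for (int l = 0; l < L; ++l) {
        if (A1(i, l) == NA_INTEGER) continue;
        qa[z1[i * L + l]] += 1.0;
        qa[z2[i * L + l]] += 1.0;
      }
      rdirichlet(qa, qout);
      for (int k = 0; k < K; ++k) Q[i * K + k] = qout[k];
    }

    // ---- update origins z | P, Q
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l) {
        if (A1(i, l) == NA_INTEGER) continue;
        const int a1 = A1(i, l) - 1, a2 = A2(i, l) - 1;
        for (int k = 0; k < K; ++k)
          w[k] = Q[i * K + k] * P[(k * L + l) * Jmax + a1];
        z1[i * L + l] = sample_cat(w, K);
        for (int k = 0; k < K; ++k)
          w[k] = Q[i * K + k] * P[(k * L + l) * Jmax + a2];
        z2[i * L + l] = sample_cat(w, K);
      }

    // ---- Metropolis update of the Dirichlet alpha (K > 1 only)
    if (K > 1) {
      double prop = alpha + norm_rand() * 0.25;
      if (prop > 0.0 && prop < 10.0) {
        double slogq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k)
            slogq += std::log(std::max(Q[i * K + k], 1e-300));
        double lr = n * (R::lgammafn(K * prop) - K * R::lgammafn(prop)
                         - R::lgammafn(K * alpha) + K * R::lgammafn(alpha))
                    + (prop - alpha) * slogq;
        if (std::log(unif_rand()) < lr) alpha = prop;
      }
    }

    // ---- log-likelihood of the data given (P, Q)
    double logL = 0.0;
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l) {
        if (A1(i, l) == NA_INTEGER) continue;
        const int a1 = A1(i, l) - 1, a2 = A2(i, l) - 1;
        double s1 = 0.0, s2 = 0.0;
        for (int k = 0; k < K; ++k) {
          s1 += Q[i * K + k] * P[(k * L + l) * Jmax + a1];
          s2 += Q[i * K + k] * P[(k * L + l) * Jmax + a2];
        }
        logL += std::log(std::max(s1, 1e-300)) + std::log(std::max(s2, 1e-300));
      }
    if (!R_finite(logL))
      stop("non-finite likelihood at sweep %d", sweep + 1);

    if (sweep >= burn_in) {
      const int s = sweep - burn_in;
      trace[s] = logL;
      alpha_trace[s] = alpha;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q[i * K + k];
      for (size_t t = 0; t < Psum.size(); ++t) Psum[t] += P[t];
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= iters;
  NumericVector Pmean(Psum.size());
  for (size_t t = 0; t < Psum.size(); ++t) Pmean[t] = Psum[t] / iters;
  Pmean.attr("dim") = IntegerVector::create(Jmax, L, K);

  return List::create(_["Q"] = Qsum, _["logL"] = trace,
                      _["P"] = Pmean, _["alpha_trace"] = alpha_trace);
}
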