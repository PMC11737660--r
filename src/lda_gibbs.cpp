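#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// doc_id / word_id are 0-based parallel vectors, one element per token
// occurrence. Uses R's RNG so that set.seed() on the R side makes runs
// bit-identical. Point estimates are taken from the final count state;
// when average = true, phi/theta sums over post-burn-in sweeps are also
// accumulated and returned.
// [[Rcpp::export(name = ".lda_gibbs_cpp")]]
List lda_gibbs_cpp(IntegerVector doc_id, IntegerVector word_id,
                   int D, int V, int K,
                   double alpha, double beta,
                   int n_iter, int burn_in, bool average) {
  const int N = doc_id.size();
  IntegerVector z(N);
  IntegerMatrix n_dk(D, K), n_kv(K, V);
  IntegerVector n_k(K), n_d(D);

  // random initial assignment
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    n_dk(doc_id[i], k)++;
    n_kv(k, word_id[i])++;
    n_k[k]++;
    n_d[doc_id[i]]++;
  }

  std::vector<double> p(K);
  const double Vbeta = V * beta;
  NumericMatrix phi_sum(K, V), theta_sum(D, K);
  int n_samples = 0;

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < N; ++i) {
      const int d = doc_id[i], w = word_id[i], k_old = z[i];
      n_dk(d, k_old)--; n_kv(k_old, w)--; n_k[k_old]--;

      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        total += (n_dk(d, k) + alpha) * (n_kv(k, w) + beta) / (n_k[k] + Vbeta);
        p[k] = total;
      }
      double u = unif_rand() * total;
      int k_new = 0;
      while (k_new < K - 1 && p[k_new] < u) ++k_new;

      z[i] = k_new;
      n_dk(d, k_new)++; n_kv(k_new, w)++; n_k[k_new]++;
    }
    if (average && iter >= burn_in) {
      for (int k = 0; k < K; ++k) {
        const double denom = n_k[k] + Vbeta;
        for (int v = 0; v < V; ++v)
          phi_sum(k, v) += (n_kv(k, v) + beta) / denom;
      }
      for (int d = 0; d < D; ++d) {
        const double denom = n_d[d] + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) += (n_dk(d, k) + alpha) / denom;
      }
      ++n_samples;
    }
  }

  return List::create(_["z"] = z, _["n_dk"] = n_dk, _["n_kv"] = n_kv,
                      _["n_k"] = n_k, _["n_d"] = n_d,
                      _["phi_sum"] = phi_sum, _["theta_sum"] = theta_sum,
                      _["n_samples"] = n_samples);
}
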