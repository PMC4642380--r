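#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
//
// docs: list of 0-based word-id integer vectors, one per document (empty
// documents allowed). Topics and words are integrated out; each sweep
// resamples every token's topic from
//   p(z_i = k | z_-i, w) ∝ (n_dk^-i + alpha) (n_kw^-i + beta) / (n_k^-i + V beta)
// in document order then token order. Uses R's RNG (unif_rand), so results
// are reproducible under set.seed(). After burn_in sweeps, every thin-th
// sweep contributes one posterior draw of the smoothed theta / phi point
// estimates to running means.
// [[Rcpp::export]]
List gibbs_lda_cpp(const List& docs, int V, int K, double alpha, double beta,
                   int n_iter, int burn_in, int thin) {
  const int D = docs.size();
  std::vector<std::vector<int>> w(D);
  int total_tokens = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
    total_tokens += dv.size();
  }

  IntegerMatrix n_dk(D, K);
  IntegerMatrix n_kw(K, V);
  IntegerVector n_k(K);
  std::vector<std::vector<int>> z(D);

  // random initialization
  for (int d = 0; d < D; ++d) {
    const int nd = w[d].size();
    z[d].resize(nd);
    for (int i = 0; i < nd; ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      ++n_dk(d, k);
      ++n_kw(k, w[d][i]);
      ++n_k[k];
    }
  }

  NumericMatrix theta_sum(D, K);
  NumericMatrix phi_sum(K, V);
  int n_saved = 0;
  const double Vbeta = V * beta;
  std::vector<double> p(K);

  for (int it = 1; it <= n_iter; ++it) {
    for (int d = 0; d < D; ++d) {
      const int nd = w[d].size();
      for (int i = 0; i < nd; ++i) {
        const int word = w[d][i];
        const int old_k = z[d][i];
        --n_dk(d, old_k);
        --n_kw(old_k, word);
        --n_k[old_k];
        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          total += (n_dk(d, k) + alpha) * (n_kw(k, word) + beta) /
                   (n_k[k] + Vbeta);
          p[k] = total;
        }
        const double u = unif_rand() * total;
        int new_k = 0;
        while (new_k < K - 1 && p[new_k] < u) ++new_k;
        z[d][i] = new_k;
        ++n_dk(d, new_k);
        ++n_kw(new_k, word);
        ++n_k[new_k];
      }
    }
    if (it > burn_in && thin > 0 && (it - burn_in) % thin == 0) {
      ++n_saved;
      for (int d = 0; d < D; ++d) {
        const double denom = w[d].size() + K * alpha;
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) += (n_dk(d, k) + alpha) / denom;
      }
      for (int k = 0; k < K; ++k) {
        const double denom = n_k[k] + Vbeta;
        for (int v = 0; v < V; ++v)
          phi_sum(k, v) += (n_kw(k, v) + beta) / denom;
      }
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector z_flat(total_tokens);
  int pos = 0;
  for (int d = 0; d < D; ++d)
    for (size_t i = 0; i < z[d].size(); ++i) z_flat[pos++] = z[d][i];

  if (n_saved > 0) {
    theta_sum = clone(theta_sum);
    phi_sum = clone(phi_sum);
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < K; ++k) theta_sum(d, k) /= n_saved;
    for (int k = 0; k < K; ++k)
      for (int v = 0; v < V; ++v) phi_sum(k, v) /= n_saved;
  }

  return List::create(_["z"] = z_flat, _["n_dk"] = n_dk, _["n_kw"] = n_kw,
                      _["n_k"] = n_k, _["theta_mean"] = theta_sum,
                      _["phi_mean"] = phi_sum, _["n_saved"] = n_saved);
}

// Fold-in sampler for held-out documents: phi is held fixed at the fitted
// estimate, only the document-topic counts are resampled.
// [[Rcpp::export]]
NumericMatrix fold_in_cpp(const List& docs, const NumericMatrix& phi,
                          double alpha, int n_iter, int burn_in, int thin) {
  const int D = docs.size();
  const int K = phi.nrow();
  NumericMatrix theta_sum(D, K);
  std::vector<double> p(K);
  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    const int nd = dv.size();
    std::vector<int> zd(nd);
    std::vector<int> ndk(K, 0);
    for (int i = 0; i < nd; ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      zd[i] = k;
      ++ndk[k];
    }
    int saved = 0;
    const double denom = nd + K * alpha;
    for (int it = 1; it <= n_iter; ++it) {
      for (int i = 0; i < nd; ++i) {
        const int word = dv[i];
        --ndk[zd[i]];
        double total = 0.0;
        for (int k = 0; k < K; ++k) {
          total += (ndk[k] + alpha) * phi(k, word);
          p[k] = total;
        }
        const double u = unif_rand() * total;
        int new_k = 0;
        while (new_k < K - 1 && p[new_k] < u) ++new_k;
        zd[i] = new_k;
        ++ndk[new_k];
      }
      if (it > burn_in && thin > 0 && (it - burn_in) % thin == 0) {
        ++saved;
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) += (ndk[k] + alpha) / denom;
      }
    }
    if (saved == 0) {  // fall back to the final state
      for (int k = 0; k < K; ++k) theta_sum(d, k) = (ndk[k] + alpha) / denom;
    } else {
      for (int k = 0; k < K; ++k) theta_sum(d, k) /= saved;
    }
  }
  return theta_sum;
}
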