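# Exact posterior for a tiny LDA instance by exhaustive enumeration.
#
# docs: list of 0-based word-id vectors. Enumerates all K^N topic-assignment
# states, scores each with the collapsed joint p(z, w) (Dirichlet-multinomial
# in both the document-topic and topic-word blocks), and returns the exact
# posterior mean of the smoothed document-topic proportions
# (n_dk + alpha) / (N_d + K alpha). Independent of the Gibbs sampler: no
# sampling, direct summation.
exact_theta_posterior <- function(docs, V, K, alpha, beta) {
  D <- length(docs)
  lens <- lengths(docs)
  N <- sum(lens)
  doc_of <- rep(seq_len(D), lens)
  word_of <- unlist(docs) + 1L
  states <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  theta_mean <- matrix(0, D, K)
  total_weight <- 0
  for (s in seq_len(nrow(states))) {
    z <- states[s, ]
    n_dk <- matrix(0, D, K)
    n_kw <- matrix(0, K, V)
    for (i in seq_len(N)) {
      n_dk[doc_of[i], z[i]] <- n_dk[doc_of[i], z[i]] + 1
      n_kw[z[i], word_of[i]] <- n_kw[z[i], word_of[i]] + 1
    }
    n_k <- rowSums(n_kw)
    log_w <- sum(lgamma(n_dk + alpha)) - sum(lgamma(lens + K * alpha)) +
      sum(lgamma(n_kw + beta)) - sum(lgamma(n_k + V * beta))
    w <- exp(log_w)
    total_weight <- total_weight + w
    theta_mean <- theta_mean + w * (n_dk + alpha) /
      matrix(lens + K * alpha, D, K)
  }
  theta_mean / total_weight
}
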