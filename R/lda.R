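#' Fit a latent Dirichlet allocation topic model by collapsed Gibbs sampling
#'
#' Models each post as a random mixture over `K` latent topics, each topic a
#' distribution over the vocabulary. Inference is collapsed Gibbs sampling:
#' the topic proportions and word distributions are integrated out and each
#' token's topic assignment is resampled in turn from
#' \deqn{p(z_i = k \mid z_{-i}, w) \propto
#'   (n_{dk}^{-i} + \alpha)\,\frac{n_{kw}^{-i} + \beta}{n_k^{-i} + V\beta}}
#' where \eqn{n_{dk}}, \eqn{n_{kw}}, \eqn{n_k} are the usual count tables
#' excluding token \eqn{i}. Sweeps visit documents in order and tokens in
#' order within each document. After `burn_in` sweeps, every `thin`-th sweep
#' contributes one draw to the posterior-mean estimates of the document-topic
#' matrix \eqn{\theta} and the topic-word matrix \eqn{\phi}.
#'
#' Defaults follow common practice for this sampler: a symmetric document
#' prior `alpha = 50/K`, word prior `beta = 0.01`, 1000 sweeps with the first
#' half discarded, and estimates averaged over every 10th retained sweep.
#' Identical seed and input give bit-identical assignments. Empty documents
#' are retained (their \eqn{\theta} row is the uniform prior mean), so the
#' model keeps one row per post.
#'
#' @param corpus a tokenized [forum_corpus()] (see [tokenize_corpus()]).
#' @param K number of topics, `>= 1`.
#' @param alpha symmetric document-topic Dirichlet concentration, `> 0`.
#' @param beta symmetric topic-word Dirichlet concentration, `> 0`.
#' @param n_iter total Gibbs sweeps.
#' @param burn_in sweeps discarded before averaging, `< n_iter`.
#' @param thin keep every `thin`-th post-burn-in sweep for averaging.
#' @param seed integer RNG seed. With `n_chains > 1`, chain `c` uses
#'   `seed + c - 1`.
#' @param n_chains number of independently initialised chains; the chain
#'   with the highest collapsed joint log-likelihood ([logLik.lda_model()])
#'   at its final state is returned. Restarting guards against the
#'   label-splitting local modes a single sparse-prior chain can get stuck
#'   in.
#' @return an object of class `lda_model`: token assignments `z`, count
#'   tables `n_dk` (documents by topics), `n_kw` (topics by vocabulary),
#'   `n_k`, averaged `theta_mean` / `phi_mean` (when any sweep was retained),
#'   the `vocabulary`, document ids, and the call parameters in `params`.
#' @seealso [estimate_theta()], [estimate_phi()], [top_words()]
#' @export
fit_lda <- function(corpus, K, alpha = 50 / K, beta = 0.01,
                    n_iter = 1000, burn_in = 500, thin = 10, seed = 1L,
                    n_chains = 1L) {
  stopifnot(inherits(corpus, "forum_corpus"))
  if (is.null(corpus$tokens)) stop("corpus must be tokenized before fitting")
  if (!is.numeric(K) || K < 1 || K != as.integer(K)) {
    stop("K must be a positive integer")
  }
  K <- as.integer(K)
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (burn_in < 0 || burn_in >= n_iter) {
    stop("burn_in must be in [0, n_iter)")
  }
  docs <- token_ids(corpus)
  if (sum(lengths(docs)) == 0) {
    stop("cannot fit: corpus has no tokens (all documents empty)")
  }
  V <- length(corpus$vocabulary)
  n_chains <- max(1L, as.integer(n_chains))
  best <- NULL
  for (chain in seq_len(n_chains)) {
    chain_seed <- as.integer(seed) + chain - 1L
    set.seed(chain_seed)
    res <- gibbs_lda_cpp(docs, V, K, alpha, beta,
                         as.integer(n_iter), as.integer(burn_in),
                         as.integer(thin))
    ll <- collapsed_loglik(res$n_dk, res$n_kw, res$n_k, lengths(docs),
                           alpha, beta)
    if (is.null(best) || ll > best$ll) {
      best <- list(res = res, ll = ll, seed = chain_seed)
    }
  }
  res <- best$res
  structure(list(
    z = res$z,
    n_dk = res$n_dk,
    n_kw = res$n_kw,
    n_k = res$n_k,
    theta_mean = if (res$n_saved > 0) res$theta_mean else NULL,
    phi_mean = if (res$n_saved > 0) res$phi_mean else NULL,
    n_saved = res$n_saved,
    doc_lengths = lengths(docs),
    doc_ids = corpus$posts$post_id,
    vocabulary = corpus$vocabulary,
    forum_id = corpus$forum_id,
    loglik = best$ll,
    params = list(K = K, alpha = alpha, beta = beta, n_iter = n_iter,
                  burn_in = burn_in, thin = thin, seed = as.integer(seed),
                  n_chains = n_chains, chain_seed = best$seed)
  ), class = "lda_model")
}

# collapsed joint log p(z, w): Dirichlet-multinomial in both blocks
collapsed_loglik <- function(n_dk, n_kw, n_k, lens, alpha, beta) {
  K <- ncol(n_dk)
  V <- ncol(n_kw)
  sum(lgamma(n_dk + alpha)) - sum(lgamma(lens + K * alpha)) +
    nrow(n_dk) * (lgamma(K * alpha) - K * lgamma(alpha)) +
    sum(lgamma(n_kw + beta)) - sum(lgamma(n_k + V * beta)) +
    K * (lgamma(V * beta) - V * lgamma(beta))
}

#' Collapsed joint log-likelihood of a fitted model
#'
#' `log p(z, w)` of the final Gibbs state, with topic proportions and word
#' distributions integrated out. Used to select among restarted chains.
#'
#' @param object an `lda_model`.
#' @param ... unused.
#' @export
logLik.lda_model <- function(object, ...) {
  structure(object$loglik, df = NA_integer_, class = "logLik")
}

#' Document-topic proportions of a fitted model
#'
#' The smoothed point estimate
#' \eqn{\theta_{dk} = (n_{dk} + \alpha) / (N_d + K\alpha)}, averaged over the
#' retained post-burn-in sweeps when sample averaging was enabled during
#' fitting (`average = TRUE`, the default), otherwise evaluated at the final
#' state. Each row is a proper distribution; an empty document gets the
#' uniform row `1/K`.
#'
#' @param model an [fit_lda()] object.
#' @param average use the posterior-averaged estimate when available.
#' @return documents-by-topics proportion matrix, rows named by post id.
#' @export
estimate_theta <- function(model, average = TRUE) {
  stopifnot(inherits(model, "lda_model"))
  theta <- if (average && !is.null(model$theta_mean)) {
    model$theta_mean
  } else {
    theta_from_counts(model$n_dk, model$params$alpha)
  }
  rownames(theta) <- model$doc_ids
  theta
}

theta_from_counts <- function(n_dk, alpha) {
  K <- ncol(n_dk)
  sweep_denom <- rowSums(n_dk) + K * alpha
  (n_dk + alpha) / sweep_denom
}

#' Topic-word distributions of a fitted model
#'
#' The smoothed point estimate
#' \eqn{\phi_{kw} = (n_{kw} + \beta) / (n_k + V\beta)}, averaged over retained
#' sweeps when available. A topic assigned no tokens gets the uniform row
#' `1/V`.
#'
#' @inheritParams estimate_theta
#' @return topics-by-vocabulary probability matrix, columns named by term.
#' @export
estimate_phi <- function(model, average = TRUE) {
  stopifnot(inherits(model, "lda_model"))
  phi <- if (average && !is.null(model$phi_mean)) {
    model$phi_mean
  } else {
    phi_from_counts(model$n_kw, model$n_k, model$params$beta)
  }
  colnames(phi) <- model$vocabulary
  phi
}

phi_from_counts <- function(n_kw, n_k, beta) {
  V <- ncol(n_kw)
  (n_kw + beta) / (n_k + V * beta)
}

#' Highest-probability words of each topic
#'
#' @param phi topics-by-vocabulary matrix ([estimate_phi()]) or an
#'   `lda_model`.
#' @param m how many words per topic; must not exceed the vocabulary size.
#' @param vocabulary term labels; taken from `phi` column names by default.
#' @return a list with one data frame per topic: columns `rank`, `term`,
#'   `probability`. Ties are broken toward the lower vocabulary id.
#' @export
top_words <- function(phi, m = 10, vocabulary = NULL) {
  if (inherits(phi, "lda_model")) phi <- estimate_phi(phi)
  if (is.null(vocabulary)) vocabulary <- colnames(phi)
  if (is.null(vocabulary)) vocabulary <- paste0("w", seq_len(ncol(phi)) - 1L)
  V <- ncol(phi)
  if (m > V) stop("m = ", m, " exceeds vocabulary size ", V)
  lapply(seq_len(nrow(phi)), function(k) {
    ord <- order(-phi[k, ], seq_len(V))[seq_len(m)]
    data.frame(rank = seq_len(m), term = vocabulary[ord],
               probability = unname(phi[k, ord]),
               stringsAsFactors = FALSE)
  })
}

#' Write the per-topic top-words report as TSV
#'
#' @param model an `lda_model` (or a phi matrix with column names).
#' @param path output file; columns topic, rank, term, probability.
#' @param m words per topic.
#' @return `path`, invisibly.
#' @export
write_top_words <- function(model, path, m = 10) {
  tw <- top_words(model, m)
  rows <- do.call(rbind, lapply(seq_along(tw), function(k) {
    cbind(topic = k - 1L, tw[[k]])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.lda_model <- function(x, ...) {
  p <- x$params
  cat("LDA topic model (collapsed Gibbs sampling)\n")
  cat(sprintf("  forum: %s — %d documents, %d tokens, %d vocabulary terms\n",
              x$forum_id, nrow(x$n_dk), sum(x$n_k), length(x$vocabulary)))
  cat(sprintf("  K = %d, alpha = %.4g, beta = %.4g; %d sweeps (burn-in %d, %d retained draws)\n",
              p$K, p$alpha, p$beta, p$n_iter, p$burn_in, x$n_saved))
  invisible(x)
}

#' @export
summary.lda_model <- function(object, m = 8, ...) {
  tw <- top_words(object, m = min(m, length(object$vocabulary)))
  mass <- object$n_k / sum(object$n_k)
  out <- list(model = object, top_words = tw, token_share = mass)
  class(out) <- "summary.lda_model"
  out
}

#' @export
print.summary.lda_model <- function(x, ...) {
  print(x$model)
  for (k in seq_along(x$top_words)) {
    cat(sprintf("  topic %d (%.1f%% of tokens): %s\n", k - 1L,
                100 * x$token_share[k],
                paste(x$top_words[[k]]$term, collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.lda_model <- function(object, ...) estimate_phi(object)

#' Infer topic proportions for new documents
#'
#' Folds held-out documents into a fitted model: the topic-word distributions
#' are held fixed at the fitted estimate and only the new documents' topic
#' assignments are resampled. Tokens absent from the training vocabulary are
#' dropped.
#'
#' @param object an `lda_model`.
#' @param newdata a [forum_corpus()] (tokenized or not; tokenization uses no
#'   stop list if needed) or a list of character token vectors. When omitted,
#'   returns [estimate_theta()] of the training documents.
#' @param n_iter,burn_in,thin fold-in sweep schedule.
#' @param seed RNG seed.
#' @param ... unused.
#' @return documents-by-topics proportion matrix.
#' @export
predict.lda_model <- function(object, newdata = NULL, n_iter = 200,
                              burn_in = 100, thin = 2, seed = 1L, ...) {
  if (is.null(newdata)) return(estimate_theta(object))
  toks <- if (inherits(newdata, "forum_corpus")) {
    if (is.null(newdata$tokens)) tokenize(newdata$posts$text) else newdata$tokens
  } else {
    newdata
  }
  docs <- lapply(toks, function(tok) {
    ids <- match(tok, object$vocabulary) - 1L
    ids[!is.na(ids)]
  })
  phi <- estimate_phi(object)
  set.seed(as.integer(seed))
  theta <- fold_in_cpp(docs, phi, object$params$alpha,
                       as.integer(n_iter), as.integer(burn_in),
                       as.integer(thin))
  theta
}

#' Simulate documents from a fitted topic model
#'
#' Draws new documents from the fitted generative process: per document a
#' topic mixture from `Dirichlet(alpha)`, then tokens topic-then-word from
#' the fitted topic-word distributions.
#'
#' @param object an `lda_model`.
#' @param nsim number of documents.
#' @param seed RNG seed.
#' @param length_mean mean document length in tokens.
#' @param ... unused.
#' @return list of character token vectors.
#' @export
simulate.lda_model <- function(object, nsim = 1, seed = NULL,
                               length_mean = 50, ...) {
  if (!is.null(seed)) set.seed(seed)
  phi <- estimate_phi(object)
  K <- nrow(phi)
  lapply(seq_len(nsim), function(i) {
    theta <- rdirichlet_one(rep(object$params$alpha, K))
    len <- max(1L, stats::rpois(1, length_mean))
    ks <- sample.int(K, len, replace = TRUE, prob = theta)
    vapply(ks, function(k) {
      object$vocabulary[sample.int(ncol(phi), 1, prob = phi[k, ])]
    }, character(1))
  })
}

#' @export
plot.lda_model <- function(x, topics = NULL, m = 8, ...) {
  tw <- top_words(x, m = min(m, length(x$vocabulary)))
  if (is.null(topics)) topics <- seq_len(min(length(tw), 4)) - 1L
  op <- graphics::par(mfrow = c(length(topics), 1),
                      mar = c(2, 8, 2, 1))
  on.exit(graphics::par(op))
  for (k in topics) {
    d <- tw[[k + 1]]
    graphics::barplot(rev(d$probability), names.arg = rev(d$term),
                      horiz = TRUE, las = 1,
                      main = paste("topic", k), ...)
  }
  invisible(x)
}
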