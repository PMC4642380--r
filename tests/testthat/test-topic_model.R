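test_that("degenerate K = 1 assigns every token to topic 0", {
  corpus <- tokenize_corpus(random_corpus(10, seed = 3))
  model <- fit_lda(corpus, K = 1, n_iter = 5, burn_in = 2, seed = 1)
  expect_true(all(model$z == 0))
  expect_equal(model$n_k[1], sum(lengths(corpus$tokens)))
  theta <- estimate_theta(model)
  expect_true(all(theta == 1))
})

test_that("same corpus and seed give bitwise-identical fits", {
  corpus <- tokenize_corpus(random_corpus(15, seed = 5))
  m1 <- fit_lda(corpus, K = 3, n_iter = 40, burn_in = 20, seed = 99)
  m2 <- fit_lda(corpus, K = 3, n_iter = 40, burn_in = 20, seed = 99)
  expect_identical(m1$z, m2$z)
  expect_identical(m1$n_kw, m2$n_kw)
  expect_identical(estimate_theta(m1), estimate_theta(m2))
  m3 <- fit_lda(corpus, K = 3, n_iter = 40, burn_in = 20, seed = 100)
  expect_false(identical(m1$z, m3$z))
})

test_that("count tables stay consistent with assignments throughout the run", {
  corpus <- tokenize_corpus(random_corpus(12, seed = 8))
  docs <- forumtopics:::token_ids(corpus)
  lens <- lengths(docs)
  for (iters in c(1, 3, 7)) {
    model <- fit_lda(corpus, K = 4, n_iter = iters, burn_in = 0,
                     thin = 1, seed = 2)
    expect_equal(rowSums(model$n_dk), unname(lens))
    expect_equal(rowSums(model$n_kw), as.numeric(model$n_k))
    expect_equal(sum(model$n_k), sum(lens))
    expect_true(all(model$n_dk >= 0) && all(model$n_kw >= 0))
    # counts must be exactly the tabulation of z
    doc_of <- rep(seq_along(docs), lens)
    n_dk <- t(vapply(seq_along(docs), function(d) {
      tabulate(model$z[doc_of == d] + 1L, 4L)
    }, integer(4)))
    expect_equal(unname(model$n_dk), n_dk)
    n_kw <- matrix(0L, 4, length(corpus$vocabulary))
    w <- unlist(docs) + 1L
    for (i in seq_along(w)) {
      n_kw[model$z[i] + 1L, w[i]] <- n_kw[model$z[i] + 1L, w[i]] + 1L
    }
    expect_equal(unname(model$n_kw), n_kw)
  }
})

test_that("theta and phi point estimates follow the smoothed-count formulas", {
  # hand-evaluated cases
  expect_equal(
    as.vector(forumtopics:::theta_from_counts(matrix(c(8, 0), 1), 0.5)),
    c(8.5 / 9, 0.5 / 9))
  expect_equal(
    as.vector(forumtopics:::phi_from_counts(matrix(c(3, 1, 0), 1), 4, 0.1)),
    c(3.1 / 4.3, 1.1 / 4.3, 0.1 / 4.3))

  # fitted model: rows are distributions, both averaged and final-state
  corpus <- tokenize_corpus(random_corpus(15, seed = 5))
  model <- fit_lda(corpus, K = 3, n_iter = 60, burn_in = 30, thin = 5,
                   seed = 4)
  for (avg in c(TRUE, FALSE)) {
    theta <- estimate_theta(model, average = avg)
    phi <- estimate_phi(model, average = avg)
    expect_equal(unname(rowSums(theta)), rep(1, nrow(theta)),
                 tolerance = 1e-9)
    expect_equal(unname(rowSums(phi)), rep(1, nrow(phi)), tolerance = 1e-9)
    expect_true(all(theta >= 0) && all(phi >= 0))
  }
})

test_that("empty documents are retained with a uniform topic row", {
  df <- make_posts_df(3, texts = c("vape coil juice vape", "", "coil coil"))
  corpus <- tokenize_corpus(forum_corpus(df))
  model <- fit_lda(corpus, K = 4, n_iter = 20, burn_in = 10, seed = 1)
  theta <- estimate_theta(model)
  expect_equal(nrow(theta), 3)
  expect_equal(unname(theta[2, ]), rep(0.25, 4))

  all_empty <- tokenize_corpus(forum_corpus(
    make_posts_df(2, texts = c("", ""))))
  expect_error(fit_lda(all_empty, K = 2, n_iter = 5, burn_in = 1),
               "empty")
  expect_error(fit_lda(corpus, K = 0, n_iter = 5, burn_in = 1),
               "positive integer")
})

test_that("top_words ranks by probability with vocabulary-order tie-break", {
  phi <- matrix(1 / 4, 2, 4,
                dimnames = list(NULL, c("aa", "bb", "cc", "dd")))
  tw <- top_words(phi, m = 2)
  expect_equal(tw[[1]]$term, c("aa", "bb"))
  expect_equal(tw[[2]]$term, c("aa", "bb"))

  phi2 <- matrix(c(0.7, 0.2, 0.1), 1, dimnames = list(NULL, c("x", "y", "z")))
  expect_equal(top_words(phi2, m = 1)[[1]]$term, "x")
  expect_error(top_words(phi2, m = 4), "exceeds vocabulary")

  # sort oracle on a random phi
  set.seed(9)
  phi3 <- random_theta(5, 40)
  colnames(phi3) <- sprintf("w%02d", 1:40)
  tw3 <- top_words(phi3, m = 40)
  for (k in 1:5) {
    oracle <- colnames(phi3)[order(-phi3[k, ], seq_len(40))]
    expect_identical(tw3[[k]]$term, oracle)
    expect_equal(tw3[[k]]$probability, unname(phi3[k, oracle]))
  }
})

test_that("permuting topic labels leaves the proportion multiset invariant", {
  corpus <- tokenize_corpus(random_corpus(15, seed = 6))
  model <- fit_lda(corpus, K = 4, n_iter = 30, burn_in = 15, seed = 3)
  theta <- estimate_theta(model, average = FALSE)
  perm <- c(3, 1, 4, 2)
  theta_perm <- forumtopics:::theta_from_counts(
    model$n_dk[, perm], model$params$alpha)
  expect_equal(unname(theta_perm), unname(theta[, perm]))
  expect_equal(sort(as.vector(theta_perm)), sort(as.vector(theta)))
})

test_that("restarted chains are selected by collapsed log-likelihood", {
  corpus <- tokenize_corpus(random_corpus(20, seed = 12))
  single <- lapply(0:2, function(off) {
    fit_lda(corpus, K = 3, n_iter = 30, burn_in = 15, seed = 50 + off)
  })
  lls <- vapply(single, function(m) as.numeric(logLik(m)), numeric(1))
  multi <- fit_lda(corpus, K = 3, n_iter = 30, burn_in = 15, seed = 50,
                   n_chains = 3)
  expect_equal(as.numeric(logLik(multi)), max(lls))
  best <- single[[which.max(lls)]]
  expect_identical(multi$z, best$z)
  expect_equal(multi$params$chain_seed, best$params$chain_seed)
  # multi-chain fits remain deterministic
  multi2 <- fit_lda(corpus, K = 3, n_iter = 30, burn_in = 15, seed = 50,
                    n_chains = 3)
  expect_identical(multi$z, multi2$z)
})

test_that("model methods print, summarise, predict and export", {
  corpus <- tokenize_corpus(random_corpus(15, seed = 5))
  model <- fit_lda(corpus, K = 2, n_iter = 40, burn_in = 20, seed = 7)
  expect_output(print(model), "collapsed Gibbs")
  expect_output(print(summary(model, m = 3)), "topic 0")
  expect_equal(dim(coef(model)),
               c(2, length(corpus$vocabulary)))

  # fold-in on the training documents: proper rows
  theta_new <- predict(model, corpus, n_iter = 50, burn_in = 25, seed = 1)
  expect_equal(unname(rowSums(theta_new)), rep(1, n_posts(corpus)),
               tolerance = 1e-9)

  sims <- simulate(model, nsim = 3, seed = 2, length_mean = 20)
  expect_length(sims, 3)
  expect_true(all(unlist(sims) %in% corpus$vocabulary))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_top_words(model, tsv, m = 5)
  rep <- utils::read.delim(tsv)
  expect_equal(nrow(rep), 10)
  expect_named(rep, c("topic", "rank", "term", "probability"))

  # theta export is readable by the doc-topics reader
  dt <- withr::local_tempfile(fileext = ".tsv")
  write_doc_topics(estimate_theta(model), dt)
  expect_equal(unname(read_doc_topics(dt, K = 2)),
               unname(estimate_theta(model)), tolerance = 1e-9)
})
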