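#' Configuration for the synthetic forum-corpus generator
#'
#' Describes a forum-scale corpus drawn from a known topic-mixture generative
#' process. Post lengths follow a log-normal distribution parameterised by
#' its mean and standard deviation on the token scale; the defaults (mean
#' 189, SD 378 tokens) echo the scale of a short-post discussion forum while
#' keeping simulated corpora small. Topics are drawn once per corpus from a
#' symmetric Dirichlet over an abstract vocabulary (`w0001`, `w0002`, ...);
#' each post draws its own sparse topic mixture.
#'
#' @param n_posts number of posts, `>= 1`.
#' @param K_true number of topics.
#' @param V vocabulary size, `>= K_true`.
#' @param alpha_true per-post topic Dirichlet concentration (small values
#'   give posts dominated by one topic).
#' @param beta_true topic-word Dirichlet concentration (small values give
#'   well-separated topics).
#' @param length_mean,length_sd mean and SD of the log-normal post-length
#'   distribution, in tokens (minimum length 1).
#' @param injection named numeric vector: lexicon category -> target
#'   prevalence in `[0, 1]`, applied by [simulate_corpus()] when lexicons are
#'   supplied.
#' @param forum_id forum identifier stamped on the posts.
#' @param seed integer RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_posts = 500, K_true = 5, V = 200,
                       alpha_true = 0.1, beta_true = 0.05,
                       length_mean = 189, length_sd = 378,
                       injection = NULL, forum_id = "synthetic",
                       seed = 1L) {
  if (n_posts < 1) stop("n_posts must be >= 1")
  if (V < K_true) stop("V must be at least K_true")
  if (alpha_true <= 0 || beta_true <= 0) {
    stop("alpha_true and beta_true must be positive")
  }
  if (!is.null(injection)) {
    if (is.null(names(injection)) || any(!nzchar(names(injection)))) {
      stop("injection must be a named vector (category -> prevalence)")
    }
    if (any(injection < 0 | injection > 1)) {
      stop("injection prevalences must lie in [0, 1]")
    }
  }
  structure(list(n_posts = as.integer(n_posts), K_true = as.integer(K_true),
                 V = as.integer(V), alpha_true = alpha_true,
                 beta_true = beta_true, length_mean = length_mean,
                 length_sd = length_sd, injection = injection,
                 forum_id = forum_id, seed = as.integer(seed)),
            class = "sim_config")
}

# one draw from Dirichlet(alpha_vec)
rdirichlet_one <- function(alpha_vec) {
  g <- stats::rgamma(length(alpha_vec), shape = alpha_vec, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha_vec))
  g / sum(g)
}

#' Simulate a forum corpus with known topic structure
#'
#' Draws a corpus from the topic-mixture generative process: per-topic word
#' distributions `phi_true` from a symmetric Dirichlet(`beta_true`), then per
#' post a topic mixture `theta_true` from Dirichlet(`alpha_true`), a
#' log-normal token count (minimum 1), and tokens topic-then-word. When
#' `cfg$injection` names lexicon categories and `lexicons` is supplied, the
#' corresponding terms are injected at the exact target prevalence via
#' [inject_lexicon_terms()]. The returned corpus is tokenized (no stop list;
#' the abstract vocabulary contains no stop words).
#'
#' @param cfg a [sim_config()].
#' @param lexicons named list of [lexicon()] objects; required when
#'   `cfg$injection` is set.
#' @return list with elements `corpus` (a tokenized [forum_corpus()]) and
#'   `truth` (class `sim_truth`: `theta_true` posts-by-topics, `phi_true`
#'   topics-by-vocabulary with term column names, `doc_lengths`,
#'   `dominant_topic`, `topic_token_share` — the realised fraction of tokens
#'   drawn from each topic — and `injected_flags`, a posts-by-categories
#'   logical matrix).
#'   Identical seeds give identical output.
#' @export
simulate_corpus <- function(cfg, lexicons = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  vocab <- sprintf("w%0*d", max(4, nchar(cfg$V)), seq_len(cfg$V))
  phi_true <- t(vapply(seq_len(cfg$K_true),
                       function(k) rdirichlet_one(rep(cfg$beta_true, cfg$V)),
                       numeric(cfg$V)))
  colnames(phi_true) <- vocab

  # log-normal parameterised by token-scale mean and sd
  sigma2 <- log(1 + (cfg$length_sd / cfg$length_mean)^2)
  mu <- log(cfg$length_mean) - sigma2 / 2
  lens <- pmax(1L, as.integer(round(
    stats::rlnorm(cfg$n_posts, meanlog = mu, sdlog = sqrt(sigma2)))))

  theta_true <- matrix(0, cfg$n_posts, cfg$K_true)
  texts <- character(cfg$n_posts)
  topic_tokens <- numeric(cfg$K_true)
  for (d in seq_len(cfg$n_posts)) {
    theta <- rdirichlet_one(rep(cfg$alpha_true, cfg$K_true))
    theta_true[d, ] <- theta
    ks <- sample.int(cfg$K_true, lens[d], replace = TRUE, prob = theta)
    topic_tokens <- topic_tokens + tabulate(ks, cfg$K_true)
    words <- vapply(ks, function(k) {
      vocab[sample.int(cfg$V, 1L, prob = phi_true[k, ])]
    }, character(1))
    texts[d] <- paste(words, collapse = " ")
  }

  width <- max(6, nchar(cfg$n_posts))
  posts <- data.frame(
    forum_id = cfg$forum_id,
    thread_id = paste0("t", formatC((seq_len(cfg$n_posts) - 1L) %/% 20 + 1L,
                                    width = 4, flag = "0")),
    post_id = sprintf("p%0*d", width, seq_len(cfg$n_posts)),
    author = sprintf("user%03d", (seq_len(cfg$n_posts) - 1L) %% 97 + 1L),
    timestamp = "",
    text = texts,
    stringsAsFactors = FALSE)
  corpus <- forum_corpus(posts, cfg$forum_id)

  inj_cats <- names(cfg$injection)
  injected <- matrix(FALSE, cfg$n_posts, length(inj_cats),
                     dimnames = list(NULL, inj_cats))
  if (length(inj_cats) > 0) {
    if (is.null(lexicons)) {
      stop("cfg$injection is set but no lexicons were supplied")
    }
    for (cat in inj_cats) {
      lex <- lexicons[[cat]]
      if (is.null(lex)) stop("no lexicon for injection category '", cat, "'")
      res <- inject_lexicon_terms(corpus, lex, cfg$injection[[cat]],
                                  seed = cfg$seed + match(cat, inj_cats))
      corpus <- res$corpus
      injected[, cat] <- res$injected_flags
    }
  }
  corpus <- tokenize_corpus(corpus, character(0))

  truth <- structure(list(theta_true = theta_true, phi_true = phi_true,
                          doc_lengths = lens,
                          dominant_topic = max.col(theta_true, "first"),
                          topic_token_share = topic_tokens / sum(topic_tokens),
                          injected_flags = injected),
                     class = "sim_truth")
  list(corpus = corpus, truth = truth)
}

#' Inject lexicon terms into a corpus at an exact prevalence
#'
#' Appends one uniformly chosen lexicon term to each of exactly
#' `round(p * n_posts)` distinct posts, chosen without replacement. Posts
#' that already contain a lexicon term naturally are counted into the quota,
#' so the resulting [prevalence()] equals `round(p * n) / n` exactly — the
#' injection is count-based, not Bernoulli. The token layer of the corpus is
#' cleared (the text changed); re-run [tokenize_corpus()] if needed.
#'
#' @param corpus a [forum_corpus()].
#' @param lex a non-empty [lexicon()].
#' @param p target prevalence in `[0, 1]`.
#' @param seed RNG seed for the choice of posts and terms.
#' @return list: `corpus` (modified), `injected_flags` (logical per post:
#'   post contains a lexicon term after injection).
#' @export
inject_lexicon_terms <- function(corpus, lex, p, seed = 1L) {
  stopifnot(inherits(corpus, "forum_corpus"),
            inherits(lex, "factor_lexicon"))
  if (length(lex$terms) == 0) stop("lexicon '", lex$category, "' is empty")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  n <- n_posts(corpus)
  quota <- round(p * n)
  natural <- which(post_matches(corpus$posts$text, lex))
  if (length(natural) > quota) {
    stop("cannot reach prevalence ", p, ": ", length(natural),
         " posts already match lexicon '", lex$category,
         "' but the quota is ", quota)
  }
  need <- quota - length(natural)
  set.seed(as.integer(seed))
  candidates <- setdiff(seq_len(n), natural)
  chosen <- if (need > 0) sample(candidates, need) else integer(0)
  if (length(chosen) > 0) {
    terms <- sample(lex$terms, length(chosen), replace = TRUE)
    corpus$posts$text[chosen] <- ifelse(
      nzchar(corpus$posts$text[chosen]),
      paste(corpus$posts$text[chosen], terms),
      terms)
  }
  corpus$tokens <- NULL
  corpus$vocabulary <- NULL
  flags <- logical(n)
  flags[c(natural, chosen)] <- TRUE
  list(corpus = corpus, injected_flags = flags)
}

#' Greedily match fitted topics to reference topics
#'
#' Pairs each reference topic with a distinct fitted topic by repeatedly
#' taking the globally closest (smallest L1 distance) unmatched pair of
#' topic-word rows. Columns are aligned by term name; terms absent from
#' either matrix contribute their full probability to the distance.
#'
#' @param phi_hat fitted topics-by-vocabulary matrix (named columns).
#' @param phi_ref reference topics-by-vocabulary matrix (named columns).
#' @return integer vector `perm` of length `nrow(phi_ref)`: fitted topic
#'   `perm[j]` is matched to reference topic `j`. Attribute `"l1"` holds the
#'   per-pair L1 distances.
#' @export
match_topics <- function(phi_hat, phi_ref) {
  terms <- union(colnames(phi_hat), colnames(phi_ref))
  pad <- function(m) {
    out <- matrix(0, nrow(m), length(terms), dimnames = list(NULL, terms))
    out[, colnames(m)] <- m
    out
  }
  A <- pad(phi_hat); B <- pad(phi_ref)
  Kh <- nrow(A); Kr <- nrow(B)
  d <- matrix(0, Kh, Kr)
  for (i in seq_len(Kh)) {
    for (j in seq_len(Kr)) d[i, j] <- sum(abs(A[i, ] - B[j, ]))
  }
  perm <- integer(Kr)
  l1 <- numeric(Kr)
  free_h <- rep(TRUE, Kh); free_r <- rep(TRUE, Kr)
  for (step in seq_len(min(Kh, Kr))) {
    sub <- d
    sub[!free_h, ] <- Inf
    sub[, !free_r] <- Inf
    idx <- arrayInd(which.min(sub), dim(sub))
    perm[idx[2]] <- idx[1]
    l1[idx[2]] <- d[idx[1], idx[2]]
    free_h[idx[1]] <- FALSE
    free_r[idx[2]] <- FALSE
  }
  attr(perm, "l1") <- l1
  perm
}
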