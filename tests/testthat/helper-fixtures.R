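# shared fixture builders; everything is generated in code

make_posts_df <- function(n = 3, forum_id = "forumA",
                          texts = NULL) {
  if (n == 0) {
    return(data.frame(forum_id = character(0), thread_id = character(0),
                      post_id = character(0), author = character(0),
                      timestamp = character(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(texts)) {
    texts <- paste("post number", seq_len(n), "about vaping and quitting")
  }
  data.frame(
    forum_id = forum_id,
    thread_id = paste0("t", (seq_len(n) - 1) %/% 2 + 1),
    post_id = paste0("p", seq_len(n)),
    author = paste0("user", seq_len(n)),
    timestamp = paste0("2014-05-0", (seq_len(n) - 1) %% 9 + 1, "T12:00:00Z"),
    text = texts,
    stringsAsFactors = FALSE)
}

make_corpus <- function(n = 3, forum_id = "forumA", texts = NULL) {
  forum_corpus(make_posts_df(n, forum_id, texts))
}

# a corpus whose texts are draws over a tiny fixed vocabulary
random_corpus <- function(n = 20, forum_id = "rand", seed = 1) {
  set.seed(seed)
  vocab <- c("vape", "coil", "juice", "throat", "quit", "craving",
             "morning", "cheap", "cloud", "friend")
  texts <- vapply(seq_len(n), function(i) {
    paste(sample(vocab, sample(3:12, 1), replace = TRUE), collapse = " ")
  }, character(1))
  make_corpus(n, forum_id, texts)
}

shipped_lexicons <- function() {
  load_lexicons(system.file("extdata", "lexicons.csv",
                            package = "forumtopics"))
}

# random proper theta matrix (rows sum to 1)
random_theta <- function(n_doc, K, alpha = 0.5) {
  t(vapply(seq_len(n_doc), function(i) {
    g <- stats::rgamma(K, alpha)
    if (sum(g) == 0) g <- rep(1, K)
    g / sum(g)
  }, numeric(K)))
}
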