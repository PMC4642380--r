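test_that("lexicon CSVs load with dedup and validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("category,group,term",
               "e-cigarette,subject matter,atty",
               "e-cigarette,subject matter,vape",
               "e-cigarette,subject matter,atty"), path)
  lx <- load_lexicons(path)
  expect_length(lx, 1)
  expect_setequal(lx[["e-cigarette"]]$terms, c("atty", "vape"))

  writeLines("category,group,term", path)
  expect_length(load_lexicons(path), 0)

  expect_error(lexicon("x", "bogus group", "term"), "unknown group")
  expect_error(lexicon("x", "health", c("ok", "")), "empty term")

  shipped <- shipped_lexicons()
  expect_length(shipped, 11)
  expect_true("atty" %in% shipped[["e-cigarette"]]$terms)
})

test_that("post_matches is boundary-aware, case-insensitive, multiword-capable", {
  ecig <- lexicon("e-cigarette", "subject matter", c("atty", "e-cig"))
  expect_true(post_matches("my atty burnt out", ecig))
  expect_true(post_matches("My ATTY burnt out!", ecig))
  expect_false(post_matches("attyx is broken", ecig))
  expect_false(post_matches("battery died", ecig))

  quitting <- lexicon("quitting", "health", "cold turkey")
  expect_true(post_matches("went cold turkey yesterday", quitting))
  expect_true(post_matches("went Cold, Turkey yesterday", quitting))
  expect_false(post_matches("the cold made the turkey tough", quitting))

  empty <- lexicon("empty", "context", character(0))
  expect_false(post_matches("anything at all", empty))
  expect_equal(post_matches(character(0), ecig), logical(0))

  # stop-like terms still match: prevalence runs on raw text
  sensory <- lexicon("sensory experience", "context", "hit")
  expect_true(post_matches("that hit was smooth", sensory))
})

test_that("prevalence is the proportion of posts containing a lexicon term", {
  ecig <- lexicon("e-cigarette", "subject matter", c("vape", "atty"))
  corpus <- make_corpus(4, texts = c("i vape daily", "my atty died",
                                     "plain post", "another plain post"))
  m <- prevalence(list(corpus), list(ecig))
  expect_equal(m["forumA", "e-cigarette"], 0.5)
  expect_true(all(m >= 0 & m <= 1))

  all_match <- make_corpus(3, texts = rep("vape vape", 3))
  expect_equal(prevalence(list(all_match), list(ecig))[1, 1], 1)

  empty_lex <- lexicon("none", "context", character(0))
  expect_equal(prevalence(list(corpus), list(empty_lex))[1, 1], 0)

  # a post with several matching terms still counts once
  multi <- make_corpus(2, texts = c("vape atty vape", "nothing"))
  expect_equal(prevalence(list(multi), list(ecig))[1, 1], 0.5)

  empty_corpus <- forum_corpus(make_posts_df(0, forum_id = "ghost"),
                               forum_id = "ghost")
  expect_error(prevalence(list(empty_corpus), list(ecig)), "ghost")
})

test_that("adding a term to a lexicon never decreases prevalence", {
  set.seed(11)
  corpora <- lapply(1:3, function(i) random_corpus(25, paste0("f", i),
                                                   seed = i))
  base_terms <- c("vape", "coil")
  extra <- c("juice", "throat", "quit", "cloud")
  m_prev <- prevalence(corpora, list(lexicon("x", "context", base_terms)))
  for (k in seq_along(extra)) {
    m_next <- prevalence(corpora, list(
      lexicon("x", "context", c(base_terms, extra[seq_len(k)]))))
    expect_true(all(m_next >= m_prev))
    m_prev <- m_next
  }
})

test_that("heat-map colour scale is monotone with absolute [0, max] scaling", {
  m <- matrix(c(0, 0.15, 0.3, 0.6), 2, 2,
              dimnames = list(c("f1", "f2"), c("c1", "c2")))
  cols <- forumtopics:::prevalence_colors(m, c("#F7FBFF", "#08306B"))
  lightness <- function(col) sum(grDevices::col2rgb(col))
  # value 0 -> lightest hue, max value -> darkest hue
  expect_equal(cols[1, 1], "#F7FBFF")
  expect_equal(cols[2, 2], "#08306B")
  lums <- apply(cols, c(1, 2), lightness)
  expect_true(all(order(-as.vector(lums)) == order(as.vector(m))))

  # degenerate all-zero matrix stays at the light end
  cols0 <- forumtopics:::prevalence_colors(matrix(0, 1, 1))
  expect_equal(cols0[1, 1], "#F7FBFF")
})

test_that("heat map files are written for png and svg", {
  m <- matrix(runif(6), 2, 3,
              dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  class(m) <- c("prevalence_matrix", class(m))
  for (ext in c(".png", ".svg")) {
    path <- withr::local_tempfile(fileext = ext)
    render_heatmap(m, path)
    expect_true(file.exists(path))
    expect_gt(file.size(path), 0)
  }
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_prevalence(m, tsv)
  back <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(m),
               ignore_attr = TRUE, tolerance = 1e-12)
})
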