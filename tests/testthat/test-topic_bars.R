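test_that("document-topics are the (doc, topic) pairs at or above the threshold", {
  theta <- rbind(c(0.6, 0.4), c(0.5, 0.5), c(1.0, 0.0))
  expect_equal(nrow(count_document_topics(theta[1, , drop = FALSE], 0.3)$pairs), 2)
  expect_equal(nrow(count_document_topics(theta[1, , drop = FALSE], 0.5)$pairs), 1)
  # closed threshold: 0.5 counts at 0.5
  expect_equal(nrow(count_document_topics(theta[2, , drop = FALSE], 0.5)$pairs), 2)
  # strictly mixed rows give no pairs at threshold 1
  expect_equal(nrow(count_document_topics(theta[1:2, , drop = FALSE], 1)$pairs), 0)
  expect_equal(nrow(count_document_topics(theta, 1)$pairs), 1)
  expect_error(count_document_topics(theta, 0), "\\(0, 1\\]")
  expect_error(count_document_topics(theta, 1.2), "\\(0, 1\\]")
})

test_that("document-topic count is non-increasing in the threshold", {
  set.seed(21)
  for (rep in 1:100) {
    theta <- random_theta(sample(2:20, 1), sample(2:6, 1),
                          alpha = runif(1, 0.1, 2))
    grid <- sort(runif(8, 0.01, 1))
    counts <- vapply(grid, function(tr) {
      nrow(count_document_topics(theta, tr)$pairs)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  # limits: tiny threshold approaches n * K, threshold 1 at most n
  theta <- random_theta(10, 4)
  expect_equal(nrow(count_document_topics(theta, 1e-12)$pairs), 40)
  expect_lte(nrow(count_document_topics(theta, 1)$pairs), 10)
})

test_that("threshold calibration minimises |document-topics - posts|, ties go up", {
  # every document 100% one topic: all candidates give exactly n pairs
  theta_pure <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(calibrate_threshold(theta_pure, c(0.2, 0.5, 0.9)), 0.9)

  # worked tie case: 5 pairs at 0.3 vs 1 pair at 0.6, both off by 2
  theta <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(1.0, 0.0))
  expect_equal(calibrate_threshold(theta, c(0.3, 0.6)), 0.6)

  expect_error(calibrate_threshold(theta, numeric(0)), "empty")
  expect_error(calibrate_threshold(theta, c(0.5, 1.5)), "\\(0, 1\\]")

  # exhaustive-grid oracle on random matrices
  set.seed(31)
  grid <- seq(0.05, 0.95, by = 0.05)
  for (rep in 1:25) {
    theta <- random_theta(sample(5:40, 1), sample(2:8, 1))
    chosen <- calibrate_threshold(theta, grid)
    dev <- vapply(grid, function(tr) {
      abs(nrow(count_document_topics(theta, tr)$pairs) - nrow(theta))
    }, numeric(1))
    expect_true(chosen %in% grid)
    expect_equal(dev[match(chosen, grid)], min(dev))
    expect_equal(chosen, max(grid[dev == min(dev)]))
  }
})

test_that("topic proportions divide per-topic counts by total document-topics", {
  # symmetric case
  theta <- diag(4)
  dts <- count_document_topics(theta, 0.5)
  expect_equal(unname(topic_proportions(dts)), rep(0.25, 4))
  expect_equal(sum(topic_proportions(dts)), 1)

  empty <- count_document_topics(rbind(c(0.5, 0.5)), 0.9)
  expect_error(topic_proportions(empty), "no document-topics")
})

test_that("category grouping preserves mass and flags unmapped topics", {
  frac <- stats::setNames(c(0.2, 0.3, 0.5), c("0", "1", "2"))

  ident <- topic_category_map(c("0", "1", "2"), c("c0", "c1", "c2"))
  expect_equal(unname(category_proportions(frac, ident)),
               unname(frac))

  all_one <- topic_category_map(c("0", "1", "2"), rep("everything", 3))
  expect_equal(unname(category_proportions(frac, all_one)), 1)

  ab <- topic_category_map(c("0", "1", "2"), c("A", "A", "B"))
  got <- category_proportions(frac, ab)
  expect_equal(got, c(A = 0.5, B = 0.5))
  expect_equal(sum(got), 1)

  partial <- topic_category_map(c("0", "1"), c("A", "A"))
  expect_error(category_proportions(frac, partial), "2")

  # zero-share topics may be unmapped
  frac0 <- stats::setNames(c(0.4, 0.6, 0), c("0", "1", "2"))
  expect_equal(sum(category_proportions(frac0, partial)), 1)
})

test_that("topic-category maps round-trip through CSV with colours", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("topic_id,category,color",
               "0,Psychology,#1b9e77",
               "1,Psychology,#1b9e77",
               "2,Quitting Methods,#d95f02"), path)
  map <- read_topic_category_map(path)
  expect_equal(unname(map$topic_category),
               c("Psychology", "Psychology", "Quitting Methods"))
  expect_equal(map$colors[["Quitting Methods"]], "#d95f02")
  expect_error(topic_category_map(c("0", "0"), c("a", "b")), "duplicate")
})

test_that("topic-bar segments are proportional and figures render", {
  seg <- forumtopics:::topic_bar_segments(c(A = 0.6, B = 0.4))
  expect_equal(seg$width[1] / seg$width[2], 1.5)
  expect_equal(seg$left, c(0, 0.6))
  expect_equal(seg$right, c(0.6, 1))

  rows <- list(forum1 = c(A = 0.6, B = 0.4),
               forum2 = c(A = 0.2, B = 0.5, C = 0.3))
  for (ext in c(".png", ".svg")) {
    path <- withr::local_tempfile(fileext = ext)
    render_topic_bars(rows, path)
    expect_true(file.exists(path) && file.size(path) > 0)
  }
  single <- withr::local_tempfile(fileext = ".png")
  render_topic_bars(list(only = c(everything = 1)), single)
  expect_true(file.exists(single))
  expect_error(render_topic_bars(list(), "x.png"), "at least one")
})
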