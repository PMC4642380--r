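#' Collect document-topics above a threshold
#'
#' A topic is a *major constituent* of a document when its estimated
#' proportion in that document reaches a minimum threshold; each such
#' (document, topic) pair is one *document-topic*. The comparison is closed
#' (`>=`). Documents whose proportions never reach the threshold contribute
#' no pairs.
#'
#' @param theta documents-by-topics proportion matrix.
#' @param threshold minimum proportion, in `(0, 1]`.
#' @return an object of class `document_topic_set`: `threshold`, `pairs`
#'   (data frame with zero-based `doc` and `topic` columns), `n_documents`
#'   and `K`.
#' @export
count_document_topics <- function(theta, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single number in (0, 1]")
  }
  hit <- which(theta >= threshold, arr.ind = TRUE)
  pairs <- data.frame(doc = as.integer(hit[, 1]) - 1L,
                      topic = as.integer(hit[, 2]) - 1L)
  pairs <- pairs[order(pairs$doc, pairs$topic), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(threshold = threshold, pairs = pairs,
                 n_documents = nrow(theta), K = ncol(theta)),
            class = "document_topic_set")
}

#' @export
print.document_topic_set <- function(x, ...) {
  cat(sprintf("<document_topic_set> threshold %.2f: %d document-topics over %d documents\n",
              x$threshold, nrow(x$pairs), x$n_documents))
  invisible(x)
}

#' Calibrate the document-topic threshold
#'
#' Scans a candidate grid and returns the threshold whose document-topic
#' count is closest to the number of documents — the calibration that keeps
#' roughly one major topic per post, maximising the share of content that is
#' represented without flooding the summary with trace topics. Ties are
#' broken toward the larger (stricter) threshold.
#'
#' @param theta documents-by-topics proportion matrix.
#' @param grid ordered candidate thresholds in `(0, 1]`; default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @return the selected threshold (an element of `grid`).
#' @export
calibrate_threshold <- function(theta, grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(grid) == 0) stop("candidate grid is empty")
  if (any(grid <= 0 | grid > 1)) stop("grid candidates must lie in (0, 1]")
  n_doc <- nrow(theta)
  counts <- vapply(grid, function(tr) sum(theta >= tr), numeric(1))
  dev <- abs(counts - n_doc)
  best <- which(dev == min(dev))
  grid[best[which.max(grid[best])]]
}

#' Per-topic share of document-topics
#'
#' The forum-level summary statistic: the number of document-topic elements
#' for each topic divided by the total number of document-topic elements.
#'
#' @param dts a [count_document_topics()] result.
#' @param K number of topics; defaults to the set's `K`.
#' @return numeric vector of length `K` summing to 1, names `"0".."K-1"`.
#' @export
topic_proportions <- function(dts, K = dts$K) {
  stopifnot(inherits(dts, "document_topic_set"))
  n <- nrow(dts$pairs)
  if (n == 0) stop("no document-topics at threshold ", dts$threshold,
                   "; proportions undefined")
  counts <- tabulate(dts$pairs$topic + 1L, nbins = K)
  stats::setNames(counts / n, as.character(seq_len(K) - 1L))
}

#' Aggregate topic proportions into thematic categories
#'
#' Topics judged thematically similar are grouped into categories via a
#' user-supplied map; a category's share is the sum of its member topics'
#' shares. Every topic carrying non-zero share must be mapped.
#'
#' @param topic_fractions named vector from [topic_proportions()].
#' @param map a [topic_category_map()] (or bare named character vector
#'   `topic id -> category`).
#' @return named numeric vector of category fractions, in map category
#'   order, summing to 1.
#' @export
category_proportions <- function(topic_fractions, map) {
  if (inherits(map, "topic_category_map")) {
    categories <- map$categories
    map <- map$topic_category
  } else {
    categories <- unique(unname(map))
  }
  ids <- names(topic_fractions)
  unmapped <- ids[!(ids %in% names(map)) & topic_fractions > 0]
  if (length(unmapped) > 0) {
    stop("topic(s) with non-zero share are not mapped to a category: ",
         paste(unmapped, collapse = ", "))
  }
  out <- stats::setNames(numeric(length(categories)), categories)
  for (id in ids) {
    if (topic_fractions[[id]] == 0 && !(id %in% names(map))) next
    out[[map[[id]]]] <- out[[map[[id]]]] + topic_fractions[[id]]
  }
  out
}

#' Topic-to-category map
#'
#' @param topic_ids topic ids (coerced to character).
#' @param categories category name per topic.
#' @param colors optional display colour per *category* (named, or in the
#'   order categories first appear); defaults to a qualitative palette.
#' @return object of class `topic_category_map` with elements
#'   `topic_category` (named character), `categories` (unique, in first
#'   appearance order) and `colors` (named by category).
#' @export
topic_category_map <- function(topic_ids, categories, colors = NULL) {
  topic_ids <- as.character(topic_ids)
  categories <- as.character(categories)
  stopifnot(length(topic_ids) == length(categories))
  if (any(!nzchar(categories))) stop("category names must be non-empty")
  if (anyDuplicated(topic_ids)) stop("duplicate topic id in map")
  cats <- unique(categories)
  if (is.null(colors)) {
    colors <- grDevices::hcl.colors(max(3, length(cats)), "Dark 3")[
      seq_along(cats)]
    names(colors) <- cats
  } else if (is.null(names(colors))) {
    stopifnot(length(colors) >= length(cats))
    colors <- stats::setNames(colors[seq_along(cats)], cats)
  }
  structure(list(topic_category = stats::setNames(categories, topic_ids),
                 categories = cats, colors = colors),
            class = "topic_category_map")
}

#' Read a topic-to-category map from CSV
#'
#' Columns: `topic_id`, `category`, optional `color` (hex, constant within a
#' category).
#'
#' @param path CSV file.
#' @return a [topic_category_map()].
#' @export
read_topic_category_map <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  for (col in c("topic_id", "category")) {
    if (is.null(df[[col]])) stop("map file is missing column '", col, "'")
  }
  colors <- NULL
  if (!is.null(df$color)) {
    first <- !duplicated(df$category)
    colors <- stats::setNames(df$color[first], df$category[first])
  }
  topic_category_map(df$topic_id, df$category, colors)
}

#' Render the Topic Bars figure
#'
#' One horizontal stacked bar per forum, all bars spanning the same total
#' width; segment widths are proportional to the category fractions and
#' segments share colours across forums, so topic prevalence can be compared
#' within and between discussion forums at a glance. A legend maps colours to
#' categories.
#'
#' @param rows named list: forum id -> named category-fraction vector
#'   ([category_proportions()] output). Forums may have different category
#'   sets; shared categories share colours.
#' @param colors named colours per category; defaults to a qualitative
#'   palette over the union of categories.
#' @param out_path output figure (`.png` or `.svg`).
#' @return `out_path`, invisibly.
#' @export
render_topic_bars <- function(rows, out_path, colors = NULL) {
  if (length(rows) == 0) stop("need at least one forum row")
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    names(rows) <- paste0("forum", seq_along(rows))
  }
  all_cats <- unique(unlist(lapply(rows, names)))
  if (is.null(colors)) {
    colors <- stats::setNames(
      grDevices::hcl.colors(max(3, length(all_cats)), "Dark 3")[
        seq_along(all_cats)], all_cats)
  }
  open_device(out_path, width = 8, height = 1.2 + 0.8 * length(rows))
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(3, 8, 1, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  nf <- length(rows)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, nf + 1.2), axes = FALSE,
                 xlab = "", ylab = "", xaxs = "i", yaxs = "i")
  for (i in seq_len(nf)) {
    frac <- rows[[i]]
    frac <- frac / sum(frac)  # guard against rounding drift
    edges <- c(0, cumsum(frac))
    y0 <- nf - i + 0.3
    for (j in seq_along(frac)) {
      graphics::rect(edges[j], y0, edges[j + 1], y0 + 0.6,
                     col = colors[[names(frac)[j]]], border = "white")
    }
    graphics::mtext(names(rows)[i], side = 2, at = y0 + 0.3, las = 1,
                    line = 0.5, cex = 0.85)
  }
  graphics::axis(1, at = seq(0, 1, 0.25),
                 labels = paste0(seq(0, 100, 25), "%"), cex.axis = 0.8)
  graphics::legend("top", legend = all_cats, fill = colors[all_cats],
                   horiz = FALSE, ncol = min(4, length(all_cats)),
                   bty = "n", cex = 0.75)
  invisible(out_path)
}

# segment geometry used by the renderer, exposed for auditability: cumulative
# [left, right) intervals per category on the unit bar
topic_bar_segments <- function(fractions) {
  frac <- fractions / sum(fractions)
  edges <- c(0, cumsum(frac))
  data.frame(category = names(fractions),
             left = edges[-length(edges)], right = edges[-1],
             width = as.numeric(frac), stringsAsFactors = FALSE)
}
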