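#' Construct a forum corpus
#'
#' A `forum_corpus` holds the posts of one discussion forum, one document per
#' post. Posts carry the metadata retained for analysis (thread, post id,
#' author, timestamp) plus the free text; the token layer (`tokens`,
#' `vocabulary`) is empty until [tokenize_corpus()] is applied.
#'
#' @param posts data frame with columns `forum_id`, `thread_id`, `post_id`,
#'   `author`, `timestamp`, `text`. Missing optional columns are added empty;
#'   `forum_id`, `post_id` and `text` are required.
#' @param forum_id forum identifier; defaults to the single id found in
#'   `posts$forum_id`.
#' @return an object of class `forum_corpus`: a list with elements `forum_id`,
#'   `posts` (data frame), `tokens` (list of character vectors or `NULL`) and
#'   `vocabulary` (character vector or `NULL`; token ids are zero-based
#'   positions in this vector).
#' @export
forum_corpus <- function(posts, forum_id = NULL) {
  required <- c("forum_id", "post_id", "text")
  missing_req <- setdiff(required, names(posts))
  if (length(missing_req) > 0) {
    stop("posts is missing required column(s): ",
         paste(missing_req, collapse = ", "))
  }
  for (opt in c("thread_id", "author", "timestamp")) {
    if (is.null(posts[[opt]])) posts[[opt]] <- rep("", nrow(posts))
  }
  posts <- posts[, c("forum_id", "thread_id", "post_id", "author",
                     "timestamp", "text"), drop = FALSE]
  for (col in names(posts)) {
    posts[[col]] <- as.character(posts[[col]])
    posts[[col]][is.na(posts[[col]])] <- ""
  }
  ids <- unique(posts$forum_id)
  if (nrow(posts) > 0 && length(ids) > 1) {
    stop("a corpus holds one forum; found forum ids: ",
         paste(ids, collapse = ", "))
  }
  if (is.null(forum_id)) forum_id <- if (length(ids) == 1) ids else ""
  if (anyDuplicated(posts$post_id)) {
    dup <- unique(posts$post_id[duplicated(posts$post_id)])
    stop("duplicate post_id within forum '", forum_id, "': ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  rownames(posts) <- NULL
  structure(list(forum_id = forum_id, posts = posts,
                 tokens = NULL, vocabulary = NULL),
            class = "forum_corpus")
}

#' @export
print.forum_corpus <- function(x, ...) {
  cat("<forum_corpus> forum:", x$forum_id, "-", nrow(x$posts), "posts")
  if (!is.null(x$tokens)) {
    cat(";", sum(lengths(x$tokens)), "tokens,",
        length(x$vocabulary), "vocabulary terms")
  }
  cat("\n")
  invisible(x)
}

#' Number of posts in a corpus
#' @param corpus a [forum_corpus()]
#' @export
n_posts <- function(corpus) nrow(corpus$posts)

#' Read forum posts from disk
#'
#' Reads a line-delimited JSON (`jsonl`, the native format: one post object per
#' line) or RFC-4180 CSV file of forum posts. Records must carry `forum_id`,
#' `post_id` and `text`; `thread_id`, `author` and `timestamp` default to the
#' empty string when absent.
#'
#' @param path file to read.
#' @param fmt `"jsonl"` or `"csv"`; default guessed from the file extension.
#' @return a [forum_corpus()], posts in file order.
#' @export
read_posts <- function(path, fmt = c("jsonl", "csv")) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- if (missing(fmt)) guess_fmt(path) else match.arg(fmt)
  if (fmt == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(forum_corpus(empty_posts_df()))
    }
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) {
                        stop("parse error at line ", i, " of ", path, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
      for (f in c("forum_id", "post_id", "text")) {
        if (is.null(rec[[f]])) {
          stop("parse error at line ", i, " of ", path,
               ": missing field '", f, "'", call. = FALSE)
        }
      }
      recs[[i]] <- data.frame(
        forum_id = as.character(rec$forum_id),
        thread_id = as.character(rec$thread_id %||% ""),
        post_id = as.character(rec$post_id),
        author = as.character(rec$author %||% ""),
        timestamp = as.character(rec$timestamp %||% ""),
        text = as.character(rec$text),
        stringsAsFactors = FALSE)
    }
    posts <- do.call(rbind, recs)
  } else {
    posts <- utils::read.csv(path, colClasses = "character",
                             encoding = "UTF-8")
    if (nrow(posts) == 0) return(forum_corpus(empty_posts_df()))
    for (f in c("forum_id", "post_id", "text")) {
      if (is.null(posts[[f]])) stop("csv is missing column '", f, "'")
    }
  }
  forum_corpus(posts)
}

#' Write forum posts to disk
#'
#' Inverse of [read_posts()]: `read_posts(write_posts(corpus, path))` restores
#' every retained field, including texts containing newlines or quotes.
#'
#' @param corpus a [forum_corpus()].
#' @param path output file.
#' @param fmt `"jsonl"` (default, robust to embedded newlines) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_posts <- function(corpus, path, fmt = c("jsonl", "csv")) {
  stopifnot(inherits(corpus, "forum_corpus"))
  fmt <- if (missing(fmt)) guess_fmt(path) else match.arg(fmt)
  posts <- corpus$posts
  if (fmt == "jsonl") {
    con <- tryCatch(file(path, open = "wb"),
                    error = function(e) stop("cannot write ", path))
    on.exit(close(con))
    if (nrow(posts) > 0) {
      for (i in seq_len(nrow(posts))) {
        line <- jsonlite::toJSON(as.list(posts[i, , drop = FALSE]),
                                 auto_unbox = TRUE)
        writeLines(line, con, useBytes = TRUE)
      }
    }
  } else {
    utils::write.csv(posts, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

guess_fmt <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
}

empty_posts_df <- function() {
  data.frame(forum_id = character(), thread_id = character(),
             post_id = character(), author = character(),
             timestamp = character(), text = character(),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a stop-word list
#'
#' Plain text, one word per line. Entries are lower-cased and trimmed; blank
#' lines are dropped. Suitable for augmented lists that add contraction
#' fragments ("ill", "dont") and forum usernames to a standard list.
#'
#' @param path file with one word per line.
#' @return character vector of unique lowercase words.
#' @export
read_stopwords <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  w <- tolower(trimws(readLines(path, encoding = "UTF-8", warn = FALSE)))
  w <- w[nzchar(w)]
  if (any(grepl("\\s", w))) stop("stop-word entries must not contain whitespace")
  unique(w)
}

#' Read externally computed document-topic compositions
#'
#' Parses the tab-separated doc-topics dialect used by common topic-modeling
#' toolkits: each row is a document index, a document name, then alternating
#' topic-id / proportion pairs. Output rows are dense over topics
#' `0..K-1` so a file produced by any toolkit ordering topics by weight is
#' read into a documents-by-topics proportion matrix.
#'
#' @param path doc-topics TSV file.
#' @param K number of topics; inferred from the largest topic id when `NULL`.
#' @return numeric matrix, one row per document, `K` columns; proportions
#'   clipped to `[0, 1]`. Row names are the document names.
#' @export
read_doc_topics <- function(path, K = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = if (is.null(K)) 0 else K))
  }
  parsed <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "[\t ]+")[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 2 || length(f) %% 2 != 0) {
      stop("malformed doc-topics row at line ", i, ": expected doc index, ",
           "name, then topic/proportion pairs", call. = FALSE)
    }
    name <- f[2]
    pairs <- matrix(as.numeric(f[-(1:2)]), ncol = 2, byrow = TRUE)
    if (anyNA(pairs)) stop("non-numeric topic/proportion at line ", i,
                           call. = FALSE)
    list(name = name, topic = as.integer(pairs[, 1]), prop = pairs[, 2])
  })
  max_topic <- max(vapply(parsed, function(p) max(p$topic), integer(1)))
  if (is.null(K)) K <- max_topic + 1L
  if (max_topic >= K) stop("topic id ", max_topic, " exceeds K = ", K)
  theta <- matrix(0, nrow = length(parsed), ncol = K)
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    if (any(p$prop < -1e-9 | p$prop > 1 + 1e-9)) {
      stop("proportion outside [0, 1] at line ", i, call. = FALSE)
    }
    s <- sum(p$prop)
    if (s < 0.99 || s > 1.01) {
      stop("proportions at line ", i, " sum to ", format(s),
           ", outside [0.99, 1.01]", call. = FALSE)
    }
    theta[i, p$topic + 1L] <- pmin(1, pmax(0, p$prop))
  }
  rownames(theta) <- vapply(parsed, `[[`, character(1), "name")
  theta
}

#' Write a document-topic matrix in the doc-topics TSV dialect
#'
#' Companion writer for [read_doc_topics()]: doc index, doc name, then
#' topic-id/proportion pairs in topic-id order.
#'
#' @param theta documents-by-topics proportion matrix.
#' @param path output file.
#' @param names document names; defaults to rownames or `doc<i>`.
#' @return `path`, invisibly.
#' @export
write_doc_topics <- function(theta, path, names = NULL) {
  if (is.null(names)) {
    names <- rownames(theta) %||% paste0("doc", seq_len(nrow(theta)) - 1L)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  K <- ncol(theta)
  for (i in seq_len(nrow(theta))) {
    pairs <- as.vector(rbind(0:(K - 1), format(theta[i, ], digits = 12,
                                               scientific = FALSE,
                                               trim = TRUE)))
    writeLines(paste(c(i - 1L, names[i], pairs), collapse = "\t"), con,
               useBytes = TRUE)
  }
  invisible(path)
}
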