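#' Tokenize post text
#'
#' The token rule used throughout the package: Unicode-aware lower-casing,
#' apostrophes stripped inside words (so "I'll" becomes "ill" and can be
#' caught by an augmented stop list), splitting on runs of non-alphanumeric
#' characters, then dropping pure numbers, single-character tokens and stop
#' words. No stemming is applied: surviving tokens are the original word
#' forms, lower-cased only, which keeps fitted topics readable.
#'
#' @param text character vector of raw post texts.
#' @param stops character vector of lowercase stop words (may be empty).
#' @return a list of character vectors, one token sequence per input text; a
#'   single string yields a list of length one.
#' @examples
#' tokenize("Vaping, vaping VAPING!", character(0))
#' @export
tokenize <- function(text, stops = character(0)) {
  stops <- unique(tolower(stops))
  text <- tolower(as.character(text))
  # strip apostrophes (ASCII and typographic) before splitting, so
  # contractions collapse to single tokens
  text <- gsub("['’]", "", text)
  pieces <- strsplit(text, "[^[:alnum:]]+")
  lapply(pieces, function(tok) {
    tok <- tok[nzchar(tok)]
    tok <- tok[nchar(tok) > 1L]
    tok <- tok[!grepl("^[0-9]+$", tok)]
    tok[!(tok %in% stops)]
  })
}

#' Tokenize every post of a corpus and build its vocabulary
#'
#' Fills the corpus token layer: one token sequence per post (empty posts keep
#' an empty sequence, they are retained, not dropped) and a vocabulary mapping
#' each distinct surviving token to a dense zero-based integer id, in sorted
#' order. Stop words never enter the vocabulary.
#'
#' @param corpus a [forum_corpus()].
#' @param stops character vector of lowercase stop words.
#' @return the corpus with `tokens` and `vocabulary` filled.
#' @export
tokenize_corpus <- function(corpus, stops = character(0)) {
  stopifnot(inherits(corpus, "forum_corpus"))
  corpus$tokens <- tokenize(corpus$posts$text, stops)
  corpus$vocabulary <- sort(unique(unlist(corpus$tokens, use.names = FALSE)))
  corpus
}

# token sequences as zero-based integer id vectors; corpus must be tokenized
token_ids <- function(corpus) {
  if (is.null(corpus$tokens)) stop("corpus is not tokenized")
  lapply(corpus$tokens, function(tok) {
    match(tok, corpus$vocabulary) - 1L
  })
}
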