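LEXICON_GROUPS <- c("subject matter", "health", "context")

#' Construct a contextual-factor lexicon
#'
#' A lexicon operationalizes one contextual factor of tobacco-product use
#' (e.g. setting, time, sensory experience, or the e-cigarette subject matter
#' itself) as a set of terms. Terms may be multiword ("cold turkey"); matching
#' is case-insensitive and boundary-aware, see [post_matches()].
#'
#' @param category factor name, non-empty.
#' @param group one of `"subject matter"`, `"health"`, `"context"`.
#' @param terms character vector of terms; lower-cased and deduplicated.
#' @return an object of class `factor_lexicon`.
#' @export
lexicon <- function(category, group, terms) {
  if (!is.character(category) || length(category) != 1 || !nzchar(category)) {
    stop("category must be a non-empty string")
  }
  if (!(group %in% LEXICON_GROUPS)) {
    stop("unknown group '", group, "'; expected one of: ",
         paste(LEXICON_GROUPS, collapse = ", "))
  }
  terms <- unique(tolower(trimws(as.character(terms))))
  if (any(!nzchar(terms))) stop("empty term in lexicon '", category, "'")
  structure(list(category = category, group = group, terms = terms),
            class = "factor_lexicon")
}

#' @export
print.factor_lexicon <- function(x, ...) {
  cat("<lexicon>", x$category, paste0("[", x$group, "]:"),
      length(x$terms), "terms\n")
  invisible(x)
}

#' Load contextual-factor lexicons from a CSV file
#'
#' Expects columns `category`, `group`, `term`, one term per row (the tabular
#' mirror of a factor-definition table). Rows sharing a category are collected
#' into one lexicon; duplicate (category, term) rows collapse to a single
#' term.
#'
#' @param path CSV file with columns category, group, term.
#' @return named list of [lexicon()] objects, in order of first appearance.
#' @export
load_lexicons <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  if (nrow(df) == 0) return(structure(list(), names = character(0)))
  for (col in c("category", "group", "term")) {
    if (is.null(df[[col]])) stop("lexicon file is missing column '", col, "'")
  }
  cats <- unique(df$category)
  out <- lapply(cats, function(cat) {
    rows <- df[df$category == cat, , drop = FALSE]
    grp <- unique(rows$group)
    if (length(grp) != 1) {
      stop("category '", cat, "' appears under multiple groups: ",
           paste(grp, collapse = ", "))
    }
    lexicon(cat, grp, rows$term)
  })
  names(out) <- cats
  out
}

# lexicon terms as token sequences under the boundary rule
term_token_seqs <- function(lex) {
  seqs <- strsplit(tolower(lex$terms), "[^[:alnum:]]+")
  seqs <- lapply(seqs, function(s) s[nzchar(s)])
  seqs[lengths(seqs) > 0]
}

#' Does a post mention a lexicon?
#'
#' TRUE iff at least one lexicon term occurs in the post text on word
#' boundaries, case-insensitively. Matching runs on the raw lower-cased text
#' (not the stop-word-filtered token stream), so terms that happen to be
#' stop-like ("hit") still count. Multiword terms match as contiguous word
#' sequences; "atty" matches "my atty burnt out" but not "attyx".
#'
#' @param post_text character vector of raw post texts.
#' @param lex a [lexicon()].
#' @return logical vector, one element per post.
#' @export
post_matches <- function(post_text, lex) {
  stopifnot(inherits(lex, "factor_lexicon"))
  seqs <- term_token_seqs(lex)
  if (length(seqs) == 0) return(rep(FALSE, length(post_text)))
  # boundary rule: compare on the word-token level
  words <- strsplit(gsub("['’]", "", tolower(as.character(post_text))),
                    "[^[:alnum:]]+")
  vapply(words, function(w) {
    w <- w[nzchar(w)]
    if (length(w) == 0) return(FALSE)
    for (s in seqs) {
      n <- length(s)
      if (n == 1) {
        if (s %in% w) return(TRUE)
      } else if (length(w) >= n) {
        hits <- which(w == s[1])
        for (h in hits) {
          if (h + n - 1 <= length(w) && all(w[h:(h + n - 1)] == s)) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }, logical(1))
}

#' Per-forum prevalence of contextual factors
#'
#' The prevalence of a contextual factor in a forum is the proportion of the
#' forum's posts containing at least one term from the factor's lexicon. A
#' post counts once per category no matter how many of its terms match.
#'
#' @param corpora list of [forum_corpus()] objects, one per forum.
#' @param lexicons list of [lexicon()] objects.
#' @return a forums-by-categories numeric matrix of fractions in `[0, 1]`
#'   (class `prevalence_matrix`); rows named by forum id, columns by category.
#' @export
prevalence <- function(corpora, lexicons) {
  if (inherits(corpora, "forum_corpus")) corpora <- list(corpora)
  if (inherits(lexicons, "factor_lexicon")) lexicons <- list(lexicons)
  forums <- vapply(corpora, function(co) co$forum_id, character(1))
  for (co in corpora) {
    if (n_posts(co) == 0) stop("empty corpus for forum '", co$forum_id, "'")
  }
  cats <- vapply(lexicons, function(l) l$category, character(1))
  m <- matrix(0, nrow = length(corpora), ncol = length(lexicons),
              dimnames = list(forums, cats))
  for (i in seq_along(corpora)) {
    for (j in seq_along(lexicons)) {
      hit <- post_matches(corpora[[i]]$posts$text, lexicons[[j]])
      m[i, j] <- mean(hit)
    }
  }
  class(m) <- c("prevalence_matrix", class(m))
  m
}

#' Write a prevalence matrix as TSV
#'
#' @param m matrix from [prevalence()].
#' @param path output TSV (forums as rows).
#' @return `path`, invisibly.
#' @export
write_prevalence <- function(m, path) {
  df <- data.frame(forum = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# colour for each cell: sequential light-to-dark ramp, absolute on
# [0, max cell] so forums stay comparable
prevalence_colors <- function(m, palette = c("#F7FBFF", "#08306B"),
                              n_levels = 100) {
  ramp <- grDevices::colorRampPalette(palette)(n_levels)
  top <- max(m, 0)
  idx <- if (top == 0) rep(1L, length(m)) else {
    pmax(1L, ceiling(as.vector(m) / top * n_levels))
  }
  matrix(ramp[idx], nrow = nrow(m), dimnames = dimnames(m))
}

#' Render the contextual-factor heat map
#'
#' Draws the cross-forum comparison grid: rows are contextual-factor
#' categories, columns are forums, and each cell is shaded on a sequential
#' palette scaled to `[0, max cell]` — the darker the hue, the higher the
#' proportion of posts mentioning that factor. A colour-scale legend is drawn
#' alongside.
#'
#' @param m matrix from [prevalence()].
#' @param out_path output figure; `.png` and `.svg` are supported.
#' @param palette two colours, light to dark, defining the sequential ramp.
#' @return `out_path`, invisibly.
#' @export
render_heatmap <- function(m, out_path,
                           palette = c("#F7FBFF", "#08306B")) {
  open_device(out_path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  cols <- prevalence_colors(m, palette)
  nf <- nrow(m); nc <- ncol(m)
  op <- graphics::par(mar = c(5, 9, 2, 5))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  graphics::plot(NULL, xlim = c(0, nf), ylim = c(0, nc), axes = FALSE,
                 xlab = "", ylab = "", xaxs = "i", yaxs = "i")
  for (i in seq_len(nf)) {
    for (j in seq_len(nc)) {
      graphics::rect(i - 1, nc - j, i, nc - j + 1, col = cols[i, j],
                     border = "grey80")
    }
  }
  graphics::axis(1, at = seq_len(nf) - 0.5, labels = rownames(m),
                 las = 2, tick = FALSE, cex.axis = 0.8)
  graphics::axis(2, at = nc - seq_len(nc) + 0.5, labels = colnames(m),
                 las = 1, tick = FALSE, cex.axis = 0.8)
  # colour-scale legend
  ramp <- grDevices::colorRampPalette(palette)(50)
  top <- max(m, 0)
  usr <- graphics::par("usr")
  xleg <- usr[2] + 0.02 * (usr[2] - usr[1])
  wleg <- 0.04 * (usr[2] - usr[1])
  for (k in seq_along(ramp)) {
    graphics::rect(xleg, (k - 1) / 50 * nc, xleg + wleg, k / 50 * nc,
                   col = ramp[k], border = NA, xpd = NA)
  }
  graphics::text(xleg + wleg, c(0, nc), labels = sprintf("%.2f", c(0, top)),
                 pos = 4, xpd = NA, cex = 0.7)
  invisible(out_path)
}

open_device <- function(path, width, height) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (grepl("\\.svg$", path, ignore.case = TRUE)) {
    grDevices::svg(path, width = width, height = height)
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  } else {
    stop("unsupported figure format: ", path, " (use .png or .svg)")
  }
}
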