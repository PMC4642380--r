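#' Read and validate a pipeline run configuration
#'
#' The run configuration is a YAML (or JSON) document describing an
#' end-to-end analysis:
#'
#' ```yaml
#' seed: 7
#' output_dir: runs/demo
#' lexicons: lexicons.csv          # category,group,term
#' stopwords: [stopwords.txt]      # zero or more one-word-per-line files
#' threshold_grid: [0.05, 0.10, ..., 0.95]   # optional
#' category_map: map.csv           # optional topic_id,category[,color]
#' lda: {n_iter: 1000, burn_in: 500, thin: 10}   # optional overrides
#' forums:
#'   - id: vapor_health
#'     posts: vapor_health.jsonl
#'     K: 20
#'   - id: stopsmoking
#'     posts: stopsmoking.jsonl
#'     doc_topics: stopsmoking_doc_topics.tsv   # skip LDA, use these
#'     K: 20
#' ```
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#' @return validated configuration list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    cfg <- yaml::read_yaml(config)
    cfg$.path <- normalizePath(config)
  } else if (is.list(config)) {
    cfg <- config
  } else {
    stop("config must be a file path or a list")
  }
  if (is.null(cfg$output_dir)) stop("config field 'output_dir' is required")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (!is.null(cfg$forums)) {
    ids <- vapply(cfg$forums, function(f) as.character(f$id %||% ""),
                  character(1))
    if (any(!nzchar(ids))) stop("every forum entry needs an 'id'")
    if (anyDuplicated(ids)) stop("forum ids must be unique")
    for (f in cfg$forums) {
      if (is.null(f$posts)) stop("forum '", f$id, "' needs a 'posts' path")
      if (!file.exists(f$posts)) {
        stop("forum '", f$id, "': posts file not found: ", f$posts)
      }
    }
  }
  for (p in cfg$stopwords) {
    if (!file.exists(p)) stop("stop-word file not found: ", p)
  }
  if (!is.null(cfg$lexicons) && !file.exists(cfg$lexicons)) {
    stop("lexicon file not found: ", cfg$lexicons)
  }
  cfg$threshold_grid <- as.numeric(cfg$threshold_grid %||%
                                     seq(0.05, 0.95, by = 0.05))
  class(cfg) <- "run_config"
  cfg
}

run_manifest <- function(cfg, stage, extra = list()) {
  m <- c(list(
    stage = stage,
    package = "forumtopics",
    version = as.character(utils::packageVersion("forumtopics")),
    seed = cfg$seed,
    config_hash = if (!is.null(cfg$.path)) {
      unname(tools::md5sum(cfg$.path))
    } else {
      NA_character_
    }
  ), extra)
  m
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

load_stops <- function(cfg) {
  unique(unlist(lapply(cfg$stopwords, read_stopwords), use.names = FALSE))
}

#' Generate synthetic forum corpora from a run configuration
#'
#' For each entry under `simulate:` in the configuration (fields of
#' [sim_config()], plus `id`), writes the posts (`<id>.jsonl`), the ground
#' truth (`<id>_truth.json`: true theta, phi, dominant topics, injection
#' flags) and a run manifest into `output_dir`.
#'
#' @param config see [read_run_config()].
#' @return named list of `simulate_corpus()` results, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$simulate)) stop("config has no 'simulate' section")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  lexicons <- if (!is.null(cfg$lexicons)) load_lexicons(cfg$lexicons)
  sims <- cfg$simulate
  if (!is.null(sims$id)) sims <- list(sims)  # single entry
  out <- list()
  entries <- list()
  for (i in seq_along(sims)) {
    s <- sims[[i]]
    id <- as.character(s$id %||% paste0("synthetic", i))
    injection <- NULL
    if (!is.null(s$injection)) injection <- unlist(s$injection)
    sc <- sim_config(
      n_posts = s$n_posts %||% 500, K_true = s$K_true %||% 5,
      V = s$V %||% 200, alpha_true = s$alpha_true %||% 0.1,
      beta_true = s$beta_true %||% 0.05,
      length_mean = s$length_mean %||% 189,
      length_sd = s$length_sd %||% 378,
      injection = injection, forum_id = id,
      seed = cfg$seed + i - 1L)
    sim <- simulate_corpus(sc, lexicons)
    posts_path <- file.path(cfg$output_dir, paste0(id, ".jsonl"))
    write_posts(sim$corpus, posts_path)
    truth_path <- file.path(cfg$output_dir, paste0(id, "_truth.json"))
    jsonlite::write_json(list(
      theta_true = sim$truth$theta_true,
      phi_true = sim$truth$phi_true,
      vocabulary = colnames(sim$truth$phi_true),
      dominant_topic = sim$truth$dominant_topic - 1L,
      injected_flags = sim$truth$injected_flags,
      doc_lengths = sim$truth$doc_lengths
    ), truth_path, digits = NA)
    out[[id]] <- sim
    entries[[id]] <- list(posts = posts_path, truth = truth_path,
                          n_posts = sc$n_posts, K_true = sc$K_true)
  }
  write_manifest(run_manifest(cfg, "simulate", list(forums = entries)),
                 file.path(cfg$output_dir, "simulate_manifest.json"))
  invisible(out)
}

#' Run the lexicon-prevalence stage
#'
#' Reads every configured forum, matches the contextual-factor lexicons
#' against raw post text, and writes `prevalence.tsv` plus the cross-forum
#' heat map (`heatmap.png` and `heatmap.svg`) and a manifest to `output_dir`.
#'
#' @param config see [read_run_config()].
#' @return the [prevalence()] matrix, invisibly.
#' @export
run_prevalence <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$lexicons)) stop("config field 'lexicons' is required")
  if (length(cfg$forums) == 0) stop("config lists no forums")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  lexicons <- load_lexicons(cfg$lexicons)
  corpora <- lapply(cfg$forums, function(f) read_posts(f$posts))
  m <- prevalence(corpora, lexicons)
  write_prevalence(m, file.path(cfg$output_dir, "prevalence.tsv"))
  render_heatmap(m, file.path(cfg$output_dir, "heatmap.png"))
  render_heatmap(m, file.path(cfg$output_dir, "heatmap.svg"))
  write_manifest(run_manifest(cfg, "prevalence", list(
    forums = rownames(m), categories = colnames(m),
    max_cell = max(m))),
    file.path(cfg$output_dir, "prevalence_manifest.json"))
  invisible(m)
}

#' Run the topic-modeling and Topic Bars stage
#'
#' Per forum: obtain document-topic proportions (collapsed-Gibbs LDA via
#' [fit_lda()], or an externally computed doc-topics file when the forum
#' entry has `doc_topics:`), calibrate the document-topic threshold on the
#' configured grid, count document-topics, compute topic and category
#' proportions, and write per-forum doc-topics and proportions TSVs, the
#' shared Topic Bars figure, and a manifest recording posts n, topics n,
#' chosen threshold and document-topics n per forum.
#'
#' Without a `category_map` each topic is its own category (`topic00`,
#' `topic01`, ...).
#'
#' @param config see [read_run_config()].
#' @return named list per forum: `theta`, `threshold`, `document_topics`,
#'   `topic_fractions`, `category_fractions`; invisibly.
#' @export
run_topicbars <- function(config) {
  cfg <- read_run_config(config)
  if (length(cfg$forums) == 0) stop("config lists no forums")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  stops <- load_stops(cfg)
  map <- if (!is.null(cfg$category_map)) {
    read_topic_category_map(cfg$category_map)
  }
  results <- list()
  rows <- list()
  entries <- list()
  for (f in cfg$forums) {
    if (!is.null(f$doc_topics)) {
      theta <- read_doc_topics(f$doc_topics, K = f$K)
    } else {
      corpus <- tokenize_corpus(read_posts(f$posts), stops)
      K <- as.integer(f$K %||% 20L)
      lda <- cfg$lda %||% list()
      model <- fit_lda(corpus, K,
                       alpha = lda$alpha %||% (50 / K),
                       beta = lda$beta %||% 0.01,
                       n_iter = lda$n_iter %||% 1000,
                       burn_in = lda$burn_in %||% 500,
                       thin = lda$thin %||% 10,
                       seed = cfg$seed,
                       n_chains = lda$n_chains %||% 1L)
      theta <- estimate_theta(model)
      write_top_words(model,
                      file.path(cfg$output_dir,
                                paste0(f$id, "_top_words.tsv")),
                      m = min(10, length(model$vocabulary)))
    }
    write_doc_topics(theta,
                     file.path(cfg$output_dir,
                               paste0(f$id, "_doc_topics.tsv")))
    threshold <- calibrate_threshold(theta, cfg$threshold_grid)
    dts <- count_document_topics(theta, threshold)
    frac <- topic_proportions(dts)
    fmap <- map %||% topic_category_map(
      names(frac), sprintf("topic%02d", as.integer(names(frac))))
    cat_frac <- category_proportions(frac, fmap)
    utils::write.table(
      data.frame(category = names(cat_frac),
                 proportion = as.numeric(cat_frac)),
      file.path(cfg$output_dir, paste0(f$id, "_proportions.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results[[f$id]] <- list(theta = theta, threshold = threshold,
                            document_topics = dts,
                            topic_fractions = frac,
                            category_fractions = cat_frac)
    rows[[f$id]] <- cat_frac[cat_frac > 0]
    entries[[f$id]] <- list(posts_n = nrow(theta),
                            topics_n = ncol(theta),
                            threshold = threshold,
                            document_topics_n = nrow(dts$pairs))
  }
  colors <- if (!is.null(map)) map$colors
  render_topic_bars(rows, file.path(cfg$output_dir, "topic_bars.png"),
                    colors = colors)
  render_topic_bars(rows, file.path(cfg$output_dir, "topic_bars.svg"),
                    colors = colors)
  write_manifest(run_manifest(cfg, "topicbars", list(
    threshold_grid = cfg$threshold_grid, forums = entries)),
    file.path(cfg$output_dir, "topicbars_manifest.json"))
  invisible(results)
}

#' Run the full pipeline
#'
#' [run_simulate()] (when the config has a `simulate` section; simulated
#' forums are appended to the forum list), then [run_prevalence()] (when
#' lexicons are configured) and [run_topicbars()].
#'
#' @param config see [read_run_config()].
#' @return list with elements `prevalence` and `topicbars`, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  if (!is.null(cfg$simulate)) {
    run_simulate(cfg)
    sims <- cfg$simulate
    if (!is.null(sims$id)) sims <- list(sims)
    for (i in seq_along(sims)) {
      s <- sims[[i]]
      id <- as.character(s$id %||% paste0("synthetic", i))
      cfg$forums <- c(cfg$forums, list(list(
        id = id, posts = file.path(cfg$output_dir, paste0(id, ".jsonl")),
        K = s$K %||% s$K_true %||% 5)))
    }
  }
  prev <- if (!is.null(cfg$lexicons)) run_prevalence(cfg)
  bars <- run_topicbars(cfg)
  invisible(list(prevalence = prev, topicbars = bars))
}
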