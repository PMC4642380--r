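Package: forumtopics
Title: Comparative Topic Modeling and Lexicon Prevalence for Health Discussion Forums
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative mining of tobacco-product discussion
    forums. Estimates the prevalence of contextual-factor lexicons (setting,
    time, social relationships, sensory experience, cost, symptoms, quitting,
    perceptions, practitioners, subject matter) as the proportion of posts
    containing a lexicon term, and renders a cross-forum heat map. Fits latent
    Dirichlet allocation by collapsed Gibbs sampling (compiled sampler), derives
    per-document topic proportions, calibrates a document-topic threshold so the
    number of document-topics is close to the number of posts, and summarises
    forums as category-grouped topic proportions drawn as horizontal stacked
    bars ("Topic Bars"). Includes a synthetic forum-corpus generator with known
    topic structure and exact lexicon-term injection so every stage is testable
    without crawled forum data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
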