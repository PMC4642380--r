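---
title: "Comparative forum mining: lexicon prevalence, LDA, and Topic Bars"
author: "forumtopics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative forum mining: lexicon prevalence, LDA, and Topic Bars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forumtopics)
```

## The analysis

Online discussion forums for e-cigarettes, hookah and smoking cessation
contain rich, naturalistic accounts of how people use tobacco products —
where, when, with whom, what it feels like, what it costs, and what happens
when they try to quit. This package implements a two-stage comparative
analysis of such forums. The unit of analysis throughout is one post = one
document; the headline statistics are per-forum proportions of posts, so
thread-level aggregation is deliberately not offered.

**Stage 1 — lexicon prevalence.** Each contextual factor of tobacco use
(setting, time, social relationships, sensory experience, cost, symptoms,
quitting, health perceptions, health-care practitioners, and the two
subject-matter factors, e-cigarette and hookah) is represented by a lexicon
of terms. The prevalence of a factor in a forum is the fraction of the
forum's posts containing at least one of its terms — a post counts once no
matter how many terms it contains. The forums × factors matrix is rendered
as a heat map with a sequential palette scaled absolutely on
`[0, max cell]`, so hues are comparable across forums, with the darkest
hue anchored at the largest observed cell.

Two design points deserve emphasis. Matching runs on the raw lower-cased
text with word-boundary semantics ("atty" matches "my atty", not "attyx";
"cold turkey" must appear as a contiguous word pair), *not* on the
stop-word-filtered token stream used for topic modeling. The two subsystems
are independent: stop-word filtering is an artifact of topic-model
preprocessing, and lexicon terms that happen to be stop-like ("hit") must
still count. Second, whether multiword terms were matched as phrases or
split into unigrams is genuinely open; the matcher supports both and treats
every lexicon entry as a contiguous token sequence, which reduces to
unigram matching for single-word terms.

**Stage 2 — topic modeling and Topic Bars.** Per forum, a latent Dirichlet
allocation model is fitted: each post is a random mixture $\theta_d$ over
$K$ topics, each topic a distribution $\phi_k$ over the vocabulary.
Inference is collapsed Gibbs sampling — $\theta$ and $\phi$ are integrated
out and each token's assignment is resampled from

$$p(z_i = k \mid z_{-i}, w) \;\propto\;
  (n_{dk}^{-i} + \alpha)\,
  \frac{n_{kw}^{-i} + \beta}{n_{k}^{-i} + V\beta},$$

with documents visited in order and tokens in order within a document, so a
fixed seed reproduces the chain bit for bit. Point estimates are the
smoothed proportions $\hat\theta_{dk} = (n_{dk}+\alpha)/(N_d+K\alpha)$ and
$\hat\phi_{kw} = (n_{kw}+\beta)/(n_k+V\beta)$, averaged over retained
post-burn-in sweeps (Rao–Blackwellised sample averaging).

The forum summary is the *document-topic* statistic. A topic is a major
constituent of a post when $\hat\theta_{dk} \ge T$; each such (post, topic)
pair is one document-topic. Posts that never reach the threshold are
represented by no pair — a post with small amounts of every topic is not
representative of any. The per-topic share is the topic's document-topic
count over the total; shares are summed within user-supplied thematic
categories and drawn as horizontal stacked bars of identical total width,
one per forum, with shared category colours.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `K` | per forum (20 is typical; 40 for large, short-post forums) | number of topics; chosen by the analyst for interpretability, not optimised in-package |
| `alpha` | `50 / K` | symmetric document-topic concentration (dimensionless); the common toolkit default |
| `beta` | `0.01` | symmetric topic-word concentration |
| `n_iter`, `burn_in`, `thin` | 1000, 500, 10 | Gibbs sweeps, discarded prefix, sample-averaging stride |
| `n_chains` | 1 | independent restarts; best final state by collapsed log-likelihood is kept |
| threshold grid | `seq(0.05, 0.95, 0.05)` | candidate document-topic thresholds |

Only $K$ is a substantive modelling choice; the priors are the established
defaults of the sampling toolkits this estimator mirrors, stated explicitly
so that runs are reproducible. Hyperparameter optimisation (asymmetric
$\alpha$) is intentionally not implemented: symmetric priors keep the
sampler exactly checkable against an enumeration oracle, and the
document-topic statistic is robust to the prior at the calibrated
threshold. Empty posts are retained with the uniform row $1/K$ rather than
dropped, because document-topic counting needs one row per post.

**Threshold calibration.** "Close to the number of posts" is formalised as
minimising $|D(T) - N|$ over the grid, where $D(T)$ is the document-topic
count; ties break toward the *larger* (stricter) threshold. The closed
comparison ($\ge$) at the boundary is a declared convention — the choice is
not observable from published counts, and fixing it makes calibration
deterministic. $D(T)$ is non-increasing in $T$, approaching $N\cdot K$ as
$T \to 0^+$ and at most $N$ at $T = 1$, so the calibration always has a
well-defined minimiser on the grid.

## Tokenization

The token rule is a declared convention (topic-modeling toolkits do not
publish one with their outputs): Unicode-aware lower-casing; apostrophes
stripped inside words so contractions collapse ("I'll" → "ill") and can be
caught by an augmented stop list that includes such fragments alongside
forum usernames; splitting on non-alphanumeric runs; pure numbers and
single-character tokens dropped; **no stemming**, because unstemmed topics
are far easier to label. Usernames are handled as extra stop words rather
than detected structurally — detection would be site-specific.

## The synthetic-data generator

Crawled forum data cannot be redistributed, so the package ships a
generator that emulates the *scale and statistical structure* of forum
corpora, not their language. Per corpus: $\phi_k \sim
\mathrm{Dir}(\beta_{true}\mathbf 1_V)$ over an abstract vocabulary
(`w0001`, ...); per post: $\theta_d \sim \mathrm{Dir}(\alpha_{true}\mathbf
1_K)$, a log-normal token count (parameterised by token-scale mean and SD,
minimum 1), and tokens drawn topic-then-word. Defaults: 500 posts, $K_{true}
= 5$, $V = 200$, $\alpha_{true} = 0.1$ (sparse mixtures — real posts are
mostly about one thing), $\beta_{true} = 0.05$ (well-separated topics:
expected pairwise overlap of two such draws over 200 words is tiny), post
length mean 189 / SD 378 tokens, echoing the shorter-post end of real forum
corpora, whose per-forum mean lengths run from roughly 150 to 500 tokens
with SDs of 2–3 times the mean. Lexicon injection is *count-based*:
exactly `round(p · n)` distinct posts receive one uniformly chosen term,
with natural matches counted into the quota, so measured prevalence equals
the target exactly and the recovery test is an equality, not a statistical
bound.

What the generator does **not** emulate: real word-frequency profiles
(Zipfian tails, misspellings), thread and reply structure, bursty authors,
temporal signal, or topic correlation. Passing recovery tests therefore
shows the estimator and statistics are correct *under the model's own
assumptions*; it does not certify topic quality on real forum text, where
$K$ selection and lexicon coverage remain analyst judgments.

## Validation design

The test suite checks each stage against something independent of the code
under test:

- **Enumeration oracle.** On a 2-document, 6-token, $V=3$, $K=2$ corpus the
  collapsed posterior is summed exactly over all $2^6$ assignment states;
  the sampler's posterior-mean $\theta$ (20,000 retained sweeps) must agree
  within total variation 0.05. (With symmetric priors the exact answer is
  uniform by label exchangeability — the test verifies the sampler actually
  mixes across relabelings rather than sticking in one mode.)
- **Parameter recovery.** 500 posts, $K_{true}=5$, $V=200$,
  $\alpha_{true}=0.1$, mean length 60 (SD 30, down from the forum-scale
  default purely to keep the study compact); fit with $K=5$, 1000 sweeps.
  After greedy $L_1$ matching of fitted to true topics, mean per-topic
  $L_1(\hat\phi, \phi_{true}) < 0.15$ and
  $\mathrm{corr}(\hat\theta, \theta_{true}) > 0.8$. The recovery fit uses
  $\alpha = 0.1$ — the generator's own concentration — rather than the
  $50/K$ analysis default: recovery studies fit with the matched prior,
  and a flat document prior deliberately blurs sparse mixtures. It also
  uses three restarted chains selected by the collapsed joint
  log-likelihood $\log p(z, w)$; a sparse-prior chain can occasionally
  freeze in a label-split mode, which the log-likelihood identifies by a
  margin of thousands of nats.
- **Exact prevalence recovery** after injection at $p = 0.25$ into 2000
  posts, and the worked-example proportions (1435/2368 → 60.60%, 362/2368 →
  15.29%, 225/2368 → 9.50% under two-decimal rounding).
- **Threshold statistic.** Monotonicity of $D(T)$ and optimality of the
  calibrated threshold against exhaustive grid evaluation on random
  $\theta$ matrices.
- **End to end.** The full pipeline on a sparse synthetic forum must
  reproduce the generator's mixture — formalised as the same document-topic
  statistic applied to the true $\theta$ — within ±0.05 per category, and
  identical seeds must yield byte-identical TSVs.

## Degenerate inputs and numerical conventions

Ties in `top_words` break toward the lower vocabulary id; topics with no
tokens get uniform $\hat\phi$ rows; an all-empty corpus refuses to fit; a
document-topic set with zero pairs has undefined proportions and errors
rather than returning `NaN`; doc-topics files are validated to row sums in
`[0.99, 1.01]` (toolkits print rounded proportions) and clipped to
`[0, 1]`. All randomness flows through R's own generator — including inside
the compiled sampler — so `set.seed` governs everything; multi-chain fits
derive chain seeds as `seed + chain - 1`.

## Limitations

Lexicon-based prevalence has no notion of negation or sense ("buzz" the
sensation vs "buzz" the doorbell); prevalence comparisons inherit whatever
coverage bias the lexicons have. $K$ and the topic→category map are analyst
inputs: the package computes with them but cannot validate their semantics.
The Gibbs sampler is single-threaded; corpora in the tens of millions of
tokens will want longer runs than the defaults. And forum members are not a
probability sample of any population — these statistics describe the
forums, not tobacco users at large.
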