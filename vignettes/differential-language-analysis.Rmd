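---
title: "Differential language analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential language analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Given a corpus of short personal messages (social-media status updates)
and a table of person-level outcomes — demographics such as gender (coded
0 = male to 1 = female) and age, and psychometric scores such as the Big
Five personality dimensions — differential language analysis (DLA) asks:
*which language features most distinguish people along each outcome?*
Unlike closed-vocabulary analysis, which counts words inside a priori
category lexica, the open-vocabulary approach derives its feature set from
the corpus itself: every word, every multiword phrase that behaves like a
collocation, and every automatically induced topic.

`dlatools` implements the full pipeline: feature extraction, per-feature
covariate-adjusted regression with family-wise error control,
correlation-scaled visualization, and an out-of-sample predictive
comparison of open- versus closed-vocabulary feature sets. Because no
suitable public corpus ships with person-level psychometric outcomes, the
package also contains a synthetic-corpus generator with *known planted
structure*; every statistical claim the test suite makes is scored against
that ground truth.

# Feature extraction

**Tokenization.** Messages are split by an emoticon-aware tokenizer:
a prioritized regex battery matches hearts (`<3`), western emoticons in
both orientations (`:-)`, `D:`), and eastern forms (`^_^`, `>_<`) before
any punctuation splitting, then URLs, mentions, hashtags, words (which may
embed digits — `2day`, `b4`), numbers, and finally single glyphs.
Alphabetic tokens are lowercased; emoticons are left untouched because
case is meaningless inside a glyph. Elongations (`soooo`) are kept as
written: the analysis reports surface forms. Nothing is deleted a priori —
that is the open-vocabulary principle.

**Words and phrases.** All contiguous 1–3-grams are counted per author,
never across a message boundary, and always pooled over the author's
messages: the unit of analysis is the person, not the message. Phrases
are kept only when they carry information beyond their parts, measured by
pointwise mutual information,

$$\mathrm{pmi}(w_1\ldots w_n) \;=\; \log\frac{p(w_1 \ldots w_n)}{\prod_i p(w_i)},$$

with the n-gram probability taken within its own order (an n-gram's
probability is its corpus count over the total count of n-grams of that
length). A phrase is retained when its PMI exceeds $c \cdot n$ in
natural-log units, with $c = 2$ by default (`pmiThresholdCoef`). The
threshold scales with phrase length and sits well above 0, the PMI of a
chance juxtaposition of independent words, while deterministic
collocations (PMI $\log(1/p)$ for marginal probability $p$) pass easily.
Both the coefficient and, implicitly, the log base are configuration: we
state them explicitly because different PMI conventions (log2, log10)
circulate in the literature, and the threshold only makes sense in the
same units as the statistic.

**Normalization and variance stabilization.** Counts are divided by the
author's total word (unigram) use — phrases share the unigram denominator,
so all features live on one scale — and passed through the Anscombe
transform $p \mapsto 2\sqrt{p + 3/8}$, the classical variance stabilizer
for count-derived frequencies. An author who never uses a feature
contributes $2\sqrt{3/8} \approx 1.2247$. Finally, features used by fewer
than 1% of authors ($\lceil 0.01\,n \rceil$, so "at least 1%") are
dropped: rare features cannot be estimated reliably and would dominate
the multiple-testing budget.

**Topics.** Latent Dirichlet Allocation is estimated by a collapsed Gibbs
sampler (Rcpp) over *individual messages* as documents — status updates
are short and rarely mix topics, which also motivates the small
document-topic prior, $\alpha = 0.3/K$ by default. The topic-word prior
is $\beta = 0.01$. After the final sweep, $p(w\,|\,t)$ is the
$\beta$-smoothed assignment count and $p(t\,|\,w)$ the per-word
normalized count. An author's topic usage is
$\sum_w p(t\,|\,w)\,p(w\,|\,\text{author})$ with the author's word
distribution renormalized over the model vocabulary, so usage vectors sum
to one. `K = 50` is the desk-scale default; studies at corpus scale have
used thousands of topics, and `K` is fully configurable, as is importing
an externally estimated topic-word table (`importTopicModel`) in
`word,topic,weight` form.

Collapsed Gibbs on block-structured corpora has well-known merge/split
local modes: two true topics captured by one sampled topic while another
true topic is split. `fitLDA` therefore runs `nRestarts = 5` independent
chains (all derived deterministically from one seed) and keeps the final
state with the highest collapsed joint log-likelihood, which separates
these modes by a wide margin. This is chain selection, not hyperparameter
optimization during sampling, which the sampler deliberately avoids.

**Closed vocabulary.** LIWC-style lexica are supported in two dialects
(CSV `category,term` rows and the classic `%`-header `.dic` format) with
literal tokens and trailing-`*` stem wildcards. A category value is the
share of the author's words matching any of its patterns; a token
matching two patterns of one category counts once, while overlapping
categories are independent. Matching is unigram-only; the few multiword
entries some lexica contain are dropped with a warning, since their
counting semantics are not defined by the format. The proprietary LIWC
dictionary itself is not shipped; a small synthetic demo lexicon under
`inst/extdata/` exercises the format.

# Correlational analysis

For each feature and outcome independently, the outcome is regressed on
the feature plus covariates (typically gender and age), all variables
z-scored, by ordinary least squares. The feature's coefficient is the
*standardized* $\beta$ reported everywhere; with no covariates it equals
the Pearson correlation exactly, which the tests verify to $10^{-10}$
against `cor()`. The p-value is the two-tailed t-test of that coefficient
with $n - k - 2$ degrees of freedom ($k$ covariates). One regression per
feature — never a joint model — is deliberate: a joint or penalized fit
suppresses features collinear with stronger ones, whereas the point of
DLA is a complete ranking of individually distinguishing features.

`runDLA` computes all features at once by residualizing the feature
matrix and outcome on the covariates (Frisch–Waugh–Lovell), which is
algebraically identical to the per-feature regressions; the test suite
checks the equivalence against `lm` route by route. Zero-variance
features go to a skip log in the result metadata, never silently away.

Multiple testing is controlled per outcome over the whole feature family:
Bonferroni at a two-tailed family $\alpha$ of 0.001 by default (20,000
features would demand $p < 5\times10^{-8}$), or Benjamini–Hochberg for
power analyses, where the step-up procedure's larger rejection set is the
point. Missing outcomes or covariates drop authors pairwise, per outcome.

The subsampling power utility redraws authors without replacement at each
requested sample size, *recomputes the 1%-usage feature set on the
subsample* (the feature family shrinks with the corpus, and holding it
fixed would misstate small-sample power), reruns the analysis and counts
significant features, averaged over replicates.

# Visualization

Word clouds scale font size by $|\beta|$ — not frequency — and color by
corpus-frequency quartile on a dark-to-light ramp, so the most
discriminating features are biggest and the most common ones darkest.
Only features significant after correction may be rendered. Redundant
phrases are pruned by scanning in decreasing $|\beta|$: a single word is
always kept; a phrase sharing a word with an already-kept feature
survives only if each of its other words is *strictly rarer* than the
shared word (rarity proxies informativeness; 'beautiful day' adds
'beautiful' to 'day', 'the day' adds nothing). The strictness on ties is
our choice — the seminal description is by example only — and errs toward
sparser clouds. Topic clouds (up to the 6 most distinguishing, placed on
the cloud's perimeter, word size proportional to $p(w\,|\,t)$) are pruned
when more than 25% of their top 15 words already appear in a retained
higher-ranked topic: 4 of 15 shared words trigger the drop, 3 do not.
Layout is a seeded Archimedean spiral; aesthetics are not part of any
contract, but determinism is — the same seed yields a byte-identical SVG,
and every figure writes a JSON sidecar listing each rendered feature with
its $\beta$, p, frequency, size and color bin.

Trends of a feature over a continuous outcome (age) are drawn with
first-order LOESS: at each grid point a weighted linear regression of the
z-scored feature on age *and gender*, with tricube weights over
age-distance (span 0.75, 100-point grid over the observed range, no
extrapolation), evaluated at the sample-mean "neutral" gender. We
implement the local regressions directly rather than through
`stats::loess` because the estimator specified here weights by age
distance only while remaining linear in both predictors, which is not
`loess`'s two-dimensional distance weighting.

# Predictive evaluation

The information content of feature sets is compared out of sample: one
seeded 75/25 author split shared by every feature set; features computed
from *training statistics only* (collocation probabilities, usage
thresholds, topic models, lexicon normalization) and applied frozen to
test authors; PCA (centered, unwhitened) fitted on training data reduces
each set to half the number of training users; a linear SVM classifies
binary outcomes and ridge regression predicts continuous ones, the
regularization parameter chosen by scoring a held-out 10% of the training
set and refitting the winner on all of it. Metrics are accuracy (share
predicted correctly) and $R = \sqrt{\max(0, 1 - \mathrm{SSE}/\mathrm{SST})}$
computed on the test set; clipping negative out-of-sample $R^2$ at zero
keeps $R$ defined. Union feature sets concatenate columns (deduplicated)
before PCA. Ridge is solved in closed form from the centered normal
equations over an explicit 7-value log-spaced penalty grid (checked
against an independent solution in the tests); the SVM is `e1071`'s
linear kernel.

Improvement over a designated baseline set is tested by a paired
bootstrap over test authors: resample authors with replacement, compare
the two models' per-author correctness (or squared errors) on each
resample, and report the one-sided $p = (\#\{\Delta \le 0\} + 1)/(B + 1)$
with $B = 2000$ resamples. The seminal protocol announces a significance
test for this comparison without naming one; the paired bootstrap is our
choice and is labelled as such.

# The synthetic-corpus generator

The generator emulates the statistical shape of a large status-update
corpus; its defaults are the study conditions, not tuning knobs:

* messages per author ~ Poisson(206), words per message ~ Poisson(20),
  hence roughly 4,100 words per author;
* a 2,000-word background vocabulary with Zipf exponent 1.1 — heavy
  tailed like real text but small enough that desk-scale corpora still
  exercise the 1%-usage filter;
* gender ~ Bernoulli(0.62), age from a shifted log-normal matched to
  mean 23.43 and SD 8.96 with a floor at 13 (right-skewed, as social-media
  age distributions are), five standard-normal personality traits;
* fixed collocations (`new_york`, `happy_birthday`, `ice_cream`) emitted
  as intact word sequences, and emoticon tokens, so the collocation
  filter and tokenizer face realistic structure;
* planted effects shift a feature's *log* emission rate by a stated
  amount per SD of an outcome — multiplicative, keeping rates positive
  and mimicking the small standardized effects real language shows.

A companion generator produces topic-structured corpora: disjoint
per-topic vocabularies, each message drawn from a single topic sampled
from an author mixture that can be tied to an outcome through a logit
shift. Ground truth (planted effects, true topic-word matrix, author
mixtures) is emitted alongside the corpus, and recovery tests score
against that file only, never against generator internals.

What the generator does *not* emulate: real lexical content, syntax,
message-length/vocabulary correlations, author-specific style, or
non-stationarity over time. Passing recovery tests therefore show that
the pipeline finds the structure it is pointed at under realistic
sparsity and multiplicity — not that any particular real-world finding
would replicate.

# Problem sizes, numerical choices, defaults

The test and calibration suites run at desk scale, chosen so the full
suite completes comfortably on one CPU: null and planted-recovery corpora
use 500 authors at roughly 400–500 words per author (about 1,500–2,000
features surviving the 1% filter), topic corpora 60–300 authors, and the
predictive comparison 240 authors with eight planted gender-marker words
deliberately absent from the demo lexicon. The author-inclusion defaults
(at least 1,000 words, age under 65 exclusive) apply to real corpora;
calibration corpora are generated above whichever bound they exercise.

Numerical conventions worth stating: PMI uses natural logs, with an
explicit $-\infty$ sentinel for unseen phrases; the usage filter rounds
up (`ceiling`); Anscombe inputs outside $[0,1]$ are errors, not clamps;
`topWords` breaks prevalence ties lexicographically so displays are
stable; the Gibbs sampler consumes R's RNG stream, so one `set.seed`
governs everything including restarts; per-stage CLI seeds are derived
from the global seed plus the stage name, so stages are independently
reproducible; zero-variance features and outcomes are refused loudly
everywhere rather than propagating NaNs.

# Known limitations

* The phrase-pruning generalization ("every non-shared word strictly
  rarer than the shared word") is an interpretation of a rule described
  in the literature only through a single example.
* p-values come from t distributions applied to Anscombe-transformed
  frequencies; for very rare features the normal approximation is rough,
  which is one more reason the 1%-usage filter is on by default.
* The LOESS trend assumes the gender covariate enters each local model
  linearly; evaluation at the gender mean equals averaging the two group
  curves only under that linearity.
* No tokenizer-level language identification is attempted: the
  author-inclusion criteria cover word volume and age, but a
  primary-language filter would need profile metadata the input formats
  do not carry.
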