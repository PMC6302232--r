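---
title: "Methods: disease message volume and content surveillance"
author: "infodemics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disease message volume and content surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infodemics)
```

## The problem

Claims data measure disease prevalence precisely but slowly; social
media measures public attention to disease immediately but noisily.
This package implements the standard surveillance pipeline that joins
the two: filter a message stream by disease keyword lexica, correct
for keyword ambiguity, localize messages to counties, model message
content as topics and themes, quantify disease-content association,
and compare corrected message volume with claims prevalence.

This vignette documents the models, their assumptions, the parameters
that matter, and the numerical conventions, in the order the pipeline
runs them.

## Keyword filtering

Messages are tokenized (NFKC normalization, lowercasing, punctuation
stripping; `#hashtags` and `@mentions` survive as single tokens, URLs
become a `<url>` sentinel) and scanned against per-disease keyword
phrase lists. At each token position the longest matching phrase wins,
ties break by lexicon order, and matched tokens are consumed, so a
token run contributes at most one keyword per disease.

Two count tables result. The per-keyword count $n_k$ is the number of
*messages* containing keyword $k$ (not occurrences). The per-disease
message count de-duplicates multiple keyword hits within one message;
a message naming two diseases counts once toward each. Duplicate texts
(reposts) are *not* collapsed by default — a repost is a real unit of
public attention — but `filterCorpus(..., dedupe = TRUE)` collapses
them for sensitivity analyses.

The bundled 14-disease lexicon is a compact consumer-health-style
starting point, deliberately editable: keyword lists are an input of
this method, not an output, and real deployments should curate their
own.

## Correction factors

Keyword precision varies enormously: "pancreatic cancer" is always
literal, "stroke" almost never is. For each keyword a uniform random
sample of 30 matching messages (all of them, if fewer exist) is
annotated as genuinely disease-referencing or not; the relevant
fraction is the correction factor $w_k \in [0, 1]$, and the corrected
message count of a disease is

$$\widehat{N}_d = \sum_{k \in d} w_k \, n_k .$$

The sample size of 30 per keyword is the conventional manual-review
budget; it gives a binomial standard error of at most
$0.5/\sqrt{30} \approx 0.09$ per keyword. Internal arithmetic keeps
$\widehat{N}_d$ real-valued; reports round half-up to an integer. The
aggregate per-disease factor is reported as the *ratio*
$\widehat{N}_d / N_d$, never used as an input — reconstructing
corrected counts from an aggregate factor is lossy whenever keywords
have unequal precision, which is exactly the interesting case.

Because each keyword contributes its own $n_k$ term, a message
containing two keywords of the same disease is counted in both terms;
with heavily overlapping lexica the corrected count can then exceed
the de-duplicated message count. The package warns when this occurs
rather than silently re-normalizing.

On synthetic corpora the estimator targets the planted relevance rate.
Note a subtlety the tests respect: the mean of repeated annotation
samples converges to the *corpus's empirical* relevant fraction, which
itself fluctuates binomially around the planted rate, so calibration
checks use the combined standard error of both layers.

## Geolocation

Coordinates, when present, take priority and are resolved by
point-in-polygon lookup against county boundary fixtures (a ray-cast
test over arbitrary simple polygons; the bundled synthetic boundaries
are rectangles, real shapefiles can be substituted). Otherwise the
free-text profile location is parsed:

1. "city, state" → direct gazetteer lookup (state as full name or
   2-letter code);
2. a bare city name maps iff one place holds at least 90% of the total
   population over all same-named places ("Chicago" maps; a
   "Springfield" split across ~50 towns does not) *and* the name is
   not on the common-word exclusion list (top English/Spanish nouns,
   verbs and adjectives — "Reading" never maps from a bare field);
3. the same concentration rule applies to bare county names, with
   county population approximated by the sum of its gazetteer places.

The threshold is a parameter (`threshold = 0.9`, compared as ≥), and
the mapping count is monotone non-increasing in it — a property the
test suite checks. Everything here is a pure function of (message,
gazetteer, boundaries), so assignments are exactly reproducible.

## Topics

The modelling vocabulary keeps tokens used by at least 5% of distinct
authors (author frequency, not token frequency, so prolific posters
cannot rescue rare words) and removes every token of every disease
keyword unconditionally — otherwise the later correlation of topic
load with "contains a disease keyword" would be circular.

LDA is fitted by collapsed Gibbs sampling (own Rcpp implementation;
symmetric priors). Defaults follow the common conventions for this
sampler family: $\alpha = 50/K$, $\beta = 0.01$, 1,000 sweeps with 200
burn-in. $K = 200$ is the full-scale configuration; desk-scale runs in
this package use $K$ between 3 and 25 so that the whole suite stays in
seconds. $\phi$ and the marginal topic distribution are averaged over
post-burn-in sweeps with Dirichlet smoothing. The sampler keeps a
private seeded RNG stream, so a fit is bit-reproducible regardless of
the caller's R RNG state; the joint log-likelihood is recorded every
sweep as a convergence diagnostic.

Per-message topic distributions use the word-posterior mixture

$$p(t \mid m) = \sum_{w \in m} p(w \mid m)\, p(t \mid w), \qquad
  p(t \mid w) \propto \phi_{t w}\, p(t),$$

with $p(w \mid m)$ the within-message relative token frequency.
Out-of-vocabulary tokens are dropped before normalizing; messages with
no in-vocabulary token are flagged undefined and excluded from all
correlations. This form is invariant to duplicating a message's token
list, and a single-token message's distribution is exactly
$p(t \mid w)$ — both tested.

Disease association is the Pearson correlation between each topic's
load vector and the binary per-disease mention label across messages
(equivalently the point-biserial correlation; no transformation is
applied to the loads). Two-sided p-values come from the
t-distribution; Benjamini–Hochberg adjustment runs over the full
family of (disease, topic) pairs, with zero-variance pairs recorded as
`NA` and excluded from the family. Significance is declared at
adjusted $p < 0.001$ — applying the threshold *after* adjustment is
the stricter of the two possible orderings, and the one implemented.

## Themes

The $K \times V$ matrix $\phi$ is factorized as $\phi \approx WH$
with $W \ge 0$ ($K \times T$) and $H \ge 0$ ($T \times V$), minimizing
Frobenius error by Lee–Seung multiplicative updates from a
nonnegative-double-SVD initialization. NNDSVD makes the factorization
deterministic for a given $\phi$; the update error is non-increasing
by construction (tested to $10^{-10}$ slack), and non-convergence
within the iteration budget produces a warning carrying the final
residual, never a silent result. $T = 10$ at full scale; the demo
uses $T = 4$.

Row-normalizing $H$ gives $p(w \mid t)$; the theme prior is
proportional to the column mass of $W$; Bayes' rule yields
$p(t \mid w)$, and per-message theme distributions follow the same
mixture formula as topics. The hard theme assignment is the argmax
with ties broken toward the lowest theme index. Theme *names* are
manual configuration strings — nothing in the model assigns
semantics, so the package never pretends otherwise.

Reported statistics use hard assignments, because the target outputs
are integer message counts per (disease, theme): $N(d,t)$ messages of
disease $d$ assigned to theme $t$, $p(t \mid d) = N(d,t)/N(d)$, and

$$\mathrm{PMI}(d, t) = \log \frac{p(d, t)}{p(d)\, p(t)}$$

over the universe of (disease, message) incidences, natural log by
default with a configurable base (the choice of base rescales but
never reorders associations). Zero joint counts report `NA` rather
than $-\infty$. The probability-mass alternative
$\sum_m p(t \mid m) / N(d)$ is available behind
`useHardAssignment = FALSE`.

## Prevalence

County prevalence is unique patients with at least one claim for the
disease divided by county population. Two state summaries are always
computed, because both are in common use and they genuinely differ:
the unweighted mean of county prevalences, and the pooled share
(statewide unique patients over statewide population). The
volume-versus-prevalence report uses the pooled share, since headline
percentages are conventionally quoted against a statewide denominator;
the county mean is reported alongside. They coincide exactly when
county populations are equal — a consistency check in the tests.

## The synthetic world

The generator exists so that every stage above can be tested against
planted truth without any external data. Its defaults are the
package's reference conditions and are not tuned per test:

| parameter | default | meaning |
|---|---|---|
| `nUsers`, `nMessages` | 400, 2000 | corpus size |
| counties | 5, populations 3k–20k | rectangular extents in a synthetic lon/lat grid |
| keywords | 10 keywords, 6 diseases | planted relevance 0.15 ("stroke") to 1.0 ("breast cancer") |
| themes × topics | 4 × 12 | three topics per theme |
| `vocabSize` | 240 | one 60-word block per theme |
| `themeTopicConc`, `topicWordConc` | 1.0, 0.3 | Dirichlet concentrations |
| `diseaseThemeBias` | up to 3× | e.g. breast cancer → Awareness |
| `pKeyword` | 0.45 | messages carrying a keyword |
| `geoNoise` | 0.25 / 0.55 / 0.20 | coordinates / location field / nothing |
| `msgLenRange` | 5–25 tokens | bounded message length |

Design choices worth stating explicitly:

- **Text is a theme → topic → word hierarchy.** Each theme owns a
  disjoint topic set and a disjoint vocabulary block; topics within a
  theme draw Dirichlet word distributions over the *same* block. Topics
  are therefore separable for LDA, while topics of one theme overlap in
  vocabulary — which is precisely what makes the theme clustering
  recoverable from $\phi$ by NMF. Themes with fully disjoint topics
  *and* words would be unrecoverable from $\phi$ alone.
- **Keyword uses carry a planted relevance flag** drawn from the
  keyword's true rate. Relevant uses bias the message's theme prior by
  the disease-theme weight; irrelevant uses (the metaphorical strokes)
  are generated from the unbiased prior, so correction factors and
  content statistics interact the way they do in real corpora.
- **Truth lives in a sidecar**, keyed by message id, never in the
  text, so no filtering stage can cheat.
- **Surface noise** (capitalization, trailing punctuation, URLs,
  hashtags) exercises the tokenizer without ever splitting an injected
  keyword phrase.
- The platform's historical 140-character limit is honored only
  loosely through the bounded token range; realistic English, user
  networks and temporal bursts are deliberately out of scope.

What passing tests therefore show: each stage recovers what it is
mathematically supposed to recover under its own model assumptions,
at the configured noise levels. What they do not show: robustness to
misspelled keywords, code-switching, sarcasm, bot traffic, or
population-biased platform usage — all properties of real streams
that the generator does not emulate.

## Numerical conventions and scale

- All reported percentages and corrected counts round **half-up**
  (2 decimals for percentages, integers for counts), via
  `roundHalfUp()`; base R's banker's rounding would disagree with
  published-style tables on exact halves. Internal values stay
  real-valued.
- Argmax ties break toward the lowest index; keyword-match ties break
  toward longer phrases, then lexicon order.
- Degenerate inputs are explicit: empty annotation samples error,
  zero-variance correlation pairs are `NA` and leave the BH family,
  messages without in-vocabulary tokens are flagged and excluded,
  zero joint counts give `NA` PMI.
- Every stochastic component takes a seed; the Gibbs sampler and the
  generator restore the caller's RNG state.
- Problem sizes in the test suite and acceptance script — corpora of
  500–2,000 messages, $K \le 25$, 150–300 Gibbs sweeps, five seeds
  per recovery property — were chosen as the smallest scales at which
  the planted structure is comfortably identifiable; the full-scale
  configuration ($K = 200$, $T = 10$, millions of messages) is pure
  configuration, not a different code path.

## Known limitations

- Keyword recall is unmeasured: the correction factor estimates
  precision only, and messages about a disease that avoid every
  lexicon phrase are invisible.
- Bare-name geolocation is conservative by design; profile fields
  like "planet earth" are unmappable, and population-bias correction
  across urban/rural platform use is out of scope.
- Theme semantics are manual labels; two analysts can legitimately
  name the same NMF factor differently.
- With few messages per disease, hard-assignment theme counts are
  noisy; the probability-mass variant smooths them at the cost of no
  longer matching integer count tables.
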