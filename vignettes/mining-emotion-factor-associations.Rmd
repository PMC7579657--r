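---
title: "Mining emotion–factor associations in cancer social-media posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining emotion–factor associations in cancer social-media posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emomine)
```

## The analysis model

`emomine` treats a social-media post as the unit of analysis and reduces
it to a binary vector over 47 items: four emotion groups — hope/gratitude
(HG), fear/anxiety/overwhelmed (FAO), sadness/depression/loneliness/guilt
(SDLG), anger/denial (AD) — and 43 emotion-related factor groups (gender,
age bands, cancer types, stages, treatments, survival stages, symptom
clusters). The four groups aggregate nine ontology emotion classes via a
fixed map: {hope, gratitude} → HG, {anxiety, overwhelmed} → FAO,
{depression, loneliness, guilt} → SDLG, {anger, denial} → AD. The group
labels additionally mention "fear" and "sadness" for readability, but the
coding is entirely driven by the nine classes; the labels are cosmetic.

Coding is dictionary-based. A lexicon row maps a normalized surface term
(case-folded, whitespace-collapsed) to a concept class and to one of the
47 items, or to a role marker: `cancer_keyword` (topic inclusion),
`stop_keyword` (off-topic exclusion, e.g. a zodiac sense of "cancer"),
`ad_keyword` (advertising exclusion). Matching is token-based with
multi-token terms matched over contiguous token runs; *all* matching
entries contribute (set union), so a post containing "breast cancer"
sets the breast-cancer item and still matches a standalone "cancer"
entry. There is no stemming or morphological analysis: the intended
input is either a pre-tokenized corpus or the package's own synthetic
corpus, and the lexicon is a swappable input precisely so that
language-specific term lists can be supplied.

### The selection funnel

A post is analyzed iff it (a) mentions the cancer topic, (b) mentions at
least one emotion term, (c) matches no stop keyword, and (d) matches no
advertising keyword. Stop-keyword posts are removed *before* the emotion
count and advertising posts are subtracted *after* it, so the report
satisfies `n_selected = n_with_emotion - n_ad_excluded` — the identity
that published funnels of this design obey (e.g. 434,299 emotion-bearing
posts minus 112,960 advertising posts = 321,339 analyzed). Whether a
stop keyword should remove the whole post or merely the match is an open
design point in this kind of pipeline; post-level removal was chosen
because stop terms here indicate an off-topic document, not a noisy
token.

Indicators are idempotent under repeated mentions (count-once) and
multiple distinct emotion groups in one post are all coded 1, which is
why emotion percentages may sum above 100.

### Association rules

Frequent itemsets are mined with a hand-rolled Apriori (level-wise
candidate generation, downward-closure pruning); the miner is the
package's central primitive and is validated against brute-force subset
enumeration in the tests. Rules are restricted to the shape the analysis
calls for — a non-empty antecedent of factor items and a single emotion
group consequent — with

* support(A ⇒ e) = P(A ∪ {e}),
* confidence = support / P(A),
* lift = confidence / P(e).

Defaults `min_support = 0.01` and `min_confidence = 0.1` are the
smallest thresholds consistent with published rule tables of this
analysis (rule supports ≥ 0.010; anger/denial confidences as low as
0.107); both are configurable. Because posts are multi-label at the
post level, antecedents such as {male, female} are legitimate — a post
can mention both genders. Ranking uses lift with deterministic
tie-breaks (higher support, then lexicographic antecedent), and all
outputs are deterministically ordered so reruns are diffable. Reported
metrics are half-up rounded to 3 decimals in the CSV; a JSONL sibling
keeps full precision.

### Co-occurrence networks

Posts are stratified by length: long-form (blogs + cafés + message
boards) versus Twitter (140-character cap). Nodes are items with
frequency (posts mentioning the item) and degree (distinct co-mentioned
items, ≤ 46); an undirected edge's weight counts posts mentioning both
endpoints — post counts, not mention pairs, carrying the count-once
semantics through. Node tables report the top `ceiling(fraction × 47)`
nodes (24 at the default 0.5) with percentages using the stratum's post
count as denominator, which is what makes multi-label percentages above
50% possible. The conservation identity Σ_edges weight =
Σ_posts C(m_p, 2), with m_p the post's item count, is asserted in the
tests and the acceptance script.

## The synthetic corpus generator

Real corpora of this kind are not redistributable, so the generator
defines the study conditions the package is validated under:

* **Factor presence** is independent Bernoulli per item. Default
  prevalences are taken from the published marginal counts over the
  321,339-post corpus (gender/age/cancer-type rows of the channel
  table; treatment/stage/survival/symptom items from the two network
  node tables using stratum additivity). Items absent from every
  printed table (middle stage, transplantation, poor circulation,
  thrombocytopenia, infection, the rarest age bands) were set once to
  small realistic values (0.002–0.02) and not revisited.
* **Emotions** follow a logistic model: `P(e | F) = plogis(qlogis(β_e)
  + Σ_{f ∈ F} log effect_e[f])`. This is the smallest model in which
  lift is a tunable parameter with a closed-form oracle. Default
  effects (1.3–3.0) plant the qualitatively reported associations
  (treatments/acute survival/breast cancer → HG; early stage/GI
  problems/pancreatic cancer → FAO; hair loss/surgery/fatigue → SDLG;
  hair loss/acute survival → AD).
* **Baselines** β were calibrated analytically — a fixed point of the
  exact conditioned marginals, computed by `expected_emotion_marginals()`
  before any corpus was drawn — so the default conditioned emotion
  marginals are 46.5/45.2/39.4/8.0%, the published values. The frozen
  baselines are 0.1605/0.1803/0.1687/0.0345.
* **Conditioning.** Zero-emotion posts are resampled (factors and
  emotions jointly), because the analyzed corpus contains only
  emotion-bearing posts; a `no_emotion` contamination fraction
  reinstates them to exercise the filter, and an `ad` fraction plants
  advertising keywords. Channel counts default to the published shares
  (40.1/39.2/19.0/1.6%). One root seed drives per-channel derived
  streams, so a channel's posts are reproducible in isolation.
* **Rendering.** Each planted item becomes a randomly chosen lexicon
  term, shuffled with filler tokens; Twitter posts drop fillers to stay
  within 140 characters and raise a generation error naming the post if
  the planted terms alone cannot fit.

### The lift oracle

`expected_lift()` computes P(e | antecedent) / P(e) by exact enumeration
over the factor configurations that can influence any emotion (all other
factors are independent of the emotions and cancel), refusing more than
20 active factors. Crucially, the default oracle conditions on the post
carrying ≥ 1 emotion group — the distribution the pipeline actually
sees after resampling and filtering. Conditioning matters: it couples
the four emotions through the keep-probability and shifts every
marginal upward; with all effects equal to 1 it still leaves lift
exactly 1, so null calibration is preserved. The unconditional model
(`condition_on_emotion = FALSE`) is kept for desk-checkable examples
such as the two-configuration single-factor case, where the oracle
equals `plogis(qlogis(0.2) + log 4) / (0.5·0.5 + 0.5·0.2) = 10/7`.

## What passing tests do and do not show

The generator emulates marginal prevalences, channel shares, planted
conditional structure, and contaminants. It does **not** emulate real
language (morphology, negation, sarcasm), temporal dynamics, user-level
correlation across posts, or channel-specific factor distributions
beyond post counts. Tests passing on synthetic corpora therefore
validate the *pipeline arithmetic* — funnel counts, coding semantics,
mining correctness, network identities, recovery of known effects —
not the fidelity of any particular lexicon on real text. Corpus-specific
published numbers (e.g. which antecedents appear in the top-5 rule
tables) depend on the unavailable corpus and are not reproduced
end-to-end; what is reproduced is every piece of printed arithmetic and
every structural identity those tables obey.

## Numerical and design choices

* Percentages are half-up rounded to 1 decimal (`round_half_up()`),
  matching printed tables; R's default banker's rounding would turn
  0.05 into 0.0.
* Apriori output order is (size, lexicographic items) with an
  unambiguous separator in the join keys; ties in rule ranking break by
  support then antecedent string; edge ranking breaks ties by item
  identifiers.
* Degenerate inputs: empty corpora give zero-count funnel reports and
  empty itemset tables; `min_support ≤ 0` and zero-post frequency
  tables are errors; a consequent with zero support would make lift
  undefined and the rule is skipped with a message.
* The problem sizes exercised by the tests and the acceptance script —
  parameter recovery at 20,000 posts (bootstrap SE over 200 resamples,
  all planted |z| ≤ 3), null calibration at 50,000 posts (≥ 95% of
  single-factor lifts within ±0.1 of 1), 200 randomized
  miner-vs-enumeration trials at ≤ 15 items — were chosen as the
  smallest corpora at which the Monte-Carlo bands are meaningfully
  tight for effects of the planted magnitude.

## Known limitations

* Token-based matching cannot resolve morphological variants; a real
  Korean-language deployment would insert a morphological analyzer
  upstream and feed the lexicon's surface forms accordingly.
* Demographic items code *mentions*, not author attributes.
* The generator's independence assumption between factors understates
  the factor-factor correlation real posts exhibit (e.g. breast cancer
  and female co-mention); rule antecedents on real data would reflect
  that correlation, synthetic ones do not.
* Statistical significance of rules and centrality measures beyond
  degree are out of scope, as in the analysis design this package
  implements.
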