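---
title: "Windowed entitymetric indices: model, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed entitymetric indices: model, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p3c)
```

## The measurement model

The package quantifies the attention a biomedical entity (a disease, drug or
gene) receives within the literature of a research field — typically the
corpus of publications about one drug — as four ratios per time window:

* **Popularity** `P1 = 100 * n_i / n_T`: the share of the field's
  publications in the window that mention the entity at least once. Mentions
  are document-level: a paper repeating the entity ten times counts once.
* **Promising** `P2 = n_i/n_T - n_pi/n_pT`: the change in the popularity
  *fraction* relative to the preceding window of equal length. It is kept on
  the fraction scale because that is how the defining formula reads; report
  layers may multiply by 100 and call the result percentage points. A value
  of 0.06 therefore reads "popularity rose by 6 percentage points".
* **Prestige** `P3 = 100 * n_H20 / n_i`: the share of the entity's own
  publications that appeared in a configured top-journal set. Prestige tends
  to peak *before* popularity: high-impact venues pick a topic up early, the
  bulk of the field follows.
* **Collaboration** `CI = 100 * n_AI / n_AT`: the share of the window's
  distinct authors who wrote at least one entity paper.

All denominators come from the filtered input corpus only; the package never
assumes access to database-wide yearly totals. P3 and CI carry an inclusive
interest flag at a configurable threshold, 5% by default; the comparison is
`>=` because strictness at the boundary is otherwise arbitrary.

Two derived analyses sit on top: each entity is assigned to a research
*phase* (an expert-given, contiguous partition of the span — the default is
the four-era aspirin scheme 1951–1960 / 1961–1990 / 1991–2000 / 2001–2018)
by the window of its P1 maximum; and the interval between the P1-maximum
and P3-maximum windows is reported in years under the *start-year
convention*, `t1$start_year - t2$start_year`. Start years are canonical
because they reproduce interval arithmetic exactly even when the final
window is truncated; midpoints or end years would agree for equal-width
windows but not in general.

## Windowing

`make_windows(span, width)` cuts the span into consecutive inclusive-year
windows, truncating the last (1951–2018 at width 5 ends in the 3-year
window 2016–2018). Publication counts are additive over any refinement of a
window; distinct-author and distinct-journal counts are deliberately *not*
additive — an author active in two sub-windows is distinct in each — which
is why phase-level distinct counts are computed (or supplied) directly
rather than summed.

Undefined cells are first-class: `P1` is `NA` when a window is empty,
`P3` when the entity has no publications (`n_i = 0`, a 0/0 — reporting 0
would fake evidence of low prestige), `CI` when there are no authors, and
`P2` on the first window and on a truncated final window whose width
differs from its predecessor. One exception: if the input corpus itself
contains records from before the first window, the same-width year range
immediately preceding it silently serves as the P2 baseline — mirroring how
a first-window change can only be computed when pre-span data exist.
Undefined cells are excluded from maxima, averages and flags, and are
serialized as empty CSV fields.

## Dictionary tagging

Matching is purely lexical against a typed synonym lexicon, after a
deterministic normalization of both text and synonyms: lower-casing, Latin
accent folding (by explicit character map — locale-dependent
transliteration is not reproducible), removal of subscript underscore
markup (`P2Y_12_` → `p2y12`), punctuation → single spaces with the one
exception of ASCII hyphens flanked by alphanumerics (`cox-2` survives), and
whitespace collapsing. Normalization is idempotent, which the suite checks
by property.

A synonym matches only at word boundaries: the span must be flanked by text
edges or non-alphanumeric characters, so "asthma" never matches inside
"asthmatic". Among overlapping candidates of the same entity type the
longest wins (ties: earliest start, then entity id) and overlapped shorter
candidates are suppressed — "acetylsalicylic acid" beats "salicylic acid" —
while cross-type overlaps are all reported, accommodating gene/drug
homonyms. Stop words are *not* removed before matching, because multi-word
synonyms legitimately contain them. Within one type a normalized surface
may belong to only one entity (loading fails otherwise); across types the
same surface may recur.

The corpus-scale matcher is a vectorized fixed-string pass per synonym with
a shared boundary rule; a brute-force positional oracle (every synonym at
every offset, explicit substring comparison, independent suppression loop)
re-derives its output on over a thousand randomized lexicon/text pairs in
the test suite. The two routes are kept strictly separate.

## Author identity

Distinct-author counts use a deterministic key: accent-folded, lower-cased
surname, `|`, upper-cased initials of the given-name tokens
(`García, María J` → `garcia|MJ`). This deliberately simple blocking rule is
reproducible and auditable; it conflates namesakes sharing initials and
splits authors who change name forms, both of which bias distinct counts
somewhat relative to probabilistic disambiguation. Every function that
counts authors accepts a `key_fun` argument, so a stronger keying can be
plugged in without touching the pipeline.

## The synthetic-corpus generator

`generate_corpus()` emulates exactly the statistical structure the indices
are designed to read, with known ground truth:

* per window, exactly `m_w` records (years cycle deterministically through
  the window);
* each record mentions each planted entity independently with the trend's
  per-window probability `q_w`, realized by inserting the entity's
  canonical surface into fixed filler text that is validated to contain no
  lexicon surface forms — so the matcher must find all and only the planted
  mentions, and the pipeline's window counts must equal the generator's
  ground truth *exactly*, not just in distribution;
* records mentioning a lifted entity land in a top journal with probability
  `top_fraction * top_journal_lift` (validated ≤ 1), creating a prestige
  signal;
* author slots of entity records come from a dedicated per-entity sub-pool
  with probability `author_affinity`, creating a collaboration signal.

Defaults chosen once as plausible for a mid-sized specialty literature:
a 20-journal pool with 4 designated top journals and a 0.15 baseline
top-journal fraction; a general pool of 500 authors plus 40-author
entity sub-pools; 1–8 authors per paper, uniform. Under the closed-form
companions `E[P1] = 100 q_w` and `E[P2] = q_w − q_{w−1}`
(`expected_indices()`), estimates converge at the binomial rate
`sqrt(q(1-q)/m_w)`.

Randomness is partitioned into named substreams (one per entity's mentions,
one each for journals, author counts, author slots), each seeded by folding
a string tag into the user seed. Hence the same seed reproduces a corpus
byte-for-byte through the fixture writer, and adding one more trend leaves
every other entity's draws untouched. Entity co-mentions are independent —
a correlation structure is not modelled.

What the generator does *not* emulate, and what passing tests therefore do
not show about real data: natural language (no ambiguous or misspelled
surfaces, so matcher recall on synthetic text is exact by construction
while real-text recall depends on lexicon quality), growth in corpus size
and author-list length over decades, journal drift, author namesakes, or
correlated entity trajectories.

## Validation problem sizes

The suite validates at sizes chosen to make sampling error negligible
relative to the planted effects while keeping runs comfortably
reproducible on a laptop: oracle equivalence on 1000+ random matcher cases
and full per-window recounts on randomized corpora of a few hundred
records; the telescoping identity `sum(P2) = P1(last)/100 − P1(first)/100`
to 1e−12 on fuzzed corpora; and a recovery study with 1000 records per
window over five windows, a unimodal trend peaking at 3× its plateau
(q = 0.05/0.10/0.30/0.10/0.05), and 100 seeds — under which the planted
peak window is recovered as the P1 argmax in ≥95% of runs and estimated P1
sits within 3 binomial standard deviations of `100 q_w` in ≥99% of cells.
`scripts/acceptance.R` re-runs this study end to end and also
re-aggregates the bundled per-window reference statistics of the aspirin
literature (phase totals, phase-3/phase-1 fold changes, maxima intervals).

On those reference tables, note one deliberate output: the mean of the nine
recomputed P1-vs-P3 maxima intervals is 12.2 years under the start-year
convention; the package reports this computed mean rather than any
externally stated summary of the same column.

## Known limitations

Top-journal membership is exact normalized title matching against a
configured list — no ISSN resolution, no impact-factor computation, and
renamed journals count as different titles. Dictionary tagging has no
abbreviation resolution or disambiguation beyond the longest-match rule.
The author key is a blocking surrogate, not a disambiguator. Phase schemes
are expert input, not change-point detection. The optional live-retrieval
side of the query renderer is untested by design; `render_query()` only
formats the Boolean expression.
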