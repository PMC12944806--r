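---
title: "Phenotypic similarity ranking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic similarity ranking: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenonet)
```

## The problem

A patient population — here, patients diagnosed with Minamata disease, the
neurological syndrome caused by methylmercury exposure — is described by a
*query profile*: phenotype-ontology terms with the fraction of patients
showing each symptom. A disease corpus (such as the HPOA annotation file)
describes thousands of diseases the same way, though with heterogeneous and
partly missing frequency information. The task is to rank every corpus
disease by phenotypic similarity to the query, compare what different
similarity definitions emphasise, and aggregate them into one consensus.

The ontology is a rooted directed acyclic graph of terms connected by
*is a* edges; a term may have several parents. All graph work (reachability,
undirected shortest paths) is delegated to igraph behind the package's
term-id interface.

## Corpus normalisation

Annotations pass three steps before any scoring.

**Aspect and subtree filtering.** Only phenotypic-abnormality annotations
are kept: the aspect column must say so *and* the term must resolve inside
the supplied ontology (belt and braces — a restricted ontology makes the
second filter meaningful). Explicitly negated ("NOT") annotations are
dropped and counted; there is no principled way to use them in overlap
measures, and their prevalence in real files is low.

**Frequency normalisation.** The four HPOA frequency formats become one
probability:

| format | example | value | extra |
|---|---|---|---|
| fraction | `7/11` | 7/11 | denominator kept as weight |
| percentage | `30%` | 0.30 | no weight (sample size unknown) |
| class term | `Occasional` | 0.17 | interval [0.05, 0.29], value = midpoint |
| missing | | `unknown_default` | |

`unknown_default` is 0.5 — the mean of a uniform prior over [0, 1], i.e.
maximal ignorance about the true frequency — with 0.01 ("very rare") and
1.0 ("obligate") provided as the extreme presets for sensitivity analysis.

**Duplicate resolution.** The same disease–term pair reported twice (e.g.
by two source ontologies) collapses by three ordered rules: fractions pool
as a weighted mean with denominators as weights (this genuinely merges the
underlying samples); if any value carries an interval, the merged value is
the midpoint of the *smallest interval compatible with all values* —
implemented as the intersection of the intervals when non-empty, else the
spanning hull, with point values as degenerate intervals (intersection
first, because when annotations agree the intersection is strictly more
informative than the hull); otherwise a plain arithmetic mean. Percentages
carry no sample size, so they deliberately fall to the arithmetic-mean
rule rather than entering the weighted mean with an arbitrary weight.

Identifier unification through MONDO xrefs happens *before* duplicate
resolution, so the cross-ontology duplicates that motivate the rules are
actually merged; an id claimed by several MONDO terms resolves to the
lexicographically smallest (deterministic, warned about).

## Information content

`IC(x) = −log p(x)` in nats, where `p(x)` is the fraction of corpus
diseases annotated to `x` *or any descendant* (implicit propagation, the
standard Resnik convention; it guarantees IC is antitone from child to
parent, which the test suite asserts as an invariant). Terms no disease
reaches would have infinite IC; they instead receive add-one smoothing,
`p = 1/(n+1)` — applied only to zero-count terms so that exact toy
computations (e.g. 1 annotated disease out of 4 giving `IC = log 4`)
remain exact. An `"exclude"` mode (IC = NA) is available. The natural
logarithm is a free choice: the base cancels in GraphIC's ratio and only
rescales Resnik scores, never their ranking. The corpus over which IC is
computed is a parameter; the default is whatever corpus is being scored.

## The similarity measures

Jaccard and the TF-IDF family are classical; the conventions that needed
fixing are:

- **Empty sets**: `J(∅, ∅) = 0`, not 1, so annotation-free profiles never
  outrank genuine matches.
- **Ancestor sets are self-inclusive** (`x ∈ anc(x)`): `resnik_term(x, x)
  = IC(x)` and GraphIC's expanded sets contain the original terms.
- **TF-IDF**: tf is the stored annotation frequency (symptom importance
  enters through patient frequency; a binary 0/1 tf is available), and
  idf is the smoothed `log((1+N)/(1+df)) + 1` with `df` counting *direct*
  annotations. The smoothing keeps idf positive, so query terms outside
  the corpus vocabulary still contribute signal.
- **Frequencies weight only the TF-IDF family.** Jaccard, Resnik and
  GraphIC use term sets alone.
- **Resnik headline variant is the best-match average**; the plain grid
  average is exposed (`resnik_avg`) for correlation studies. Note a clone
  of the query is *not* guaranteed to maximise the plain average — a
  single-term disease holding the query's highest-IC term can beat it —
  which is exactly why BMA is the ranking variant.

**Query expansion** gives every ontology term the frequency
`f_y = f_x · α^d(x,y)` of its *nearest* seed `x` under undirected edge
distance (paths may climb towards the root and descend again — required
for a hypotonia seed to reach a hypertonia descendant). Equidistant seeds
tie-break to the larger resulting frequency: permutation-invariant and
favouring the stronger evidence. `α = 0` degenerates to the seed set
(`0⁰ = 1`), `α = 1` floods every term with its nearest seed's frequency;
0.5 is the default working point, and `alpha_sensitivity()` quantifies how
much the ranking cares. Expansion runs over whichever ontology is passed,
so pass the phenotypic-abnormality subtree to avoid adding terms the
corpus cannot match.

## Ranking, comparison, aggregation

Rankings sort scores descending with lexicographic disease-id tie-breaks
(deterministic, gap-free ranks). The weighted Kendall τ uses additive
hyperbolic weights: an exchange between positions *i* and *j* costs
`1/(rᵢ+1) + 1/(rⱼ+1)`, so the top of the ranking dominates the statistic.
Because the weights depend on which ranking supplies the positions, the
statistic is computed with each ranking as reference and averaged; the
Cauchy–Schwarz normalisation makes τ exactly 1 on identical and −1 on
reversed rankings. Only the O(n²) pair-enumeration implementation is
shipped — at the corpus sizes involved it is instantaneous, and the tests
pin it against an independent double-loop oracle, exhaustively over all
permutations of up to 6 items.

Consensus aggregation is equal-weight and *score-based*: each method's
scores are normalised by that method's maximum, averaged, re-ranked, and
renormalised so the top disease scores 1. A rank-based alternative
(mean of 1/rank) sits behind a flag; score-based was chosen because the
consensus is presented as a continuous normalised score, which a
rank-based Borda cannot produce. Of the two TF-IDF rankings only the
query-expanded one enters the default consensus. Top-`k` diseases are
classified by intersecting their ancestor sets with the direct children of
the disease-ontology root (the "main disease classes"), each category
counted once per disease however many paths reach it; `k = 50` by default,
configurable.

## The synthetic generator

The generator exists so that every stage is testable offline, and its
defaults are fixed study conditions, not tuning knobs: 200-term ontologies
(each term drawing 1–3 parents among earlier terms, giving multi-parent
diamonds and guaranteed acyclicity), 200 diseases with 3–50 terms drawn
with `1/i` popularity bias (a broad document-frequency spread, so TF-IDF
is non-degenerate), Beta(2, 2) symptom frequencies emitted as fractions
(denominators 5–200, exercising unequal weights), percentages, class terms
and missing cells in proportions of roughly 35/20/19/26% — close to the
one-quarter missing rate of real annotation files — plus a 10% duplicated
pair rate to exercise merging. Planted diseases provide known answers: a
*clone* (identical term set and frequencies; must rank first everywhere),
an *overlap* disease (half the query terms), and an *ancestor shift*
(every query term replaced by a parent: Jaccard-invisible but visible to
IC-based measures). Query terms are drawn at depth ≥ 2 with parent sets
disjoint from the query so the shift is genuinely overlap-free.

What the generator does **not** emulate: the real ontology's depth and
branching statistics, term-term correlation within diseases, curation
biases, or the actual scale (12k+ diseases). Passing tests therefore
demonstrate the pipeline's correctness and its qualitative behaviour
(zero-score removal, method disagreement patterns), not the published
full-corpus rankings, which require the pinned HPO/MONDO/HPOA releases as
inputs.

## Numerical and degenerate-input choices

- Unreachable term pairs get distance `Inf` (only possible in synthetic
  non-rooted graphs); expansion drops unreachable terms.
- GraphIC with an all-zero-IC union returns 0 with a warning.
- Cosine with a zero-norm vector returns 0.
- `merge_duplicates` is permutation-invariant; corpus building is fully
  deterministic (sorted orderings throughout), so identical inputs yield
  byte-identical serialised outputs.
- All generators are pure functions of (config, seed); RNG state is
  saved and restored around them.

## Problem sizes in the test suite

The suite runs the full pipeline on 200-term / 200-disease corpora across
20 seeds for the recovery checks, 100-instance identity/bound sweeps, and
exhaustive τ validation to n = 6 (720 permutations); these sizes keep the
whole suite within a few minutes on one core while still exercising
multi-parent DAG structure, all four frequency formats and every planted
scenario.

## Known limitations

- Only `is_a` relations are honoured; other OBO relationship types,
  logical definitions and imports are ignored.
- The packaged Minamata profile is a documented stand-in: it pins the
  values printed in the source survey discussion (the corrected 0.37%
  intellectual-disability frequency, the spasticity and hypotonia seed
  terms, n = 269) and fills the remainder synthetically.
- Disease–disease all-pairs similarity matrices, other IC measures
  (Lin, Jiang–Conrath) and statistical significance for τ are out of
  scope.
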