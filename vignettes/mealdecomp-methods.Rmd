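---
title: "Methods: simulating and evaluating compound-ingredient decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating compound-ingredient decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealdecomp)
```

## The problem

Meal plans list dishes the way a menu does: "Chicken Marsala, 200 g". For
nutrient profiling, allergen screening, or ingredient substitution, a
*compound* ingredient like that has to be decomposed into *basic*
ingredients — chicken breast, Marsala wine, olive oil, garlic, mushrooms —
each with an estimated mass, and those basics have to be matched to a food
composition repository before any nutrient arithmetic is possible.

Language-model backends can perform the identification and decomposition
steps, but their output is free-form text and their culinary judgement is
imperfect: they miss compounds, flag basics, invent masses that do not sum
to the stated portion, and omit or include seasonings inconsistently.
`mealdecomp` packages the whole measurement apparatus for studying this
behavior: the structured meal-plan dialect and prompts, robust parsing of
the delimited responses, the composition-store mapping with its data-type
trust hierarchy, the nutrient arithmetic, and the statistical evaluation —
all runnable offline against a synthetic generator whose ground truth is
known exactly.

## Pipeline model

A study run executes seven stages per backend:

1. **Generation** — meal plans as single HTML tables with columns
   `Ingredient`, `Ingredient Details`, `Quantity`, `Portion Size (g, dL)`.
   Portions in dL/mL convert to grams with a configurable density, 1 g/mL
   by default (the dialect mixes masses and liquid volumes in one column,
   so a conversion rule is required; water-like density is the neutral
   choice and can be overridden per ingredient).
2. **Decomposition** — the backend receives the rendered decomposition
   prompt and returns a dictionary of dictionaries encapsulated in dollar
   signs. The payload grammar accepts strict JSON-like text *and* the
   looser quoted-pair style the prompt itself illustrates (single, double
   or typographic quotes; inner dictionaries with or without braces),
   because the prompt's example format is not valid JSON and model output
   drifts further. Extraction takes the *first* `$...$` span; a failed
   extraction is re-asked once, then the item is failed and logged.
3. **Subset creation** — for each basic ingredient, candidate records are
   selected from the composition store by case-insensitive substring match
   on the description, tier by tier: SR Legacy/Foundation first, FNDDS if
   fewer than `sufficiency_threshold` (default 3) matches exist, then
   Experimental/Branded. Candidates carry only `(fdcId, description)`;
   nutrient content is deliberately withheld so the mapping decision rests
   on the description alone. Results are ordered (tier, ascending fdcId)
   so rendered mapping prompts are reproducible. The threshold default of
   3 is a package choice — "insufficient" is not quantified anywhere
   authoritative — and is configurable and logged.
4. **Mapping** — the backend picks one `fdcId` from the candidate list.
5. **Nutrients** — per-100 g profiles are retrieved and scaled by
   `mass/100`.
6. **Aggregation** — part profiles are summed over the union of nutrient
   keys (an absent key counts 0), with per-nutrient coverage reported so
   silent zeros from ragged panels remain auditable. No cooking-loss
   correction is applied: decomposed masses are evaluated as proposed.
7. **Evaluation** — identification quality and decomposition quality, as
   below.

In live mode the same contracts drive real endpoints, with request pacing
of `3600 / limit_per_hour` seconds (3.6 s at the common 1000 requests/hour
limit). The test suite exercises only the deterministic mock.

## Decomposition-quality metrics

**Mass conservation.** A decomposition *matches* when
`|parts_total − portion| ≤ ε`, with `ε = 0.5` g by default: "exact" match
is stated without tolerance anywhere, and since model output is
integer-gram styled, a half-gram band recognises exact integer agreement
while remaining configurable.

**Overestimation.** A compound is flagged when
`parts_total / portion > 1.25` — strictly greater, so a ratio of exactly
1.25 ("a quarter over") is not flagged. The boundary choice is logged on
the flag object.

**Seasoning inclusion.** The fraction of decompositions including salt,
pepper or sugar with an explicit positive mass, matched on normalized
whole words (so "black pepper" counts, "bell peppers" does not). The
denominator defaults to the compounds decomposed by *every* backend under
comparison, making the rates comparable across backends; rates round
half-up to one decimal.

**Macronutrient summaries.** Median and 25th/75th percentiles per nutrient
across compound totals, with percentiles computed by linear interpolation
(base `quantile()` type 7) — IQR conventions differ across software, so
the method is fixed and stated.

## Identification metrics and inference

Predicted compound sets are compared to rater ground truth after name
normalization (trim, collapse whitespace, case-fold; parenthetical
qualifiers are *kept*, because salad variants that differ only in their
qualifier are genuinely distinct ingredients). Per plan:
accuracy `(tp+tn)/n`, precision, recall, and F1 as their harmonic mean.
Zero-denominator conventions keep plans with no compound ingredients
scored: undefined precision becomes 1 when `fn = 0` and 0 otherwise
(symmetrically for recall), and each use of a convention is flagged on the
result. A predicted name that resolves to no plan ingredient counts as a
false positive with a warning — dropping hallucinations would inflate
precision.

Mean scores carry two-sided Student-t intervals (the per-plan score count
is small, typically 15, and no other interval method is stated
authoritatively; a bootstrap is easy to add behind the same interface).
Pairwise backend comparisons are gated by a Shapiro–Wilk test on the
paired differences at α = 0.05: normality not rejected → paired *t*;
rejected → Wilcoxon signed-rank. The signed-rank test uses the normal
approximation (`exact = FALSE`) throughout: seeded synthetic score vectors
routinely contain ties and zeros, where the exact distribution is
unavailable anyway, and a single method keeps runs deterministic. Two
degenerate cases are defined rather than errors: all-zero differences
return `p = 1` with no test run (normality of a constant is undefined),
and constant non-zero differences fall through to the signed-rank branch.
Scores are pooled across raters by concatenating aligned per-plan scores
(3 raters × 15 plans = 45 pairs); per-rater tables are also produced. No
multiple-testing correction is applied by default, matching the design
being emulated; `stats::p.adjust` composes trivially for users who want
Holm adjustment. Macronutrient agreement across backends uses classical
equal-variance one-way ANOVA.

## The synthetic generator

The generator defines the study conditions; it is not a tuning dial.
Defaults: 15 plans, 5–9 ingredients each (about a hundred ingredient
slots), compound prevalence 0.32, three raters agreeing with the
generating truth. Compound dishes come from a built-in lexicon of 30
dishes with hand-written part fractions over a pool of ~60 basic
ingredients; portions sit on a 10 g grid (120–400 g) and reference
decompositions split the portion by the dish's fractions into whole grams
that sum *exactly* to the portion (largest-remainder rounding, 1 g floor)
— mass conservation holds by construction, so any violation downstream is
attributable to the configured error model.

Simulated backends predict each true compound with probability
`sensitivity` and falsely flag each basic with probability
`1 − specificity`; predicted masses are perturbed by `none`,
`additive_noise(sd_g)` or `systematic_overestimate(fraction)`, rounded to
whole grams with a 1 g floor; seasonings are added with a configured
probability. The default three-backend roster (0.95/0.95, 0.90/0.93,
0.70/0.85, with increasing mass noise and seasoning rates) mirrors the
structure of a two-strong-models-one-weak comparison. A single master
seed derives all per-stage seeds by fixed offsets, so stages are
individually reproducible without user-side seed bookkeeping.

What the generator does *not* emulate: real culinary variety beyond the
lexicon, nutritionally authoritative composition panels, rater
disagreement structure beyond independent label flips, and the
failure modes of real language models other than the four modeled ones
(miss, false flag, mass error, malformed payload). Passing tests
therefore demonstrate that the measurement machinery is correct and that
known signal is recovered — not that any particular real model performs
at any particular level.

## Numerical and design choices

* Percentages report with half-up rounding to one decimal (base `round()`
  rounds half to even, which breaks printed-rate conventions like
  4/31 → 12.9).
* Quantity parsing accepts `g/gram(s)`, `dL`, `mL`, `cup(s)`,
  `slice(s)`, `piece(s)`; bare numbers parse as grams with a warning
  rather than failing a whole row, since dropped units are the most common
  drift in model output. Negative masses are hard errors. Decimal
  separator is the dot, locale-independent.
* Unparseable table rows are collected and warned about, never silently
  dropped; row counts are conserved (items + unparseable = data rows).
* Extra `<table>` elements: first one wins, with a warning.
* Stage intermediates persist as one JSON document per stage plus a
  manifest (`jsonlite::serializeJSON`, full precision), which round-trips
  R objects exactly; the report stage re-run from disk is bit-identical.
* Problem sizes in the shipped tests: worked examples run at their printed
  sizes; oracle-equivalence suites use 1,000 random small plans; the
  metric-recovery run uses 200 plans × 20 ingredients, where the
  Monte-Carlo standard error of mean accuracy is ≈ 0.005, comfortably
  resolving the 0.9 target.

## Known limitations

* Fixture-store search is a substring match; live repository search
  ranking is opaque and may surface different candidate subsets.
* The payload grammar recovers the dictionary styles observed in practice
  but not arbitrary free-form answers; unparseable payloads fail loudly
  by design.
* Seasoning matching is lexical (word-boundary on a fixed set); it does
  not recognise, e.g., "soy sauce" as a sodium source.
* Live mode is a contract (backend function + pacing), not a shipped
  client.
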