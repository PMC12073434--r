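# mealdecomp

Measurement tooling for a recurring problem in nutrition informatics:
meal plans name dishes ("Chicken Marsala, 200 g"), but nutrient profiling,
allergen screening and ingredient substitution need those *compound
ingredients* decomposed into *basic* ingredients with estimated masses, and
the basics matched to a food-composition repository. Language-model backends
can do the identification and decomposition, but their structured output
drifts and their mass estimates are unreliable — so the interesting question
is how to *measure* that behavior rigorously and reproducibly.

`mealdecomp` provides the whole apparatus, runnable fully offline:

* the HTML meal-plan table dialect (`Ingredient`, `Ingredient Details`,
  `Quantity`, `Portion Size (g, dL)`) with parser/serializer and
  quantity/unit handling (dL/mL → grams at configurable density);
* the three verbatim prompt templates (meal generation, decomposition,
  mapping), a backend contract, a deterministic seeded mock backend, and a
  robust parser for the dollar-delimited dictionary-of-dictionaries
  responses (mixed quoting styles, braceless inner dictionaries);
* a FoodData-Central-style composition store with the tiered subset policy
  (SR Legacy/Foundation → FNDDS → Experimental/Branded, sufficiency
  threshold 3), per-100 g nutrient retrieval, and the 3600/limit rate-limit
  contract for live clients;
* nutrient scaling/aggregation over ragged panels with coverage reporting;
* decomposition metrics: mass-conservation classification
  (match/exceeded/under at ε = 0.5 g), the strict >1.25 overestimation
  flag, seasoning-inclusion rates, macronutrient median/IQR summaries;
* the evaluation framework: per-plan confusion counts against rater ground
  truth, accuracy/precision/recall/F1 with t-intervals, Shapiro–Wilk-gated
  paired *t* / Wilcoxon signed-rank comparisons (α = 0.05), pooling across
  raters, one-way ANOVA;
* a synthetic generator with exact ground truth: labeled plans whose
  reference decompositions conserve mass by construction, simulated
  backends with configurable sensitivity/specificity/mass-error/seasoning
  behavior, and a fixture food store.

For identification, a backend predicting each true compound with
probability *s* (sensitivity) and passing over each basic with probability
*q* (specificity) at compound prevalence *π* has expected per-ingredient
accuracy *πs + (1−π)q*; the shipped metric-recovery checks verify the full
pipeline reproduces this to within Monte-Carlo error.

## Worked example

```r
library(mealdecomp)
report <- run_study(study_config(n_plans = 15, master_seed = 2))
report
```

```
Compound-ingredient identification study
  backends: model-large-a, model-large-b, model-small
  plans: 15, evaluators: 3, common compounds: 17

Accuracy (mean, CI):
  model-large-a  overall      0.990 (0.98-1.00)
  model-large-b  overall      0.931 (0.90-0.96)
  model-small    overall      0.828 (0.77-0.89)
...
Mass conservation (match / exceeded / under):
  model-large-a  89% / 11% / 0%
  model-large-b  8% / 62% / 29%
  model-small    0% / 52% / 48%
...
Pairwise comparisons:
  accuracy model-large-a vs model-small    wilcoxon p = 1.83e-05
```

(per-evaluator rows elided). The three mock backends emulate two strong
models and a weaker one: the overall rows are means over 45 pooled
plan-scores (15 plans × 3 raters) with 95% t-intervals; mass-conservation
fractions show how the configured mass-error models surface as
exceeded/under classifications; the pairwise rows report the
normality-gated test actually chosen and its two-sided p-value. With these
settings the weak backend is significantly worse than both strong ones at
α = 0.05.

Smaller pieces work standalone, e.g. the worked mass-conservation example:

```r
d <- decomposition("Grilled Vegetable Frittata",
  c(Eggs = 100, `Bell Peppers` = 75, Onions = 40, Zucchini = 65,
    `Cheddar Cheese` = 28, `Herbs (parsley, basil)` = 4))
classify_mass(150, decomposition_total_g(d))$excess_g  # 162
flag_overestimation(150, 312)$ratio                    # 2.08 -> flagged
```

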