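Package: mealdecomp
Title: Compound-Ingredient Decomposition and Nutrient Evaluation for Meal Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how language-model backends identify and decompose
    compound ingredients (dishes such as Chicken Marsala) in structured meal plans.
    Provides the HTML meal-plan table dialect and its parser, verbatim prompt
    templates with a deterministic mock backend, robust parsing of
    delimiter-encoded model responses, a food-composition store with a
    data-type priority hierarchy for subset creation, per-100 g nutrient scaling
    and aggregation, mass-conservation and seasoning analyses, and an evaluation
    framework (accuracy and F1 with confidence intervals, Shapiro-Wilk-gated
    paired tests, one-way ANOVA). A synthetic-data generator with known ground
    truth drives the full pipeline offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
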