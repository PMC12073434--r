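# Shared fixture builders: everything is constructed in code at test time.

# Six-record store exercising all tiers for the "blueberries" query plus an
# unrelated record.
tiny_store <- function() {
  food_store(list(
    food_record(101, "Blueberries, raw", "SR Legacy",
                nutrients = c(protein = 0.7, fat = 0.3, carbohydrate = 14.5, fiber = 2.4)),
    food_record(102, "Blueberries, frozen", "SR Legacy",
                nutrients = c(protein = 0.5, fat = 0.2, carbohydrate = 12.0, fiber = 2.1)),
    food_record(103, "Blueberries, wild", "Foundation",
                nutrients = c(protein = 0.6, fat = 0.4, carbohydrate = 12.2, fiber = 2.8)),
    food_record(104, "Blueberries, canned", "FNDDS",
                nutrients = c(protein = 0.6, fat = 0.3, carbohydrate = 20.1, fiber = 1.9)),
    food_record(105, "Blueberries, brand X muffin mix", "Branded",
                nutrients = c(protein = 4, fat = 8, carbohydrate = 60, fiber = 2)),
    food_record(106, "Chicken breast, raw", "SR Legacy",
                nutrients = c(protein = 22.5, fat = 2.6, carbohydrate = 0, fiber = 0))
  ))
}

# Plan with a mix of compound and basic items.
tiny_plan <- function() {
  meal_plan("dinner", list(
    meal_item("Chicken Marsala", 200, details = "with mushrooms"),
    meal_item("Vegetable Ratatouille", 180),
    meal_item("blueberries", 50, quantity = quantity(0.5, "cup")),
    meal_item("milk", 200)
  ), plan_id = "fixture-plan")
}

tiny_truth <- function(evaluator = "e1") {
  ground_truth_labels(evaluator, "fixture-plan", c(
    "Chicken Marsala" = "compound", "Vegetable Ratatouille" = "compound",
    "blueberries" = "basic", "milk" = "basic"
  ))
}

# Independent brute-force confusion oracle: direct set enumeration, no
# package confusion() internals.
oracle_confusion <- function(labels, predicted) {
  nm <- tolower(trimws(gsub("\\s+", " ", names(labels))))
  pred <- unique(tolower(trimws(gsub("\\s+", " ", predicted))))
  comp <- nm[unname(labels) == "compound"]
  basic <- nm[unname(labels) == "basic"]
  list(tp = length(intersect(comp, pred)),
       fp = length(intersect(basic, pred)) + length(setdiff(pred, nm)),
       fn = length(setdiff(comp, pred)),
       tn = length(setdiff(basic, pred)))
}

expect_mealdecomp_error <- function(expr, class) {
  expect_error(expr, class = class)
}
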