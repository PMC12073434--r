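test_that("quantity strings parse with unit normalization and conversions", {
  cases <- list(
    list(txt = "50 g", mag = 50, unit = "g", mass = 50),
    list(txt = "0 g", mag = 0, unit = "g", mass = 0),
    list(txt = "2 dL", mag = 2, unit = "dL", mass = 200),
    list(txt = "30 mL", mag = 30, unit = "mL", mass = 30),
    list(txt = "1.5 cups", mag = 1.5, unit = "cup", mass = NA_real_),
    list(txt = "2 slices", mag = 2, unit = "slice", mass = NA_real_),
    list(txt = "120 grams", mag = 120, unit = "g", mass = 120)
  )
  for (cs in cases) {
    q <- parse_quantity(cs$txt)
    expect_equal(q$magnitude, cs$mag, info = cs$txt)
    expect_equal(q$unit, cs$unit, info = cs$txt)
    expect_equal(quantity_to_mass_g(q), cs$mass, info = cs$txt)
  }
  # density applies to volumes only
  expect_equal(quantity_to_mass_g(parse_quantity("2 dL"), density_g_per_ml = 1.03), 206)
  expect_equal(quantity_to_mass_g(parse_quantity("50 g"), density_g_per_ml = 1.03), 50)
})

test_that("bare numbers parse as grams with a warning; bad input is typed", {
  expect_warning(q <- parse_quantity("75"), class = "mealdecomp_unit_warning")
  expect_equal(q$unit, "g")
  expect_equal(q$magnitude, 75)
  expect_error(parse_quantity("abc g"), class = "mealdecomp_parse_error")
  expect_error(parse_quantity("5 furlongs"), class = "mealdecomp_parse_error")
  expect_error(parse_quantity("-5 g"), class = "mealdecomp_value_error")
  expect_error(parse_quantity(""), class = "mealdecomp_parse_error")
})

test_that("name normalization trims, collapses and case-folds but keeps qualifiers", {
  expect_equal(normalize_ingredient_name("  Chicken   Marsala "), "chicken marsala")
  a <- normalize_ingredient_name("Mixed Greens Salad (with lemon vinaigrette)")
  b <- normalize_ingredient_name("Mixed Greens Salad")
  expect_false(a == b)
})

test_that("a one-row table parses to one item with the portion in grams", {
  html <- paste0(
    "<table><tr><th>Ingredient</th><th>Ingredient Details</th>",
    "<th>Quantity</th><th>Portion Size (g, dL)</th></tr>",
    "<tr><td>Chicken Marsala</td><td>with mushrooms</td><td>1 cup</td>",
    "<td>200 g</td></tr></table>")
  plan <- parse_meal_plan(html, meal_type = "dinner")
  expect_length(plan$items, 1)
  expect_equal(plan$items[[1]]$name, "Chicken Marsala")
  expect_equal(plan$items[[1]]$portion_mass_g, 200)
  expect_equal(plan$items[[1]]$quantity$unit, "cup")
  expect_equal(plan$items[[1]]$details, "with mushrooms")
})

test_that("header-only tables give empty plans; dL portions convert by density", {
  html <- paste0("<table><tr><th>Ingredient</th>",
                 "<th>Portion Size (g, dL)</th></tr></table>")
  expect_length(parse_meal_plan(html)$items, 0)

  html2 <- paste0("<table><tr><th>Ingredient</th><th>Portion Size (g, dL)</th></tr>",
                  "<tr><td>milk</td><td>2 dL</td></tr></table>")
  expect_equal(parse_meal_plan(html2)$items[[1]]$portion_mass_g, 200)
  expect_equal(parse_meal_plan(html2, density_g_per_ml = 1.03)$items[[1]]$portion_mass_g, 206)
})

test_that("structural failures raise typed errors; extra tables warn", {
  expect_error(parse_meal_plan("<p>no table</p>"), class = "mealdecomp_format_error")
  expect_error(
    parse_meal_plan("<table><tr><th>Food</th><th>Amount</th></tr></table>"),
    class = "mealdecomp_schema_error")
  two <- paste0(
    "<table><tr><th>Ingredient</th><th>Portion Size (g, dL)</th></tr>",
    "<tr><td>rice</td><td>100 g</td></tr></table>",
    "<table><tr><th>Ingredient</th><th>Portion Size (g, dL)</th></tr>",
    "<tr><td>pasta</td><td>80 g</td></tr></table>")
  expect_warning(plan <- parse_meal_plan(two), class = "mealdecomp_format_warning")
  expect_equal(plan$items[[1]]$name, "rice")
})

test_that("unparseable rows are reported, not dropped, and counts are conserved", {
  html <- paste0(
    "<table><tr><th>Ingredient</th><th>Portion Size (g, dL)</th></tr>",
    "<tr><td>rice</td><td>100 g</td></tr>",
    "<tr><td>mystery</td><td>some</td></tr>",       # unparseable portion
    "<tr><td></td><td>50 g</td></tr>",              # empty name
    "<tr><td>bread</td><td>2 slices</td></tr>",     # non-mass portion unit
    "<tr><td>pasta</td><td>80 g</td></tr></table>")
  expect_warning(plan <- parse_meal_plan(html), class = "mealdecomp_row_warning")
  unparsed <- attr(plan, "unparsed_rows")
  expect_equal(length(plan$items) + length(unparsed), 5)
  expect_equal(vapply(unparsed, `[[`, numeric(1), "row"), c(2, 3, 4))
})

test_that("negative masses are a hard value error", {
  html <- paste0("<table><tr><th>Ingredient</th><th>Portion Size (g, dL)</th></tr>",
                 "<tr><td>rice</td><td>-5 g</td></tr></table>")
  expect_error(parse_meal_plan(html), class = "mealdecomp_value_error")
})

test_that("write/parse round-trips generated plans and preserves order", {
  cfg <- simulation_config(n_plans = 6, seed = 302)
  ps <- generate_plan_set(cfg)
  for (plan in ps$plans) {
    html <- write_meal_plan(plan)
    re <- parse_meal_plan(html, plan$meal_type, plan$plan_id)
    expect_equal(plan_ingredients(re), plan_ingredients(plan))
    expect_equal(
      vapply(re$items, `[[`, numeric(1), "portion_mass_g"),
      vapply(plan$items, `[[`, numeric(1), "portion_mass_g"))
    # parse . write . parse is the identity on the parsed representation
    re2 <- parse_meal_plan(write_meal_plan(re), plan$meal_type, plan$plan_id)
    expect_identical(re2$items, re$items)
  }
  # order is significant: swapping items changes the serialization
  p <- tiny_plan()
  swapped <- meal_plan(p$meal_type, rev(p$items), p$plan_id)
  expect_false(identical(write_meal_plan(p), write_meal_plan(swapped)))
})

test_that("empty plans serialize to a header-only table", {
  html <- write_meal_plan(meal_plan("breakfast", list(), "empty"))
  expect_length(parse_meal_plan(html)$items, 0)
  expect_match(html, "Portion Size \\(g, dL\\)")
})
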