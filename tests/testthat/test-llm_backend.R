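test_that("templates match their golden files", {
  for (id in c("meal_generation", "decomposition", "mapping")) {
    golden <- readLines(test_path("fixtures", sprintf("prompt-%s.txt", id)),
                        encoding = "UTF-8", warn = FALSE)
    expect_identical(prompt_template(id), paste(golden, collapse = "\n"),
                     info = id)
  }
})

test_that("rendering substitutes every placeholder", {
  out <- render_prompt("meal_generation", list(
    meal_type = "breakfast", exclusion_list = character(0),
    html_format = "<table>...</table>"))
  expect_match(out, "breakfast", fixed = TRUE)
  expect_false(grepl("<INPUT", out, fixed = TRUE))
  # non-empty exclusion list renders comma-separated
  out2 <- render_prompt("meal_generation", list(
    meal_type = "lunch", exclusion_list = c("eggs", "milk"), html_format = "x"))
  expect_match(out2, "eggs, milk", fixed = TRUE)

  recs <- list(food_record(1, "Blueberries, raw", "SR Legacy"),
               food_record(2, "Blueberries, wild", "Foundation"))
  out3 <- render_prompt("mapping", list(food_item = "blueberries", food_list = recs))
  expect_match(out3, "Blueberries, raw", fixed = TRUE)
  expect_match(out3, "Blueberries, wild", fixed = TRUE)

  plan <- tiny_plan()
  out4 <- render_prompt("decomposition", list(meal_plan = plan))
  expect_match(out4, "<table>", fixed = TRUE)
  expect_match(out4, "Chicken Marsala", fixed = TRUE)

  expect_error(render_prompt("mapping", list(food_item = "x")),
               class = "mealdecomp_template_error")
})

test_that("payload extraction takes the first span and types its failures", {
  expect_equal(extract_delimited_payload("$21341$"), "21341")
  expect_equal(extract_delimited_payload("Sure! $x$ hope this helps"), "x")
  expect_equal(extract_delimited_payload("$a$ then $b$"), "a")
  expect_error(extract_delimited_payload("no delimiters here"),
               class = "mealdecomp_extraction_error")
  expect_error(extract_delimited_payload("unbalanced $only one"),
               class = "mealdecomp_extraction_error")
})

test_that("decomposition payloads parse across quoting styles", {
  canonical <- "{'Complex Food Item 1': {'Ingredient 1': '50 g', 'Ingredient 2': '100 g'}}"
  braceless <- "'Complex Food Item 1': 'Ingredient 1': '50 g', 'Ingredient 2': '100 g'"
  curly <- paste0("‘Complex Food Item 1’: ‘Ingredient 1’: ",
                  "‘50 g’, ‘Ingredient 2’: ‘100 g’")
  dbl <- '{"Complex Food Item 1": {"Ingredient 1": "50 g", "Ingredient 2": "100 g"}}'
  ref <- parse_decomposition_payload(canonical)
  expect_length(ref, 1)
  expect_equal(ref[[1]]$compound_name, "Complex Food Item 1")
  expect_equal(ref[[1]]$parts, c("Ingredient 1" = 50, "Ingredient 2" = 100))
  for (variant in list(braceless, curly, dbl)) {
    got <- parse_decomposition_payload(variant)
    expect_equal(got, ref, info = substr(variant, 1, 30))
  }
})

test_that("multi-compound braceless payloads split at the right boundaries", {
  payload <- paste0(
    "'Complex Food Item 1': 'Ingredient 1': '50 g', 'Ingredient 2': '100 g', ",
    "\"Complex Food Item 2\": 'Ingredient 1': '200 g', 'Ingredient 2': '150 g'")
  got <- parse_decomposition_payload(payload)
  expect_length(got, 2)
  expect_equal(got[[1]]$parts, c("Ingredient 1" = 50, "Ingredient 2" = 100))
  expect_equal(got[[2]]$parts, c("Ingredient 1" = 200, "Ingredient 2" = 150))
})

test_that("empty dictionaries and malformed payloads behave per contract", {
  expect_length(parse_decomposition_payload("{}"), 0)
  expect_length(parse_decomposition_payload("  { }  "), 0)
  expect_error(parse_decomposition_payload("'A': {'x': '0 g'}"),
               class = "mealdecomp_value_error")
  expect_error(parse_decomposition_payload("'A': {'x': 'twelve g'}"),
               class = "mealdecomp_parse_error")
  expect_error(parse_decomposition_payload("'A': {}"),
               class = "mealdecomp_parse_error")
  expect_error(parse_decomposition_payload("'A' 'B' 'C'"),
               class = "mealdecomp_parse_error")
})

test_that("parser is total: random payloads parse fully or raise typed errors", {
  set.seed(404)
  pieces <- c("'A'", ":", ",", "{", "}", "'50 g'", "'x'", "12", "\"B\"", " ")
  for (i in 1:300) {
    payload <- paste(sample(pieces, sample(1:12, 1), replace = TRUE), collapse = " ")
    res <- tryCatch(parse_decomposition_payload(payload),
                    mealdecomp_error = function(e) e)
    if (!inherits(res, "condition")) {
      for (d in res) {
        expect_s3_class(d, "decomposition")
        expect_true(length(d$parts) > 0 && all(d$parts > 0))
      }
    } else {
      expect_true(inherits(res, "mealdecomp_parse_error") ||
                    inherits(res, "mealdecomp_value_error"))
    }
  }
})

test_that("round trip: serialized decompositions reparse identically", {
  d1 <- decomposition("Chicken Marsala", c("chicken breast" = 110, "olive oil" = 10))
  d2 <- decomposition("Hummus", c("chickpeas" = 90, tahini = 22.5))
  got <- parse_decomposition_payload(format_decomposition_payload(list(d1, d2)))
  expect_equal(got, list(d1, d2))
  expect_equal(format_decomposition_payload(list()), "{}")
})

test_that("fdcId payloads parse numerically and reject junk", {
  expect_equal(parse_fdcid_payload("21341"), 21341)
  expect_equal(parse_fdcid_payload("  7  "), 7)
  expect_error(parse_fdcid_payload("abc"), class = "mealdecomp_parse_error")
  expect_error(parse_fdcid_payload("12a"), class = "mealdecomp_parse_error")
})

test_that("mock backend is deterministic and honours the malformed rate", {
  req <- list(kind = "mapping", prompt = "map blueberries", context = list(fdc_id = 101))
  r1 <- mock_backend(req, seed = 5)
  r2 <- mock_backend(req, seed = 5)
  expect_identical(r1$raw_text, r2$raw_text)
  expect_false(identical(r1$raw_text, mock_backend(req, seed = 6)$raw_text))

  dreq <- list(kind = "decomposition", prompt = "decompose",
               context = list(decompositions = list(
                 decomposition("Hummus", c(chickpeas = 60, tahini = 15)))))
  for (s in 1:25) {
    ok <- mock_backend(dreq, seed = s, malformed_rate = 0)
    expect_silent(extract_delimited_payload(ok$raw_text))
    bad <- mock_backend(dreq, seed = s, malformed_rate = 1)
    expect_error(extract_delimited_payload(bad$raw_text),
                 class = "mealdecomp_extraction_error")
  }
  # a well-formed decomposition response parses back to its context
  ok <- mock_backend(dreq, seed = 1)
  expect_equal(parse_decomposition_payload(ok$payload),
               dreq$context$decompositions)
})
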