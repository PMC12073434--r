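# Backend contract for the three prompt-driven steps (meal generation,
# compound-ingredient decomposition, database mapping): the verbatim prompt
# templates, rendering, robust parsing of the dollar-delimited responses,
# and a deterministic mock backend for offline runs.
#
# A backend is any function (model_name, prompt_text) -> response_text; the
# repository ships and tests only the seeded mock.

# Templates use curly typographic quotes where the originals do.
PROMPT_TEMPLATES <- list(
  meal_generation = list(
    text = paste0(
      "Create a detailed one-day <INPUT_meal_type> plan. Ensure the meal plan ",
      "includes precise portion sizes, specific quantities or weights of ",
      "individual ingredients, and diverse cooking methods. Include compound ",
      "ingredients like Chicken Cacciatore, Vegetable Ratatouille, or similar. ",
      "However, avoid including ingredients included in the following list: ",
      "<INPUT_list>, Structure the results in a formatted HTML format similar ",
      "to the provided example: <INPUT_html_format>."
    ),
    bindings = c(meal_type = "<INPUT_meal_type>", exclusion_list = "<INPUT_list>",
                 html_format = "<INPUT_html_format>")
  ),
  decomposition = list(
    text = paste0(
      "Analyze the meal plan provided in an HTML table (enclosed within ",
      "<table> and </table> tags): <INPUT_meal_plan>. Identify compound ",
      "ingredients listed under the ‘Ingredient’ column that consist ",
      "of multiple basic ingredients. Use the ‘Ingredient Details’ ",
      "column for additional information. For each identified compound ",
      "ingredient, report the names of these items along with their specific ",
      "ingredients and estimated quantities based on the ‘Portion Size ",
      "(g, dL)’ column, formatted in a dictionary of dictionaries. Ensure ",
      "all ingredients are specific (e.g., ‘carrots’, ",
      "‘spinach’, etc., instead of ‘vegetables’). If items ",
      "can be further broken down, do it. Example format: ‘Complex Food ",
      "Item 1’: ‘Ingredient 1’: ‘50 g’, ",
      "‘Ingredient 2’: ‘100 g’, “Complex Food Item ",
      "2”: ‘Ingredient 1’: ‘200 g’, ‘Ingredient ",
      "2’: ‘150 g’. Return only the formatted dictionary ",
      "encapsulated by dollar signs ($Content$). Dictionary should not contain ",
      "any comments. If no complex food items meeting the criteria are ",
      "identified, return an empty dictionary. Ensure that the quantities of ",
      "each ingredient accurately reflect the specified portion size within ",
      "each compound ingredient as detailed in the meal plan. For ingredients ",
      "where the exact quantity cannot be determined, provide a reasonable ",
      "estimate instead of leaving it unspecified."
    ),
    bindings = c(meal_plan = "<INPUT_meal_plan>")
  ),
  mapping = list(
    text = paste0(
      "You are tasked with matching a given ingredient <food_item> to the most ",
      "appropriate one from the following list of ingredients: ",
      "<list_of_food_items>. Each ingredient possesses unique characteristics ",
      "that influence its compatibility with others. Your objective is to ",
      "identify which ingredient from the list best complements the given one, ",
      "considering factors such as flavor profile, cooking methods, and ",
      "culinary traditions. Return only the ‘fdcId’ value of the best ",
      "match encapsulated in dollar signs (e.g., $21341$). Do not include any ",
      "comments."
    ),
    bindings = c(food_item = "<food_item>", food_list = "<list_of_food_items>")
  )
)

#' Prompt template text
#'
#' @param template_id one of `"meal_generation"`, `"decomposition"`, `"mapping"`.
#' @return the raw template string with its angle-bracket placeholders.
#' @export
prompt_template <- function(template_id) {
  tpl <- PROMPT_TEMPLATES[[match.arg(template_id, names(PROMPT_TEMPLATES))]]
  tpl$text
}

format_binding <- function(name, value) {
  if (name == "exclusion_list") {
    # empty exclusion list renders as an empty string
    return(paste(as.character(value), collapse = ", "))
  }
  if (name == "meal_plan" && inherits(value, "meal_plan")) {
    return(write_meal_plan(value))
  }
  if (name == "food_list" && is.list(value) && !inherits(value, "food_record")) {
    return(format_food_list(value))
  }
  if (inherits(value, "food_record")) return(format_food_list(list(value)))
  paste(as.character(value), collapse = ", ")
}

#' Render a prompt template
#'
#' Substitutes every placeholder of the template; residual placeholders are a
#' template error, as is a missing binding. Binding names per template:
#' * `meal_generation`: `meal_type`, `exclusion_list` (character vector;
#'   renders comma-separated, empty vector renders empty), `html_format`.
#' * `decomposition`: `meal_plan` (a [meal_plan()] object, serialized via
#'   [write_meal_plan()], or ready-made HTML text).
#' * `mapping`: `food_item`, `food_list` (a list of [food_record()]s,
#'   formatted as `fdcId: <id>, description: '<description>'` entries, or
#'   plain text).
#'
#' @param template_id template identifier.
#' @param bindings named list covering every placeholder.
#' @return rendered prompt text.
#' @export
render_prompt <- function(template_id, bindings = list()) {
  id <- match.arg(template_id, names(PROMPT_TEMPLATES))
  tpl <- PROMPT_TEMPLATES[[id]]
  missing <- setdiff(names(tpl$bindings), names(bindings))
  if (length(missing) > 0) {
    md_stop("mealdecomp_template_error", sprintf(
      "missing binding(s) for template '%s': %s", id, paste(missing, collapse = ", ")
    ))
  }
  out <- tpl$text
  for (nm in names(tpl$bindings)) {
    out <- gsub(tpl$bindings[[nm]], format_binding(nm, bindings[[nm]]),
                out, fixed = TRUE)
  }
  leftovers <- grepl("<INPUT", out, fixed = TRUE) ||
    any(vapply(PROMPT_TEMPLATES, function(t) any(vapply(
      t$bindings, grepl, logical(1), x = out, fixed = TRUE
    )), logical(1)))
  if (leftovers) {
    md_stop("mealdecomp_template_error",
            sprintf("unsubstituted placeholder remains in rendered '%s' prompt", id))
  }
  out
}

format_food_list <- function(records) {
  entries <- vapply(records, function(r) {
    sprintf("fdcId: %s, description: '%s'", num_chr(r$fdc_id), r$description)
  }, character(1))
  paste(entries, collapse = "; ")
}

#' Extract the first dollar-delimited payload from a raw response
#'
#' Model responses are asked to encapsulate their answer in dollar signs
#' (`$Content$`); surrounding commentary is discarded. If several spans are
#' present the first wins. Zero or unbalanced delimiters raise an extraction
#' error naming the pipeline step.
#'
#' @param raw raw response text.
#' @param step label used in the error message (e.g. `"decomposition"`).
#' @return the inner payload text.
#' @examples
#' extract_delimited_payload("Sure! $21341$ hope this helps")
#' @export
extract_delimited_payload <- function(raw, step = "response") {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw)) {
    md_stop("mealdecomp_extraction_error",
            sprintf("%s: raw response is not a string", step))
  }
  n_dollar <- lengths(regmatches(raw, gregexpr("$", raw, fixed = TRUE)))
  if (n_dollar < 2) {
    md_stop("mealdecomp_extraction_error", sprintf(
      "%s: expected a $-delimited payload, found %d delimiter(s)", step, n_dollar
    ))
  }
  m <- regmatches(raw, regexpr("\\$([^$]*)\\$", raw))
  substr(m, 2, nchar(m) - 1)
}

# Lenient variant used inside the pipeline: an already-extracted payload
# (no delimiter present) passes through unchanged, making extraction
# idempotent along the internal path.
maybe_extract_payload <- function(text, step = "response") {
  if (grepl("$", text, fixed = TRUE)) extract_delimited_payload(text, step) else text
}

#' Construct a decomposition (compound -> basic parts with masses)
#'
#' @param compound_name compound ingredient name.
#' @param parts named numeric vector of positive part masses in grams; names
#'   are basic-ingredient names.
#' @return an object of class `decomposition`.
#' @export
decomposition <- function(compound_name, parts) {
  if (!is.character(compound_name) || !nzchar(normalize_ingredient_name(compound_name))) {
    md_stop("mealdecomp_value_error", "compound_name must be non-empty")
  }
  if (length(parts) == 0) {
    md_stop("mealdecomp_value_error",
            sprintf("decomposition of '%s' has no parts", compound_name))
  }
  if (is.null(names(parts)) || any(!nzchar(names(parts)))) {
    md_stop("mealdecomp_value_error", "every part must be named")
  }
  if (any(!is.finite(parts)) || any(parts <= 0)) {
    md_stop("mealdecomp_value_error", sprintf(
      "decomposition of '%s' has a non-positive part mass", compound_name
    ))
  }
  structure(list(compound_name = compound_name, parts = parts),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %s (%s g total)\n",
              x$compound_name, num_chr(sum(x$parts))))
  for (nm in names(x$parts)) cat(sprintf("  - %s: %s g\n", nm, num_chr(x$parts[[nm]])))
  invisible(x)
}

#' Total decomposed mass of a decomposition
#' @param d a [decomposition()].
#' @return total part mass in grams.
#' @export
decomposition_total_g <- function(d) {
  stopifnot(inherits(d, "decomposition"))
  sum(d$parts)
}

# --- dictionary-of-dictionaries payload grammar ------------------------------
#
# The decomposition payload is a dictionary of dictionaries, but the prompt's
# example format is not valid JSON: quoting is inconsistent (straight or curly,
# single or double) and inner dictionaries may lack braces, e.g.
#   'Complex Food Item 1': 'Ingredient 1': '50 g', 'Ingredient 2': '100 g'
# The parser tokenizes quoted strings / punctuation and resolves the braceless
# form by lookahead: a key whose value is itself followed by ':' starts a new
# compound; a key whose value is a plain quantity string is a part of the
# current compound.

tokenize_payload <- function(payload) {
  s <- chartr("‘’“”", "''\"\"", payload)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("'", "\"")) {
      j <- i + 1L
      while (j <= n && chars[j] != ch) j <- j + 1L
      if (j > n) md_stop("mealdecomp_parse_error", "unterminated quoted string in payload")
      push("str", paste0(chars[seq.int(i + 1L, length.out = j - i - 1L)], collapse = ""))
      i <- j + 1L
    } else if (ch %in% c("{", "}", ":", ",")) {
      push("punct", ch)
      i <- i + 1L
    } else {
      # bare token: run up to the next structural character
      j <- i
      while (j <= n && !chars[j] %in% c("{", "}", ":", ",", "'", "\"")) j <- j + 1L
      val <- trimws(paste0(chars[i:(j - 1L)], collapse = ""))
      if (nzchar(val)) push("str", val)
      i <- j
    }
  }
  toks
}

#' Parse a decomposition payload (dictionary of dictionaries)
#'
#' Accepts both strict JSON-like dictionaries and the looser quoted-pair style
#' the decomposition prompt illustrates (single/double/typographic quotes,
#' optional braces around inner dictionaries). Quantity strings are parsed
#' with [parse_quantity()] and converted to grams. An empty dictionary yields
#' an empty list. The parser is total: it either returns valid
#' [decomposition()] objects or raises a typed parse/value error - never a
#' partially filled structure.
#'
#' @param payload extracted payload text (inside the dollar delimiters).
#' @return list of [decomposition()] objects.
#' @export
parse_decomposition_payload <- function(payload) {
  if (!is.character(payload) || length(payload) != 1 || is.na(payload)) {
    md_stop("mealdecomp_parse_error", "payload must be a string")
  }
  trimmed <- trimws(payload)
  if (trimmed == "" || gsub("\\s", "", trimmed) == "{}") return(list())
  toks <- tokenize_payload(trimmed)
  n <- length(toks)
  i <- 1L
  tok <- function(k = 0L) if (i + k <= n) toks[[i + k]] else NULL
  is_punct <- function(t, v) !is.null(t) && t$type == "punct" && t$value == v
  expect_str <- function(what) {
    t <- tok()
    if (is.null(t) || t$type != "str") {
      md_stop("mealdecomp_parse_error",
              sprintf("expected %s at token %d of payload", what, i))
    }
    i <<- i + 1L
    t$value
  }
  expect_colon <- function() {
    if (!is_punct(tok(), ":")) {
      md_stop("mealdecomp_parse_error", sprintf("expected ':' at token %d of payload", i))
    }
    i <<- i + 1L
  }
  skip_commas <- function() while (is_punct(tok(), ",")) i <<- i + 1L
  part_mass <- function(compound, name, value) {
    q <- tryCatch(suppressWarnings(parse_quantity(value)),
                  mealdecomp_parse_error = function(e) {
                    md_stop("mealdecomp_parse_error", sprintf(
                      "part '%s' of '%s': %s", name, compound, conditionMessage(e)))
                  })
    mass <- quantity_to_mass_g(q)
    if (is.na(mass)) {
      md_stop("mealdecomp_value_error", sprintf(
        "part '%s' of '%s' has non-mass unit '%s'", name, compound, q$unit))
    }
    if (mass <= 0) {
      md_stop("mealdecomp_value_error", sprintf(
        "part '%s' of '%s' has non-positive mass", name, compound))
    }
    mass
  }
  parse_braced_parts <- function(compound) {
    i <<- i + 1L  # consume '{'
    parts <- numeric(0)
    repeat {
      skip_commas()
      if (is_punct(tok(), "}")) { i <<- i + 1L; break }
      if (is.null(tok())) md_stop("mealdecomp_parse_error", "unterminated inner dictionary")
      nm <- expect_str("part name")
      expect_colon()
      val <- expect_str("part quantity")
      parts[nm] <- part_mass(compound, nm, val)
    }
    parts
  }

  if (is_punct(tok(), "{")) i <- i + 1L
  out <- list()
  repeat {
    skip_commas()
    t <- tok()
    if (is.null(t) || is_punct(t, "}")) break
    compound <- expect_str("compound name")
    expect_colon()
    if (is_punct(tok(), "{")) {
      parts <- parse_braced_parts(compound)
    } else {
      # braceless inner dictionary, resolved by lookahead
      parts <- numeric(0)
      repeat {
        nm <- expect_str("part name")
        expect_colon()
        val <- expect_str("part quantity")
        parts[nm] <- part_mass(compound, nm, val)
        skip_commas()
        t2 <- tok()
        if (is.null(t2) || is_punct(t2, "}")) break
        # next pair: STRING ':' STRING ':' means a new compound begins
        if (t2$type == "str" && is_punct(tok(1L), ":") &&
            !is.null(tok(2L)) && tok(2L)$type == "str" && is_punct(tok(3L), ":")) break
        if (!(t2$type == "str" && is_punct(tok(1L), ":"))) {
          md_stop("mealdecomp_parse_error",
                  sprintf("unexpected token after parts of '%s'", compound))
        }
      }
    }
    if (length(parts) == 0) {
      md_stop("mealdecomp_parse_error",
              sprintf("compound '%s' has an empty part dictionary", compound))
    }
    out[[length(out) + 1L]] <- decomposition(compound, parts)
    skip_commas()
  }
  out
}

#' Parse an fdcId payload
#'
#' @param payload extracted payload text; must be a (whitespace-tolerant)
#'   non-negative integer.
#' @return the identifier as a numeric scalar.
#' @examples
#' parse_fdcid_payload("21341")
#' @export
parse_fdcid_payload <- function(payload) {
  s <- trimws(payload)
  if (!grepl("^[0-9]+$", s)) {
    md_stop("mealdecomp_parse_error",
            sprintf("fdcId payload is not numeric: %s", dQuote(s, FALSE)))
  }
  as.numeric(s)
}

#' Serialize decompositions to the payload dictionary style
#'
#' Inverse of [parse_decomposition_payload()] (up to quoting style); used by
#' the mock backend. Empty input serializes to `"{}"`.
#'
#' @param decomps list of [decomposition()] objects.
#' @return payload text.
#' @export
format_decomposition_payload <- function(decomps) {
  if (length(decomps) == 0) return("{}")
  entries <- vapply(decomps, function(d) {
    parts <- vapply(names(d$parts), function(nm) {
      sprintf("'%s': '%s g'", nm, num_chr(d$parts[[nm]]))
    }, character(1))
    sprintf("'%s': {%s}", d$compound_name, paste(parts, collapse = ", "))
  }, character(1))
  paste0("{", paste(entries, collapse = ", "), "}")
}

CHATTER_PREFIX <- c(
  "", "Sure! Here is the result: ", "Certainly. ",
  "Here is the requested output:\n", "Of course! "
)
CHATTER_SUFFIX <- c(
  "", " Hope this helps!", "\nLet me know if you need anything else.", " Done."
)

#' Deterministic mock backend
#'
#' Offline stand-in for a live language-model endpoint. The request carries
#' the rendered prompt plus structured context (the answer the simulation
#' wants returned); the mock wraps that answer in the dollar-delimited payload
#' format, surrounded by deterministic conversational chatter. Responses are
#' byte-identical for identical `(request, seed)`. A configurable
#' `malformed_rate` makes the mock emit responses without delimiters, for
#' parser-robustness tests.
#'
#' @param request list with fields `kind` (one of `"meal_generation"`,
#'   `"decomposition"`, `"mapping"`), `prompt` (rendered prompt text) and
#'   `context` (for `decomposition`: `context$decompositions`, a list of
#'   [decomposition()]; for `mapping`: `context$fdc_id`; for
#'   `meal_generation`: `context$plan`, a [meal_plan()]).
#' @param seed integer seed.
#' @param malformed_rate probability in `[0, 1]` of emitting a response with
#'   no delimiters.
#' @return object of class `backend_response` with fields `raw_text` and
#'   `payload` (`NULL` when no delimiters are present).
#' @export
mock_backend <- function(request, seed, malformed_rate = 0) {
  stopifnot(is.list(request), !is.null(request$kind), !is.null(request$prompt))
  kind <- match.arg(request$kind, c("meal_generation", "decomposition", "mapping"))
  payload <- switch(kind,
    meal_generation = write_meal_plan(request$context$plan),
    decomposition = format_decomposition_payload(request$context$decompositions),
    mapping = num_chr(request$context$fdc_id)
  )
  req_seed <- combine_seed(seed, string_seed(paste0(kind, "\r", request$prompt)))
  with_seed(req_seed, {
    pre <- sample(CHATTER_PREFIX, 1)
    post <- sample(CHATTER_SUFFIX, 1)
    malformed <- runif(1) < malformed_rate
    raw <- if (malformed) {
      paste0(pre, gsub("$", "", payload, fixed = TRUE), post)
    } else {
      paste0(pre, "$", payload, "$", post)
    }
    backend_response(raw)
  })
}

#' Construct a backend response
#'
#' @param raw_text full response text.
#' @return object of class `backend_response`; `payload` holds the first
#'   dollar-delimited span if one exists, else `NULL`.
#' @export
backend_response <- function(raw_text) {
  payload <- tryCatch(extract_delimited_payload(raw_text),
                      mealdecomp_extraction_error = function(e) NULL)
  structure(list(raw_text = raw_text, payload = payload), class = "backend_response")
}

#' @export
print.backend_response <- function(x, ...) {
  cat("<backend_response>",
      if (is.null(x$payload)) "(no payload)" else "(payload present)", "\n")
  cat(substr(x$raw_text, 1, 200), "\n")
  invisible(x)
}
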