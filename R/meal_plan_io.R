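# Meal-plan data model and the HTML table dialect shared by all prompts.
# A plan is an ordered set of items; each item carries an optional household
# measure (cups, slices, ...) and a portion mass in grams. Liquid portions
# given in dL/mL are converted to grams with a configurable density
# (1 g/mL by default, i.e. water-like).

QUANTITY_UNITS <- c("g", "dL", "cup", "slice", "piece", "mL")
MASS_UNITS <- c("g", "dL", "mL")
MEAL_TYPES <- c("breakfast", "lunch", "dinner")

#' Construct a quantity (magnitude + unit)
#'
#' @param magnitude non-negative number.
#' @param unit one of `"g"`, `"dL"`, `"cup"`, `"slice"`, `"piece"`, `"mL"`.
#' @return an object of class `quantity` with fields `magnitude` and `unit`.
#' @seealso [parse_quantity()], [quantity_to_mass_g()]
#' @export
quantity <- function(magnitude, unit) {
  if (!is.numeric(magnitude) || length(magnitude) != 1 || is.na(magnitude)) {
    md_stop("mealdecomp_value_error", "quantity magnitude must be a single number")
  }
  if (magnitude < 0) {
    md_stop("mealdecomp_value_error", "quantity magnitude must be non-negative")
  }
  if (!is.character(unit) || length(unit) != 1 || !unit %in% QUANTITY_UNITS) {
    md_stop("mealdecomp_value_error", sprintf(
      "unit must be one of: %s", paste(QUANTITY_UNITS, collapse = ", ")
    ))
  }
  structure(
    list(magnitude = as.numeric(magnitude), unit = unit,
         mass_convertible = unit %in% MASS_UNITS),
    class = "quantity"
  )
}

#' @export
print.quantity <- function(x, ...) {
  cat(sprintf("<quantity> %s %s\n", num_chr(x$magnitude), x$unit))
  invisible(x)
}

#' Parse a quantity string such as "50 g" or "2 dL"
#'
#' Recognised unit spellings: `g`/`gram`/`grams`, `dl`, `ml`, `cup(s)`,
#' `slice(s)`, `piece(s)` (case-insensitive). A bare number is interpreted as
#' grams with a warning, since model output frequently drops the unit.
#'
#' @param text a single non-empty string.
#' @return a [quantity()].
#' @examples
#' parse_quantity("50 g")
#' parse_quantity("2 dL")
#' @export
parse_quantity <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    md_stop("mealdecomp_parse_error", "quantity text must be a non-empty string")
  }
  s <- trimws(text)
  m <- regmatches(s, regexec(
    "^(-?)([0-9]+(?:\\.[0-9]+)?)\\s*([A-Za-z]*)\\.?$", s
  ))[[1]]
  if (length(m) == 0) {
    md_stop("mealdecomp_parse_error",
            sprintf("cannot parse quantity from %s", dQuote(s, FALSE)))
  }
  if (m[2] == "-") {
    md_stop("mealdecomp_value_error",
            sprintf("negative quantity not allowed: %s", dQuote(s, FALSE)))
  }
  mag <- as.numeric(m[3])
  unit_raw <- tolower(m[4])
  if (unit_raw == "") {
    md_warn("mealdecomp_unit_warning",
            sprintf("no unit in %s; assuming grams", dQuote(s, FALSE)))
    unit_raw <- "g"
  }
  unit <- switch(unit_raw,
    "g" = , "gram" = , "grams" = "g",
    "dl" = "dL",
    "ml" = "mL",
    "cup" = , "cups" = "cup",
    "slice" = , "slices" = "slice",
    "piece" = , "pieces" = "piece",
    md_stop("mealdecomp_parse_error",
            sprintf("unknown unit %s in %s", dQuote(unit_raw, FALSE), dQuote(s, FALSE)))
  )
  quantity(mag, unit)
}

#' Convert a mass-convertible quantity to grams
#'
#' Grams pass through; mL and dL are converted with the given density
#' (default 1 g/mL). Household measures (cup, slice, piece) are not
#' mass-convertible and return `NA`.
#'
#' @param q a [quantity()].
#' @param density_g_per_ml density used for liquid volumes, grams per mL.
#' @return mass in grams, or `NA_real_` for non-mass units.
#' @export
quantity_to_mass_g <- function(q, density_g_per_ml = 1) {
  stopifnot(inherits(q, "quantity"))
  switch(q$unit,
    g = q$magnitude,
    mL = q$magnitude * density_g_per_ml,
    dL = q$magnitude * 100 * density_g_per_ml,
    NA_real_
  )
}

#' Construct a meal item
#'
#' @param name ingredient name (non-empty after whitespace normalization).
#' @param portion_mass_g portion mass in grams, `>= 0`.
#' @param quantity optional [quantity()] household measure.
#' @param details optional free-text details.
#' @return an object of class `meal_item`.
#' @export
meal_item <- function(name, portion_mass_g, quantity = NULL, details = NULL) {
  if (!is.character(name) || length(name) != 1 ||
      !nzchar(normalize_ingredient_name(name))) {
    md_stop("mealdecomp_value_error", "meal item name must be non-empty")
  }
  if (!is.numeric(portion_mass_g) || length(portion_mass_g) != 1 ||
      is.na(portion_mass_g) || portion_mass_g < 0) {
    md_stop("mealdecomp_value_error", "portion_mass_g must be a non-negative number")
  }
  if (!is.null(quantity)) stopifnot(inherits(quantity, "quantity"))
  structure(
    list(name = name, portion_mass_g = as.numeric(portion_mass_g),
         quantity = quantity, details = details),
    class = "meal_item"
  )
}

#' Construct a meal plan
#'
#' @param meal_type one of `"breakfast"`, `"lunch"`, `"dinner"`.
#' @param items list of [meal_item()] objects (may be empty).
#' @param plan_id identifier string.
#' @return an object of class `meal_plan`.
#' @export
meal_plan <- function(meal_type, items = list(), plan_id = "plan-1") {
  if (!meal_type %in% MEAL_TYPES) {
    md_stop("mealdecomp_value_error", sprintf(
      "meal_type must be one of: %s", paste(MEAL_TYPES, collapse = ", ")
    ))
  }
  stopifnot(is.list(items))
  for (it in items) stopifnot(inherits(it, "meal_item"))
  structure(
    list(meal_type = meal_type, items = items, plan_id = as.character(plan_id)),
    class = "meal_plan"
  )
}

#' @export
print.meal_plan <- function(x, ...) {
  cat(sprintf("<meal_plan> %s (%s), %d item(s)\n",
              x$plan_id, x$meal_type, length(x$items)))
  for (it in x$items) {
    cat(sprintf("  - %s: %s g\n", it$name, num_chr(it$portion_mass_g)))
  }
  invisible(x)
}

#' Ingredient names of a plan
#' @param plan a [meal_plan()].
#' @return character vector in document order.
#' @export
plan_ingredients <- function(plan) {
  stopifnot(inherits(plan, "meal_plan"))
  vapply(plan$items, `[[`, character(1), "name")
}

match_header <- function(headers) {
  h <- tolower(trimws(headers))
  ing <- which(h == "ingredient")
  det <- grep("detail", h)
  qty <- setdiff(grep("quantit", h), grep("portion", h))
  por <- grep("portion", h)
  list(
    ingredient = if (length(ing)) ing[1] else NA_integer_,
    details    = if (length(det)) det[1] else NA_integer_,
    quantity   = if (length(qty)) qty[1] else NA_integer_,
    portion    = if (length(por)) por[1] else NA_integer_
  )
}

#' Parse a meal plan from its HTML table dialect
#'
#' The dialect is a single `<table>` whose header row names at least an
#' `Ingredient` and a `Portion Size (g, dL)` column; `Ingredient Details`
#' and `Quantity` columns are optional. One [meal_item()] is produced per
#' data row, in document order. Portion masses are parsed to grams; dL/mL
#' volumes are converted with `density_g_per_ml`. Rows that cannot be
#' parsed (empty name, non-mass portion unit, unparseable portion text) are
#' reported in the `unparsed_rows` attribute and via a warning - never
#' silently dropped.
#'
#' @param html_text HTML text containing exactly one table (extra tables are
#'   ignored with a warning; the first wins).
#' @param meal_type,plan_id metadata for the returned plan (the table dialect
#'   itself does not carry them).
#' @param density_g_per_ml density for converting dL/mL portions to grams.
#' @return a [meal_plan()]; attribute `unparsed_rows` is a list of
#'   `list(row, reason)` records for rows that could not be parsed.
#' @export
parse_meal_plan <- function(html_text, meal_type = "lunch", plan_id = "plan-1",
                            density_g_per_ml = 1) {
  doc <- tryCatch(xml2::read_html(html_text),
                  error = function(e) md_stop("mealdecomp_format_error",
                    paste("cannot read HTML:", conditionMessage(e))))
  tables <- xml2::xml_find_all(doc, ".//table")
  if (length(tables) == 0) {
    md_stop("mealdecomp_format_error", "no <table> element found in input")
  }
  if (length(tables) > 1) {
    md_warn("mealdecomp_format_warning",
            sprintf("%d tables found; using the first", length(tables)))
  }
  rows <- xml2::xml_find_all(tables[[1]], ".//tr")
  if (length(rows) == 0) {
    md_stop("mealdecomp_schema_error", "table has no rows")
  }
  header <- xml2::xml_text(xml2::xml_find_all(rows[[1]], "./th|./td"))
  cols <- match_header(header)
  if (is.na(cols$ingredient) || is.na(cols$portion)) {
    md_stop("mealdecomp_schema_error", paste(
      "table header must name an Ingredient and a Portion Size column; got:",
      paste(dQuote(header, FALSE), collapse = ", ")
    ))
  }
  items <- list()
  unparsed <- list()
  data_rows <- rows[-1]
  for (k in seq_along(data_rows)) {
    cells <- xml2::xml_text(xml2::xml_find_all(data_rows[[k]], "./td|./th"))
    get_cell <- function(i) if (!is.na(i) && i <= length(cells)) trimws(cells[i]) else ""
    name <- get_cell(cols$ingredient)
    portion_txt <- get_cell(cols$portion)
    if (!nzchar(normalize_ingredient_name(name))) {
      unparsed[[length(unparsed) + 1]] <- list(row = k, reason = "empty ingredient name")
      next
    }
    pq <- tryCatch(
      suppressWarnings(parse_quantity(portion_txt)),
      mealdecomp_parse_error = function(e) e,
      mealdecomp_value_error = function(e) e
    )
    if (inherits(pq, "mealdecomp_value_error")) {
      md_stop("mealdecomp_value_error",
              sprintf("row %d: %s", k, conditionMessage(pq)))
    }
    if (inherits(pq, "condition")) {
      unparsed[[length(unparsed) + 1]] <-
        list(row = k, reason = paste("portion:", conditionMessage(pq)))
      next
    }
    mass <- quantity_to_mass_g(pq, density_g_per_ml)
    if (is.na(mass)) {
      unparsed[[length(unparsed) + 1]] <-
        list(row = k, reason = sprintf("portion unit %s is not a mass", pq$unit))
      next
    }
    qty <- NULL
    qtxt <- get_cell(cols$quantity)
    if (nzchar(qtxt)) {
      qty <- tryCatch(suppressWarnings(parse_quantity(qtxt)),
                      mealdecomp_error = function(e) NULL)
    }
    det <- get_cell(cols$details)
    items[[length(items) + 1]] <- meal_item(
      name = name, portion_mass_g = mass, quantity = qty,
      details = if (nzchar(det)) det else NULL
    )
  }
  if (length(unparsed) > 0) {
    md_warn("mealdecomp_row_warning",
            sprintf("%d row(s) could not be parsed (see attr 'unparsed_rows')",
                    length(unparsed)))
  }
  plan <- meal_plan(meal_type, items, plan_id)
  attr(plan, "unparsed_rows") <- unparsed
  plan
}

#' Serialize a meal plan to the HTML table dialect
#'
#' Emits the same dialect [parse_meal_plan()] accepts, with columns
#' `Ingredient`, `Ingredient Details`, `Quantity`, `Portion Size (g, dL)`.
#' Output is deterministic for equal inputs and preserves item order.
#'
#' @param plan a [meal_plan()].
#' @return a single HTML string.
#' @export
write_meal_plan <- function(plan) {
  stopifnot(inherits(plan, "meal_plan"))
  rows <- vapply(plan$items, function(it) {
    qty <- if (!is.null(it$quantity)) {
      paste(num_chr(it$quantity$magnitude), it$quantity$unit)
    } else ""
    paste0(
      "<tr><td>", html_escape(it$name), "</td><td>",
      html_escape(it$details %||% ""), "</td><td>",
      html_escape(qty), "</td><td>",
      num_chr(it$portion_mass_g), " g</td></tr>"
    )
  }, character(1))
  paste0(
    "<table>\n",
    "<tr><th>Ingredient</th><th>Ingredient Details</th>",
    "<th>Quantity</th><th>Portion Size (g, dL)</th></tr>\n",
    paste0(rows, collapse = "\n"), if (length(rows)) "\n" else "",
    "</table>"
  )
}
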