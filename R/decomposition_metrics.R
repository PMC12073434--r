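# Decomposition-quality analyses: does the summed mass of the basic parts
# conserve the compound's stated portion mass; which compounds were
# overestimated by more than a quarter of their base weight; how often are
# seasonings (salt, pepper, sugar) included with an explicit quantity; and
# macronutrient summary distributions (median + IQR) across compounds.

#' Classify mass conservation of a decomposition
#'
#' A decomposition `match`es when the summed part mass is within `epsilon`
#' grams of the compound's portion mass, has `exceeded` it when the excess is
#' greater than `epsilon`, and is `under` otherwise. The default half-gram
#' band treats integer-gram model output that reproduces the portion mass
#' exactly as a match.
#'
#' @param compound_mass_g stated portion mass of the compound (`> 0`).
#' @param parts_total_g summed mass of the decomposed parts.
#' @param epsilon tolerance in grams for an exact match (default 0.5).
#' @param compound_name optional name carried on the result.
#' @return object of class `mass_outcome` with fields `category` (one of
#'   `"match"`, `"exceeded"`, `"under"`) and `excess_g`
#'   (`parts_total_g - compound_mass_g`).
#' @examples
#' classify_mass(150, 312)  # exceeded by 162 g
#' @export
classify_mass <- function(compound_mass_g, parts_total_g, epsilon = 0.5,
                          compound_name = NA_character_) {
  if (!is.numeric(compound_mass_g) || length(compound_mass_g) != 1 ||
      is.na(compound_mass_g) || compound_mass_g <= 0) {
    md_stop("mealdecomp_value_error", "compound_mass_g must be positive")
  }
  if (!is.numeric(parts_total_g) || length(parts_total_g) != 1 ||
      is.na(parts_total_g) || parts_total_g < 0) {
    md_stop("mealdecomp_value_error", "parts_total_g must be non-negative")
  }
  if (!is.numeric(epsilon) || epsilon < 0) {
    md_stop("mealdecomp_value_error", "epsilon must be non-negative")
  }
  excess <- parts_total_g - compound_mass_g
  category <- if (abs(excess) <= epsilon) "match" else if (excess > epsilon) "exceeded" else "under"
  structure(
    list(compound_name = compound_name, compound_mass_g = compound_mass_g,
         parts_total_g = parts_total_g, category = category, excess_g = excess,
         epsilon = epsilon),
    class = "mass_outcome"
  )
}

#' Flag overestimation beyond a quarter of the base weight
#'
#' Flags a compound whose decomposed mass exceeds its portion mass by more
#' than one quarter, i.e. `parts_total_g / compound_mass_g > 1.25`. The
#' boundary is strict: a ratio of exactly 1.25 is not flagged.
#'
#' @inheritParams classify_mass
#' @param threshold flag ratio (default 1.25).
#' @return object of class `overestimation_flag` with fields `ratio` and
#'   `flagged`.
#' @export
flag_overestimation <- function(compound_mass_g, parts_total_g, threshold = 1.25,
                                compound_name = NA_character_) {
  if (!is.numeric(compound_mass_g) || length(compound_mass_g) != 1 ||
      is.na(compound_mass_g) || compound_mass_g <= 0) {
    md_stop("mealdecomp_value_error", "compound_mass_g must be positive")
  }
  ratio <- parts_total_g / compound_mass_g
  structure(
    list(compound_name = compound_name, ratio = ratio,
         flagged = ratio > threshold, threshold = threshold),
    class = "overestimation_flag"
  )
}

#' Seasoning-inclusion rate over a set of decompositions
#'
#' Counts decompositions that include at least one member of the seasoning
#' set with an explicit positive mass. Part names are matched on normalized
#' whole words, so "black pepper" counts as pepper. The rate is
#' `100 * n / denominator`, rounded half-up to one decimal.
#'
#' @param decompositions list of [decomposition()] objects.
#' @param seasoning_set seasoning words (default salt, pepper, sugar).
#' @param denominator positive count to rate against; conventionally the
#'   number of compound ingredients predicted by all models under
#'   comparison.
#' @return object of class `seasoning_report` with fields
#'   `n_included_with_quantity`, `denominator` and `rate` (percent).
#' @examples
#' d <- decomposition("Chicken Marsala", c("chicken breast" = 180, salt = 2))
#' seasoning_rate(list(d), denominator = 31)$rate  # 3.2
#' @export
seasoning_rate <- function(decompositions,
                           seasoning_set = c("salt", "pepper", "sugar"),
                           denominator) {
  if (!is.numeric(denominator) || length(denominator) != 1 ||
      is.na(denominator) || denominator <= 0) {
    md_stop("mealdecomp_value_error", "denominator must be positive")
  }
  for (d in decompositions) stopifnot(inherits(d, "decomposition"))
  pat <- paste0("\\b(", paste(tolower(seasoning_set), collapse = "|"), ")\\b")
  included <- vapply(decompositions, function(d) {
    nm <- normalize_ingredient_name(names(d$parts))
    any(grepl(pat, nm) & d$parts > 0)
  }, logical(1))
  n <- sum(included)
  structure(
    list(seasoning_set = seasoning_set,
         n_included_with_quantity = n,
         denominator = as.numeric(denominator),
         rate = round_half_up(100 * n / denominator, 1)),
    class = "seasoning_report"
  )
}

#' Median and IQR of macronutrient totals across compounds
#'
#' Percentiles use linear interpolation (base `quantile()` type 7), the
#' method stated in the report header. A nutrient absent from a compound's
#' total contributes 0, consistent with the absent-key convention of
#' [aggregate_compound()].
#'
#' @param totals non-empty list of [aggregate_compound()] results.
#' @param nutrients nutrient keys to summarize.
#' @return data frame with columns `nutrient`, `median`, `iqr_low` (25th
#'   percentile), `iqr_high` (75th percentile); attribute
#'   `percentile_method` records the interpolation rule.
#' @export
summarize_macronutrients <- function(totals,
                                     nutrients = c("protein", "fat",
                                                   "carbohydrate", "fiber")) {
  if (length(totals) == 0) {
    md_stop("mealdecomp_value_error", "totals must be non-empty")
  }
  for (t in totals) stopifnot(inherits(t, "compound_total"))
  rows <- lapply(nutrients, function(nu) {
    vals <- vapply(totals, function(t) {
      if (nu %in% names(t$amounts)) t$amounts[[nu]] else 0
    }, numeric(1))
    q <- quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(nutrient = nu, median = q[2], iqr_low = q[1], iqr_high = q[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "percentile_method") <- "linear interpolation (type 7)"
  out
}

#' Mass-conservation category fractions
#'
#' @param outcomes non-empty list of [classify_mass()] results.
#' @return named numeric vector of fractions `(match, exceeded, under)`
#'   summing to 1.
#' @export
match_rate_summary <- function(outcomes) {
  if (length(outcomes) == 0) {
    md_stop("mealdecomp_value_error", "outcomes must be non-empty")
  }
  for (o in outcomes) stopifnot(inherits(o, "mass_outcome"))
  cats <- vapply(outcomes, `[[`, character(1), "category")
  n <- length(cats)
  c(match = sum(cats == "match") / n,
    exceeded = sum(cats == "exceeded") / n,
    under = sum(cats == "under") / n)
}
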