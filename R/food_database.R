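# Food-composition store in the FoodData-Central style: records carry an
# fdcId, a description and a data type; nutrient profiles are stated per
# 100 g (or 100 mL for liquids). Subset creation follows a data-type trust
# hierarchy: curated reference data first (SR Legacy / Foundation), survey
# data (FNDDS) when the curated tiers are insufficient, and Experimental /
# Branded entries as a last resort.

FOOD_DATA_TYPES <- c("SR Legacy", "Foundation", "FNDDS", "Experimental", "Branded")

#' Construct a food record
#'
#' @param fdc_id positive integer identifier, unique within a store.
#' @param description text description of the food.
#' @param data_type one of `"SR Legacy"`, `"Foundation"`, `"FNDDS"`,
#'   `"Experimental"`, `"Branded"`.
#' @param nutrients optional named numeric vector of nutrient amounts per
#'   100 g (grams for macronutrients).
#' @return object of class `food_record`.
#' @export
food_record <- function(fdc_id, description, data_type, nutrients = NULL) {
  if (!is.numeric(fdc_id) || length(fdc_id) != 1 || is.na(fdc_id) || fdc_id <= 0 ||
      fdc_id != trunc(fdc_id)) {
    md_stop("mealdecomp_value_error", "fdc_id must be a positive integer")
  }
  if (!is.character(description) || !nzchar(trimws(description))) {
    md_stop("mealdecomp_value_error", "description must be non-empty")
  }
  if (!data_type %in% FOOD_DATA_TYPES) {
    md_stop("mealdecomp_value_error", sprintf(
      "data_type must be one of: %s", paste(FOOD_DATA_TYPES, collapse = ", ")))
  }
  if (!is.null(nutrients)) {
    nutrients <- unlist(nutrients)
    if (is.null(names(nutrients)) || any(!nzchar(names(nutrients)))) {
      md_stop("mealdecomp_value_error", "nutrients must be a named vector")
    }
    if (any(!is.finite(nutrients)) || any(nutrients < 0)) {
      md_stop("mealdecomp_value_error", "nutrient amounts must be non-negative")
    }
  }
  structure(
    list(fdc_id = as.numeric(fdc_id), description = description,
         data_type = data_type, nutrients = nutrients),
    class = "food_record"
  )
}

#' Construct a food store from a list of records
#'
#' @param records list of [food_record()] objects with unique `fdc_id`s.
#' @return object of class `food_store`.
#' @export
food_store <- function(records = list()) {
  for (r in records) stopifnot(inherits(r, "food_record"))
  ids <- vapply(records, `[[`, numeric(1), "fdc_id")
  if (anyDuplicated(ids)) {
    md_stop("mealdecomp_value_error", "fdc_id values must be unique within a store")
  }
  index <- data.frame(
    fdc_id = ids,
    description = vapply(records, `[[`, character(1), "description"),
    data_type = vapply(records, `[[`, character(1), "data_type"),
    stringsAsFactors = FALSE
  )
  index$desc_lower <- tolower(index$description)
  names(records) <- as.character(ids)
  structure(list(records = records, index = index), class = "food_store")
}

#' @export
print.food_store <- function(x, ...) {
  cat(sprintf("<food_store> %d record(s)\n", nrow(x$index)))
  if (nrow(x$index)) print(table(x$index$data_type))
  invisible(x)
}

#' @export
length.food_store <- function(x) nrow(x$index)

#' Read a food store from its JSON fixture dialect
#'
#' The fixture dialect is an array of objects
#' `{fdcId, description, dataType, nutrients: {name: amountPer100g}}`.
#'
#' @param path path to a JSON file.
#' @return a [food_store()].
#' @export
read_food_store <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  records <- lapply(raw, function(r) {
    food_record(r$fdcId, r$description, r$dataType,
                nutrients = if (length(r$nutrients)) unlist(r$nutrients))
  })
  food_store(records)
}

#' Write a food store to the JSON fixture dialect
#'
#' @param store a [food_store()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_food_store <- function(store, path) {
  stopifnot(inherits(store, "food_store"))
  out <- lapply(store$records, function(r) {
    list(fdcId = r$fdc_id, description = r$description, dataType = r$data_type,
         nutrients = as.list(r$nutrients))
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Subset-creation policy (data-type trust hierarchy)
#'
#' @param tier1,tier2,tier3 character vectors of data types; the three tiers
#'   must be disjoint and together exhaust the data-type set.
#' @param sufficiency_threshold minimum number of matches considered
#'   sufficient before falling through to the next tier (default 3).
#' @return object of class `subset_policy`.
#' @export
subset_policy <- function(tier1 = c("SR Legacy", "Foundation"),
                          tier2 = "FNDDS",
                          tier3 = c("Experimental", "Branded"),
                          sufficiency_threshold = 3) {
  tiers <- c(tier1, tier2, tier3)
  if (anyDuplicated(tiers) || !setequal(tiers, FOOD_DATA_TYPES)) {
    md_stop("mealdecomp_value_error",
            "tiers must be disjoint and exhaust the data-type set")
  }
  if (!is.numeric(sufficiency_threshold) || sufficiency_threshold < 1) {
    md_stop("mealdecomp_value_error", "sufficiency_threshold must be a positive integer")
  }
  structure(list(tier1 = tier1, tier2 = tier2, tier3 = tier3,
                 sufficiency_threshold = as.integer(sufficiency_threshold)),
            class = "subset_policy")
}

#' Build a query subset of a food store under the tier hierarchy
#'
#' Matching is a case-insensitive substring match on the description. Tier-1
#' matches (SR Legacy / Foundation) come first; if fewer than
#' `sufficiency_threshold` are found, tier-2 (FNDDS) matches are added, and
#' then tier-3 (Experimental / Branded). The returned records deliberately
#' carry no nutrient data: the downstream mapping step must decide on the
#' description alone. Order is deterministic: tier, then ascending fdcId.
#'
#' @param query non-empty search text.
#' @param store a [food_store()].
#' @param policy a [subset_policy()].
#' @return list of nutrient-free [food_record()]s; attribute `tiers_used`
#'   names the tiers that contributed.
#' @export
build_subset <- function(query, store, policy = subset_policy()) {
  stopifnot(inherits(store, "food_store"), inherits(policy, "subset_policy"))
  if (!is.character(query) || length(query) != 1 || !nzchar(trimws(query))) {
    md_stop("mealdecomp_value_error", "query must be non-empty")
  }
  idx <- store$index
  if (nrow(idx) == 0) {
    md_warn("mealdecomp_match_warning", "food store is empty")
    return(structure(list(), tiers_used = character(0)))
  }
  hit <- grepl(tolower(trimws(query)), idx$desc_lower, fixed = TRUE)
  tiers <- list(tier1 = policy$tier1, tier2 = policy$tier2, tier3 = policy$tier3)
  sel <- integer(0)
  used <- character(0)
  for (tn in names(tiers)) {
    if (length(sel) >= policy$sufficiency_threshold) break
    add <- which(hit & idx$data_type %in% tiers[[tn]])
    if (length(add)) {
      add <- add[order(idx$fdc_id[add])]
      sel <- c(sel, add)
      used <- c(used, tn)
    }
  }
  if (length(sel) == 0) {
    md_warn("mealdecomp_match_warning",
            sprintf("no record matches query %s in any tier", dQuote(query, FALSE)))
    return(structure(list(), tiers_used = character(0)))
  }
  out <- lapply(sel, function(i) {
    food_record(idx$fdc_id[i], idx$description[i], idx$data_type[i])
  })
  structure(out, tiers_used = used)
}

#' Construct a nutrient profile on the 100 g basis
#'
#' @param amounts named numeric vector of non-negative nutrient amounts per
#'   `basis_mass_g` of food (grams for macronutrients).
#' @param basis_mass_g reference mass, fixed at 100 (g, or mL for liquids).
#' @return object of class `nutrient_profile`.
#' @export
nutrient_profile <- function(amounts, basis_mass_g = 100) {
  amounts <- unlist(amounts)
  if (length(amounts) && (is.null(names(amounts)) || any(!nzchar(names(amounts))))) {
    md_stop("mealdecomp_value_error", "amounts must be named")
  }
  if (any(!is.finite(amounts)) || any(amounts < 0)) {
    md_stop("mealdecomp_value_error", "amounts must be non-negative")
  }
  if (!identical(as.numeric(basis_mass_g), 100)) {
    md_stop("mealdecomp_value_error", "profiles are stated per 100 g (or 100 mL)")
  }
  structure(list(basis_mass_g = 100, amounts = amounts), class = "nutrient_profile")
}

#' Retrieve the per-100 g nutrient profile for a record
#'
#' Never scaled: scaling to an actual portion is [scale_profile()]'s job.
#'
#' @param fdc_id record identifier present in the store.
#' @param store a [food_store()].
#' @return a [nutrient_profile()].
#' @export
get_nutrients <- function(fdc_id, store) {
  stopifnot(inherits(store, "food_store"))
  rec <- store$records[[as.character(as.numeric(fdc_id))]]
  if (is.null(rec)) {
    md_stop("mealdecomp_lookup_error",
            sprintf("fdcId %s not found in store", num_chr(fdc_id)))
  }
  nutrient_profile(rec$nutrients %||% numeric(0))
}

#' Minimum uniform request spacing under an hourly rate limit
#'
#' A live client must never issue requests closer together than
#' `3600 / limit_per_hour` seconds (e.g. 1000 requests/hour implies one
#' request every 3.6 s). Offline fixture mode performs no pacing, but the
#' schedule contract is shared.
#'
#' @param n_requests number of requests planned (used for the total span
#'   reported in the `"total_span_s"` attribute).
#' @param limit_per_hour positive request limit per hour.
#' @return minimum spacing in seconds.
#' @examples
#' schedule_requests(100, limit_per_hour = 1000)  # 3.6
#' @export
schedule_requests <- function(n_requests, limit_per_hour) {
  if (!is.numeric(limit_per_hour) || length(limit_per_hour) != 1 ||
      is.na(limit_per_hour) || limit_per_hour <= 0) {
    md_stop("mealdecomp_value_error", "limit_per_hour must be positive")
  }
  if (!is.numeric(n_requests) || n_requests < 0) {
    md_stop("mealdecomp_value_error", "n_requests must be non-negative")
  }
  spacing <- 3600 / limit_per_hour
  structure(spacing, total_span_s = max(0, n_requests - 1) * spacing)
}
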