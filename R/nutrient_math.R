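# Scaling per-100 g profiles to actual ingredient masses, and aggregation
# across the parts of a compound ingredient. Real food records have ragged
# nutrient panels, so aggregation works over the union of nutrient keys
# (absent key == 0) and reports per-nutrient coverage so silent zeros stay
# auditable. No cooking-loss correction is applied: decomposed masses are
# taken as proposed.

#' Scale a per-100 g nutrient profile to an actual mass
#'
#' @param profile a [nutrient_profile()].
#' @param mass_g actual ingredient mass in grams, `>= 0`.
#' @param ingredient_name optional name carried on the result.
#' @return object of class `scaled_profile` with fields `ingredient_name`,
#'   `mass_g` and `amounts` (each amount multiplied by `mass_g / 100`).
#' @examples
#' p <- nutrient_profile(c(protein = 10))
#' scale_profile(p, 50)$amounts  # protein 5
#' @export
scale_profile <- function(profile, mass_g, ingredient_name = NA_character_) {
  stopifnot(inherits(profile, "nutrient_profile"))
  if (!is.numeric(mass_g) || length(mass_g) != 1 || is.na(mass_g) || mass_g < 0) {
    md_stop("mealdecomp_value_error", "mass_g must be a non-negative number")
  }
  structure(
    list(ingredient_name = ingredient_name, mass_g = as.numeric(mass_g),
         amounts = profile$amounts * (mass_g / 100)),
    class = "scaled_profile"
  )
}

#' Aggregate scaled part profiles into a compound total
#'
#' Element-wise sum over the union of nutrient keys; a nutrient missing from
#' a part contributes 0. The `coverage` field reports, per nutrient, the
#' fraction of parts whose profile stated that nutrient at all.
#'
#' @param parts list of [scale_profile()] results (may be empty, giving
#'   all-zero totals).
#' @param compound_name name carried on the result.
#' @return object of class `compound_total` with fields `compound_name`,
#'   `amounts`, `parts_mass_g` (sum of part masses) and `coverage`.
#' @export
aggregate_compound <- function(parts, compound_name = NA_character_) {
  for (p in parts) stopifnot(inherits(p, "scaled_profile"))
  keys <- unique(unlist(lapply(parts, function(p) names(p$amounts))))
  amounts <- setNames(numeric(length(keys)), keys)
  coverage <- setNames(numeric(length(keys)), keys)
  for (p in parts) {
    nm <- names(p$amounts)
    amounts[nm] <- amounts[nm] + p$amounts
    coverage[nm] <- coverage[nm] + 1
  }
  if (length(parts) > 0) coverage <- coverage / length(parts)
  structure(
    list(compound_name = compound_name, amounts = amounts,
         parts_mass_g = sum(vapply(parts, `[[`, numeric(1), "mass_g")),
         coverage = coverage),
    class = "compound_total"
  )
}

#' @export
print.compound_total <- function(x, ...) {
  cat(sprintf("<compound_total> %s (%s g decomposed)\n",
              x$compound_name, num_chr(x$parts_mass_g)))
  for (nm in names(x$amounts)) {
    cat(sprintf("  %s: %.3f (coverage %.0f%%)\n", nm, x$amounts[[nm]],
                100 * x$coverage[[nm]]))
  }
  invisible(x)
}

#' Write per-compound nutrient totals as a delimited-text report
#'
#' @param totals list of [aggregate_compound()] results.
#' @param path output path; `NULL` returns the data frame without writing.
#' @param sep field separator.
#' @return the report data frame, invisibly when written.
#' @export
write_nutrient_report <- function(totals, path = NULL, sep = "\t") {
  keys <- unique(unlist(lapply(totals, function(t) names(t$amounts))))
  rows <- lapply(totals, function(t) {
    vals <- setNames(numeric(length(keys)), keys)
    vals[names(t$amounts)] <- t$amounts
    c(list(compound = t$compound_name, parts_mass_g = t$parts_mass_g), as.list(vals))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}
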