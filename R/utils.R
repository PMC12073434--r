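`%||%` <- function(x, y) if (is.null(x)) y else x

#' Typed error helper
#'
#' All user-facing errors in the package carry a subclass of
#' `mealdecomp_error` so callers can branch on the failure kind
#' (`format`, `schema`, `value`, `parse`, `extraction`, `template`,
#' `lookup`, `config`).
#' @noRd
md_stop <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "mealdecomp_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

md_warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "mealdecomp_warning")))
}

#' Round half away from zero
#'
#' Base R rounds half to even; reported percentages use conventional
#' half-up rounding (e.g. 4/31 of 100 -> 12.9).
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Deterministic small hash of a string, used to derive per-request seeds.
#' Vectorised polynomial-ish mix; collisions are harmless (they only make
#' two mock responses share chatter).
#' @noRd
string_seed <- function(text) {
  codes <- utf8ToInt(enc2utf8(text))
  if (length(codes) == 0) return(1L)
  w <- (seq_along(codes) - 1) %% 97 + 1
  as.integer((sum(codes * w) + 131 * length(codes)) %% 2147483629)
}

#' Combine a user seed with a derived component, staying inside 32-bit range.
#' @noRd
combine_seed <- function(seed, extra) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(extra)) %% 2147483629)
}

#' Evaluate code under a temporary RNG state.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Normalize an ingredient name for identity comparisons
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space and case-folds. Parenthetical qualifiers are kept: variants
#' such as "Mixed Greens Salad (with lemon vinaigrette)" and
#' "Mixed Greens Salad" remain distinct ingredients.
#'
#' @param x character vector of ingredient names.
#' @return character vector of normalized names.
#' @examples
#' normalize_ingredient_name(c("  Chicken   Marsala ", "chicken marsala"))
#' @export
normalize_ingredient_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

num_chr <- function(x) {
  # plain decimal formatting, dot separator, no scientific notation
  format(x, trim = TRUE, scientific = FALSE, digits = 15)
}
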