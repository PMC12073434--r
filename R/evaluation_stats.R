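# Evaluation framework: confusion counts of predicted compound-ingredient
# sets against rater ground truth, per-plan accuracy/precision/recall/F1,
# t-interval confidence bounds on mean scores, Shapiro-Wilk-gated paired
# comparisons (paired t when normality of the differences is not rejected,
# Wilcoxon signed-rank otherwise), pooling across raters, and classical
# one-way ANOVA for macronutrient comparisons.

#' Construct ground-truth labels for one plan and one evaluator
#'
#' @param evaluator_id evaluator identifier.
#' @param plan_id plan identifier.
#' @param labels named character vector mapping each ingredient name to
#'   `"compound"` or `"basic"`; every plan ingredient labeled exactly once.
#' @return object of class `ground_truth_labels`.
#' @export
ground_truth_labels <- function(evaluator_id, plan_id, labels) {
  if (length(labels) && (is.null(names(labels)) || any(!nzchar(names(labels))))) {
    md_stop("mealdecomp_value_error", "labels must be named by ingredient")
  }
  if (!all(labels %in% c("compound", "basic"))) {
    md_stop("mealdecomp_value_error", "labels must be 'compound' or 'basic'")
  }
  nn <- normalize_ingredient_name(names(labels))
  if (anyDuplicated(nn)) {
    md_stop("mealdecomp_value_error",
            "each ingredient must be labeled exactly once per evaluator")
  }
  structure(
    list(evaluator_id = evaluator_id, plan_id = plan_id,
         labels = setNames(as.character(labels), names(labels))),
    class = "ground_truth_labels"
  )
}

#' Confusion counts of a predicted compound set against ground truth
#'
#' Names are compared after [normalize_ingredient_name()]. Predicted names
#' that do not resolve to any plan ingredient (hallucinations) are counted as
#' false positives with a warning - dropping them silently would inflate
#' precision.
#'
#' @param truth a [ground_truth_labels()] object.
#' @param predicted_compounds character vector of names the model predicted
#'   to be compound ingredients.
#' @return object of class `confusion_counts` with fields `tp`, `fp`, `fn`,
#'   `tn` and `n_unmatched`.
#' @export
confusion <- function(truth, predicted_compounds) {
  stopifnot(inherits(truth, "ground_truth_labels"))
  truth_names <- normalize_ingredient_name(names(truth$labels))
  pred <- unique(normalize_ingredient_name(as.character(predicted_compounds)))
  unmatched <- setdiff(pred, truth_names)
  if (length(unmatched) > 0) {
    md_warn("mealdecomp_prediction_warning", sprintf(
      "%d predicted name(s) not in plan, counted as false positives: %s",
      length(unmatched), paste(unmatched, collapse = ", ")))
  }
  is_compound <- unname(truth$labels) == "compound"
  predicted <- truth_names %in% pred
  structure(
    list(tp = sum(is_compound & predicted),
         fp = sum(!is_compound & predicted) + length(unmatched),
         fn = sum(is_compound & !predicted),
         tn = sum(!is_compound & !predicted),
         n_unmatched = length(unmatched)),
    class = "confusion_counts"
  )
}

#' Per-plan metrics from confusion counts
#'
#' Accuracy is `(tp + tn) / total`; F1 is the harmonic mean of precision and
#' recall. Zero-denominator conventions keep per-plan scores defined: with
#' `tp + fp = 0`, precision is 1 when `fn = 0` (nothing to find, nothing
#' claimed) and 0 otherwise; symmetrically for recall when `tp + fn = 0`.
#' A convention use is flagged in the `conventions` field.
#'
#' @param counts a [confusion()] result (all-zero counts are an error).
#' @return object of class `evaluation_metrics` with fields `accuracy`,
#'   `precision`, `recall`, `f1`, `conventions`.
#' @export
metrics_from_confusion <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  if (total == 0) {
    md_stop("mealdecomp_value_error", "confusion counts are all zero")
  }
  conventions <- character(0)
  precision <- if (counts$tp + counts$fp > 0) {
    counts$tp / (counts$tp + counts$fp)
  } else {
    conventions <- c(conventions, "precision")
    if (counts$fn == 0) 1 else 0
  }
  recall <- if (counts$tp + counts$fn > 0) {
    counts$tp / (counts$tp + counts$fn)
  } else {
    conventions <- c(conventions, "recall")
    if (counts$fp == 0) 1 else 0
  }
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    list(accuracy = (counts$tp + counts$tn) / total,
         precision = precision, recall = recall, f1 = f1,
         conventions = conventions),
    class = "evaluation_metrics"
  )
}

#' t-interval for the mean of per-plan scores
#'
#' Two-sided Student-t interval on the mean; with all values equal the
#' interval has zero width.
#'
#' @param values numeric vector of per-plan scores, length `>= 2`.
#' @param level confidence level (default 0.95).
#' @return list with `mean`, `ci_low`, `ci_high`, `level`, `n`.
#' @export
mean_ci <- function(values, level = 0.95) {
  values <- as.numeric(values)
  if (length(values) < 2 || any(is.na(values))) {
    md_stop("mealdecomp_value_error", "need at least 2 non-missing values")
  }
  if (level <= 0 || level >= 1) {
    md_stop("mealdecomp_value_error", "level must be in (0, 1)")
  }
  n <- length(values)
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(values) / sqrt(n)
  list(mean = m, ci_low = m - half, ci_high = m + half, level = level, n = n)
}

#' Normality-gated paired comparison of two score sequences
#'
#' Differences are tested for normality with the Shapiro-Wilk test; if
#' normality is not rejected at `alpha` a paired t-test is run (statistic
#' `t`, `n - 1` degrees of freedom), otherwise a Wilcoxon signed-rank test
#' (statistic `V`, normal approximation). All p-values are two-sided. When
#' every difference is zero the comparison is degenerate (normality testing
#' on a constant is undefined): no test is run and `p_value = 1`. Constant
#' non-zero differences also defeat the Shapiro-Wilk gate and fall through
#' to the signed-rank test.
#'
#' @param scores_a,scores_b equal-length (`>= 3`) per-plan score vectors,
#'   aligned by plan.
#' @param alpha significance level for the normality gate (default 0.05).
#' @return object of class `paired_comparison` with fields `test_kind`
#'   (`"paired_t"`, `"wilcoxon"` or `"degenerate"`), `statistic`, `p_value`,
#'   `alpha`, `normality_p`, `n`.
#' @export
paired_compare <- function(scores_a, scores_b, alpha = 0.05) {
  a <- as.numeric(scores_a)
  b <- as.numeric(scores_b)
  if (length(a) != length(b) || length(a) < 3 || any(is.na(a)) || any(is.na(b))) {
    md_stop("mealdecomp_value_error",
            "scores must be equal-length (>= 3) and free of missing values")
  }
  d <- a - b
  if (all(d == 0)) {
    return(structure(
      list(test_kind = "degenerate", statistic = NA_real_, p_value = 1,
           alpha = alpha, normality_p = NA_real_, n = length(d)),
      class = "paired_comparison"))
  }
  if (sd(d) == 0) {
    # constant non-zero differences: Shapiro-Wilk is undefined
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
    return(structure(
      list(test_kind = "wilcoxon", statistic = unname(wt$statistic),
           p_value = wt$p.value, alpha = alpha, normality_p = NA_real_,
           n = length(d)),
      class = "paired_comparison"))
  }
  normality_p <- shapiro.test(d)$p.value
  if (normality_p >= alpha) {
    tt <- t.test(a, b, paired = TRUE)
    res <- list(test_kind = "paired_t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
    res <- list(test_kind = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  structure(c(res, list(alpha = alpha, normality_p = normality_p, n = length(d))),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  stat_name <- switch(x$test_kind, paired_t = "t", wilcoxon = "V", "stat")
  cat(sprintf("<paired_comparison> %s: %s = %s, p = %.4g (n = %d)\n",
              x$test_kind, stat_name,
              if (is.na(x$statistic)) "NA" else sprintf("%.4g", x$statistic),
              x$p_value, x$n))
  invisible(x)
}

#' Pool per-plan scores across evaluators
#'
#' Concatenates per-plan scores across evaluators (e.g. 3 evaluators x 15
#' plans = 45 pooled pairs) in a fixed plan order, so that two pooled
#' sequences from the same evaluators remain paired. All evaluators must
#' cover the same plans.
#'
#' @param per_evaluator_scores named list (one element per evaluator) of
#'   named numeric vectors (names are plan ids).
#' @return named numeric vector of pooled scores (`evaluator.plan` names).
#' @export
pool_evaluators <- function(per_evaluator_scores) {
  stopifnot(is.list(per_evaluator_scores), length(per_evaluator_scores) >= 1)
  plan_sets <- lapply(per_evaluator_scores, function(s) sort(names(s)))
  if (!all(vapply(plan_sets, identical, logical(1), plan_sets[[1]]))) {
    md_stop("mealdecomp_value_error", "evaluators cover different plan sets")
  }
  plan_order <- names(per_evaluator_scores[[1]])
  ev <- names(per_evaluator_scores) %||% seq_along(per_evaluator_scores)
  out <- unlist(lapply(seq_along(per_evaluator_scores), function(i) {
    s <- per_evaluator_scores[[i]][plan_order]
    setNames(s, paste(ev[i], plan_order, sep = "."))
  }))
  out
}

#' Classical one-way ANOVA
#'
#' Equal-variance one-way analysis of variance across `>= 2` groups; with
#' two groups the F statistic is the square of the pooled two-sample t
#' statistic.
#'
#' @param groups list of numeric vectors, each of length `>= 2`.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    md_stop("mealdecomp_value_error", "every group needs at least 2 values")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  ow <- oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ow$statistic), p = ow$p.value,
       df_between = unname(ow$parameter[1]), df_within = unname(ow$parameter[2]))
}
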