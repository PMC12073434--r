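test_that("confusion counts match hand enumeration", {
  truth <- ground_truth_labels("e1", "p1", c(
    A = "compound", B = "compound", C = "basic", D = "basic", E = "basic"))
  cc <- confusion(truth, c("A", "C"))
  expect_equal(cc[c("tp", "fp", "fn", "tn")], list(tp = 1, fp = 1, fn = 1, tn = 2))

  perfect <- confusion(truth, c("A", "B"))
  expect_equal(perfect$fp + perfect$fn, 0)
  empty <- confusion(truth, character(0))
  expect_equal(empty$fn, 2)
  expect_equal(empty$tp, 0)
})

test_that("hallucinated predictions warn and count as false positives", {
  truth <- tiny_truth()
  expect_warning(cc <- confusion(truth, c("Chicken Marsala", "Ghost Dish")),
                 class = "mealdecomp_prediction_warning")
  expect_equal(cc$fp, 1)
  expect_equal(cc$n_unmatched, 1)
})

test_that("confusion/accuracy/F1 agree with brute force on 1000 random plans", {
  set.seed(1234)
  for (i in 1:1000) {
    n <- sample(2:10, 1)
    nms <- paste0("ing", seq_len(n))
    labels <- setNames(sample(c("compound", "basic"), n, replace = TRUE), nms)
    predicted <- sample(nms, sample(0:n, 1))
    truth <- ground_truth_labels("e", "p", labels)
    cc <- confusion(truth, predicted)
    oc <- oracle_confusion(labels, predicted)
    expect_equal(cc[c("tp", "fp", "fn", "tn")], oc)
    # count conservation: resolvable predictions keep the plan's total
    expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, n)
    m <- metrics_from_confusion(cc)
    expect_equal(m$accuracy, (oc$tp + oc$tn) / n)
    P <- if (oc$tp + oc$fp > 0) oc$tp / (oc$tp + oc$fp) else if (oc$fn == 0) 1 else 0
    R <- if (oc$tp + oc$fn > 0) oc$tp / (oc$tp + oc$fn) else if (oc$fp == 0) 1 else 0
    expect_equal(m$precision, P)
    expect_equal(m$recall, R)
    expect_equal(m$f1, if (P + R > 0) 2 * P * R / (P + R) else 0)
    expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) >= 0))
    expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) <= 1))
    if (P + R > 0) {
      expect_lte(m$f1, max(P, R) + 1e-12)
      expect_gte(m$f1, min(P, R) - 1e-12)
    }
  }
})

test_that("metric conventions handle degenerate confusion counts", {
  mk <- function(tp, fp, fn, tn) {
    truth_n <- tp + fp + fn + tn
    structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n_unmatched = 0),
              class = "confusion_counts")
  }
  m <- metrics_from_confusion(mk(3, 1, 1, 10))
  expect_equal(m$accuracy, 13 / 15, tolerance = 1e-12)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)

  expect_equal(metrics_from_confusion(mk(2, 0, 0, 5))$f1, 1)
  expect_equal(metrics_from_confusion(mk(0, 3, 0, 5))$precision, 0)
  expect_equal(metrics_from_confusion(mk(0, 3, 0, 5))$f1, 0)
  # nothing to find, nothing claimed: all-basic plan scores perfectly
  none <- metrics_from_confusion(mk(0, 0, 0, 6))
  expect_equal(none$precision, 1)
  expect_equal(none$recall, 1)
  expect_equal(none$f1, 1)
  expect_true("precision" %in% none$conventions)
  expect_error(metrics_from_confusion(mk(0, 0, 0, 0)),
               class = "mealdecomp_value_error")
})

test_that("mean confidence intervals match the closed-form t interval", {
  eq <- mean_ci(rep(0.8, 5))
  expect_equal(eq$ci_low, 0.8)
  expect_equal(eq$ci_high, 0.8)

  v <- c(0.8, 0.9)
  got <- mean_ci(v, 0.95)
  half <- qt(0.975, df = 1) * sd(v) / sqrt(2)   # closed-form oracle
  expect_equal(got$mean, 0.85)
  expect_equal(got$ci_low, 0.85 - half)
  expect_equal(got$ci_high, 0.85 + half)

  set.seed(5)
  w <- runif(15)
  ci95 <- mean_ci(w, 0.95); ci99 <- mean_ci(w, 0.99)
  expect_lt(ci99$ci_low, ci95$ci_low)
  expect_gt(ci99$ci_high, ci95$ci_high)
  expect_error(mean_ci(0.5), class = "mealdecomp_value_error")
})

test_that("normality gating routes to the expected paired test", {
  set.seed(7531)
  a <- runif(15, 0.6, 0.9)
  b <- a - rnorm(15, 0.05, 0.02)  # light-tailed symmetric differences
  stopifnot(shapiro.test(a - b)$p.value >= 0.05)  # oracle: the gate must pass
  pc <- paired_compare(a, b)
  expect_equal(pc$test_kind, "paired_t")
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(pc$statistic, unname(tt$statistic))
  expect_equal(pc$p_value, tt$p.value)

  b2 <- a; b2[1] <- a[1] - 5  # one extreme outlier forces rejection
  stopifnot(shapiro.test(a - b2)$p.value < 0.05)
  pc2 <- paired_compare(a, b2)
  expect_equal(pc2$test_kind, "wilcoxon")
  wt <- suppressWarnings(wilcox.test(a, b2, paired = TRUE, exact = FALSE))
  expect_equal(pc2$statistic, unname(wt$statistic))
  expect_equal(pc2$p_value, wt$p.value)
})

test_that("identical sequences give the degenerate p = 1 result", {
  x <- runif(10)
  pc <- paired_compare(x, x)
  expect_equal(pc$test_kind, "degenerate")
  expect_equal(pc$p_value, 1)
  expect_true(is.na(pc$statistic))
})

test_that("swapping the paired sequences negates t and preserves p", {
  set.seed(99)
  for (i in 1:10) {
    a <- runif(12); b <- a + rnorm(12, 0.02, 0.03)
    ab <- paired_compare(a, b); ba <- paired_compare(b, a)
    expect_equal(ab$p_value, ba$p_value)
    if (ab$test_kind == "paired_t") expect_equal(ab$statistic, -ba$statistic)
  }
})

test_that("pooling concatenates aligned per-plan scores across evaluators", {
  plans <- sprintf("plan-%02d", 1:15)
  scores <- lapply(1:3, function(e) setNames(runif(15), plans))
  names(scores) <- paste0("e", 1:3)
  pooled <- pool_evaluators(scores)
  expect_length(pooled, 45)
  expect_equal(unname(pooled[1:15]), unname(scores$e1))

  one <- pool_evaluators(scores[1])
  expect_equal(unname(one), unname(scores$e1))
  # permuting evaluator order preserves the multiset of scores
  perm <- pool_evaluators(scores[c(3, 1, 2)])
  expect_equal(sort(perm), sort(pooled))
  bad <- scores
  names(bad$e2) <- c(plans[-1], "plan-99")
  expect_error(pool_evaluators(bad), class = "mealdecomp_value_error")
})

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  groups <- list(c(3.1, 2.9, 3.4), c(4.0, 4.4, 3.8), c(2.0, 2.5, 2.2))
  # manual sum-of-squares computation
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  F_oracle <- (ssb / dfb) / (ssw / dfw)
  p_oracle <- pf(F_oracle, dfb, dfw, lower.tail = FALSE)
  got <- anova_oneway(groups)
  expect_equal(got$F, F_oracle)
  expect_equal(got$p, p_oracle)

  # identical means, positive within-group variance -> F = 0
  same <- list(c(1, 2, 3), c(0, 2, 4), c(2, 2, 2, 2))
  expect_equal(anova_oneway(same)$F, 0)

  # two groups: F is the square of the pooled two-sample t statistic
  g2 <- list(c(5.1, 4.8, 5.5, 5.0), c(4.2, 4.6, 4.0, 4.5))
  tt <- t.test(g2[[1]], g2[[2]], var.equal = TRUE)
  expect_equal(anova_oneway(g2)$F, unname(tt$statistic)^2)
  expect_error(anova_oneway(list(1, c(1, 2))), class = "mealdecomp_value_error")
})
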