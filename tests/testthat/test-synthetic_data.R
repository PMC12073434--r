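test_that("generation is deterministic and respects the configured prevalence", {
  cfg <- simulation_config(n_plans = 15, compound_prevalence = 0.32, seed = 7)
  ps1 <- generate_plan_set(cfg)
  ps2 <- generate_plan_set(cfg)
  expect_identical(ps1$plans, ps2$plans)
  expect_identical(ps1$true_decompositions, ps2$true_decompositions)
  expect_length(ps1$plans, 15)

  # realized prevalence inside central binomial 99% bounds at n slots
  n_slots <- sum(vapply(ps1$plans, function(p) length(p$items), integer(1)))
  k <- sum(unlist(ps1$truth) == "compound")
  bounds <- qbinom(c(0.005, 0.995), n_slots, 0.32)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("near-zero prevalence yields all-basic truth", {
  cfg <- simulation_config(n_plans = 5, compound_prevalence = 1e-9, seed = 3)
  ps <- generate_plan_set(cfg)
  expect_true(all(unlist(ps$truth) == "basic"))
  expect_true(all(vapply(ps$true_decompositions, length, integer(1)) == 0))
})

test_that("reference decompositions conserve mass exactly by construction", {
  ps <- generate_plan_set(simulation_config(n_plans = 10, seed = 11))
  for (pid in names(ps$plans)) {
    masses <- setNames(
      vapply(ps$plans[[pid]]$items, `[[`, numeric(1), "portion_mass_g"),
      plan_ingredients(ps$plans[[pid]]))
    for (nm in names(ps$true_decompositions[[pid]])) {
      d <- ps$true_decompositions[[pid]][[nm]]
      expect_equal(sum(d$parts), masses[[nm]])
      expect_true(all(d$parts >= 1))
    }
  }
})

test_that("a perfect model reproduces truth and every mass matches", {
  cfg <- simulation_config(n_plans = 8, sensitivity = 1, specificity = 1,
                           mass_error = mass_error_model("none"), seed = 23)
  ps <- generate_plan_set(cfg)
  preds <- simulate_predictions(ps)
  for (pid in names(ps$plans)) {
    true_compounds <- names(ps$truth[[pid]])[ps$truth[[pid]] == "compound"]
    expect_setequal(preds[[pid]]$predicted, true_compounds)
    for (nm in names(preds[[pid]]$decompositions)) {
      expect_equal(preds[[pid]]$decompositions[[nm]]$parts,
                   ps$true_decompositions[[pid]][[nm]]$parts)
    }
  }
})

test_that("zero sensitivity predicts nothing; recall is zero on every plan", {
  cfg <- simulation_config(n_plans = 6, sensitivity = 0, specificity = 1, seed = 29)
  ps <- generate_plan_set(cfg)
  preds <- simulate_predictions(ps)
  for (pid in names(ps$plans)) {
    expect_length(preds[[pid]]$predicted, 0)
    truth <- ground_truth_labels("e", pid, ps$truth[[pid]])
    if (any(ps$truth[[pid]] == "compound")) {
      m <- metrics_from_confusion(confusion(truth, character(0)))
      expect_equal(m$recall, 0)
    }
  }
})

test_that("a 30% systematic overestimate flags every decomposition", {
  cfg <- simulation_config(
    n_plans = 10, sensitivity = 1, specificity = 1,
    mass_error = mass_error_model("systematic_overestimate", fraction = 0.30),
    seed = 31)
  ps <- generate_plan_set(cfg)
  preds <- simulate_predictions(ps)
  n_checked <- 0
  for (pid in names(ps$plans)) {
    masses <- setNames(
      vapply(ps$plans[[pid]]$items, `[[`, numeric(1), "portion_mass_g"),
      plan_ingredients(ps$plans[[pid]]))
    for (nm in names(preds[[pid]]$decompositions)) {
      total <- decomposition_total_g(preds[[pid]]$decompositions[[nm]])
      expect_true(flag_overestimation(masses[[nm]], total)$flagged)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("the generated store resolves the lexicon with tiered records", {
  store <- generate_food_store(seed = 41)
  basics <- setdiff(names(mealdecomp:::BASIC_LEXICON), character(0))
  tier1_hits <- vapply(basics, function(b) {
    sub <- suppressWarnings(build_subset(b, store, subset_policy(sufficiency_threshold = 1)))
    length(sub) > 0 &&
      all(vapply(sub, `[[`, character(1), "data_type") %in% c("SR Legacy", "Foundation"))
  }, logical(1))
  expect_gte(mean(tier1_hits), 0.9)

  # fallback fraction 1: every subset build reaches tier 2 or 3
  fb <- generate_food_store(seed = 41, fallback_fraction = 1)
  for (b in basics[1:10]) {
    sub <- suppressWarnings(build_subset(b, fb))
    expect_true(length(sub) > 0)
    expect_true(all(vapply(sub, `[[`, character(1), "data_type") %in%
                      c("FNDDS", "Experimental", "Branded")))
  }

  # forced duplicates: distinct fdcIds share one description
  dup <- generate_food_store(seed = 43, duplicate_fraction = 1)
  idx <- dup$index
  shared <- idx$description[duplicated(idx$description)]
  expect_gt(length(unique(shared)), 0)
  one <- idx[idx$description == shared[1], ]
  expect_gt(nrow(one), 1)
  expect_equal(anyDuplicated(one$fdc_id), 0)
})

test_that("predicted accuracy and F1 recover their simulation targets", {
  # direct simulation path (no pipeline): 200 plans x 20 slots
  sens <- 0.9; spec <- 0.9
  cfg <- simulation_config(n_plans = 200, ingredients_per_plan = c(20, 20),
                           compound_prevalence = 0.32,
                           sensitivity = sens, specificity = spec, seed = 47)
  ps <- generate_plan_set(cfg)
  preds <- simulate_predictions(ps)
  acc <- f1 <- numeric(0)
  for (pid in names(ps$plans)) {
    truth <- ground_truth_labels("e", pid, ps$truth[[pid]])
    m <- metrics_from_confusion(confusion(truth, preds[[pid]]$predicted))
    acc <- c(acc, m$accuracy); f1 <- c(f1, m$f1)
  }
  target_acc <- 0.32 * sens + 0.68 * spec
  expect_lt(abs(mean(acc) - target_acc), 3 * sd(acc) / sqrt(length(acc)))

  # independent Monte-Carlo oracle for mean F1: binomial confusion draws only
  set.seed(470)
  f1_oracle <- replicate(2000, {
    n <- 20
    n_comp <- rbinom(1, n, 0.32)
    tp <- rbinom(1, n_comp, sens)
    fp <- rbinom(1, n - n_comp, 1 - spec)
    fn <- n_comp - tp
    P <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
    R <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else 0
    if (P + R > 0) 2 * P * R / (P + R) else 0
  })
  se <- sqrt(sd(f1)^2 / length(f1) + sd(f1_oracle)^2 / length(f1_oracle))
  expect_lt(abs(mean(f1) - mean(f1_oracle)), 3 * se)
})
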