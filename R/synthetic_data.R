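# Synthetic study inputs with known ground truth: labeled meal plans whose
# compound ingredients carry exact (mass-conserving) reference
# decompositions, simulated model predictions with configurable
# sensitivity/specificity and mass-error behavior, and a fixture
# food-composition store resolving every basic ingredient in the lexicon.
#
# The built-in lexicon is small and auditable: ~30 compound dishes (echoing
# the named examples a study of this kind works with: Chicken Marsala,
# Vegetable Ratatouille, Grilled Vegetable Frittata, ...) with hand-written
# plausible part fractions, over a pool of ~60 basic ingredients.

# Part fractions sum to 1 for each dish; portions are split by these
# fractions and rounded to whole grams with exact total preservation.
COMPOUND_LEXICON <- list(
  "Chicken Marsala" = c("chicken breast" = 0.55, "marsala wine" = 0.15,
                        "mushrooms" = 0.14, "olive oil" = 0.05, "flour" = 0.04,
                        "butter" = 0.04, "garlic" = 0.03),
  "Chicken Cacciatore" = c("chicken breast" = 0.50, "tomatoes" = 0.25,
                           "bell peppers" = 0.10, "onions" = 0.08,
                           "olive oil" = 0.04, "garlic" = 0.03),
  "Vegetable Ratatouille" = c("zucchini" = 0.25, "eggplant" = 0.25,
                              "tomatoes" = 0.20, "bell peppers" = 0.15,
                              "onions" = 0.10, "olive oil" = 0.05),
  "Grilled Vegetable Frittata" = c("eggs" = 0.45, "bell peppers" = 0.15,
                                   "zucchini" = 0.15, "onions" = 0.10,
                                   "cheddar cheese" = 0.10, "milk" = 0.05),
  "Scrambled Eggs" = c("eggs" = 0.80, "butter" = 0.10, "milk" = 0.10),
  "Oatmeal with Fresh Fruit" = c("rolled oats" = 0.40, "milk" = 0.30,
                                 "blueberries" = 0.15, "banana" = 0.10,
                                 "honey" = 0.05),
  "Whole Grain Pancakes" = c("whole wheat flour" = 0.45, "milk" = 0.30,
                             "eggs" = 0.15, "butter" = 0.05, "maple syrup" = 0.05),
  "Steel-Cut Oatmeal" = c("steel-cut oats" = 0.50, "milk" = 0.40, "honey" = 0.10),
  "Hummus" = c("chickpeas" = 0.60, "tahini" = 0.15, "olive oil" = 0.10,
               "lemon juice" = 0.10, "garlic" = 0.05),
  "Mixed Greens Salad" = c("romaine lettuce" = 0.40, "cucumber" = 0.25,
                           "carrots" = 0.20, "olive oil" = 0.10,
                           "lemon juice" = 0.05),
  "Mixed Greens Salad (with lemon vinaigrette)" =
    c("romaine lettuce" = 0.40, "spinach" = 0.20, "cucumber" = 0.20,
      "olive oil" = 0.10, "lemon juice" = 0.10),
  "Mixed Greens Salad (without lemon vinaigrette)" =
    c("romaine lettuce" = 0.45, "spinach" = 0.25, "cucumber" = 0.30),
  "Greek Yogurt Parfait" = c("greek yogurt" = 0.60, "granola" = 0.20,
                             "strawberries" = 0.15, "honey" = 0.05),
  "Herb-Roasted Salmon" = c("salmon fillet" = 0.85, "olive oil" = 0.07,
                            "lemon juice" = 0.05, "parsley" = 0.03),
  "Beef Stir-Fry" = c("beef sirloin" = 0.50, "broccoli" = 0.20,
                      "bell peppers" = 0.10, "soy sauce" = 0.08,
                      "onions" = 0.07, "sesame oil" = 0.05),
  "Vegetable Soup" = c("potatoes" = 0.25, "carrots" = 0.20, "tomatoes" = 0.20,
                       "celery" = 0.15, "onions" = 0.15, "olive oil" = 0.05),
  "Caprese Salad" = c("tomatoes" = 0.45, "mozzarella" = 0.40, "olive oil" = 0.10,
                      "basil" = 0.05),
  "Turkey Sandwich" = c("whole wheat bread" = 0.45, "turkey breast" = 0.30,
                        "lettuce" = 0.10, "tomatoes" = 0.10, "mayonnaise" = 0.05),
  "Quinoa Salad" = c("quinoa" = 0.50, "cucumber" = 0.20, "tomatoes" = 0.15,
                     "feta cheese" = 0.10, "olive oil" = 0.05),
  "Whole Wheat Bagel with Light Cream Cheese" =
    c("whole wheat flour" = 0.70, "cream cheese" = 0.25, "honey" = 0.05),
  "Vegetable Omelette" = c("eggs" = 0.60, "bell peppers" = 0.12, "onions" = 0.10,
                           "mushrooms" = 0.10, "butter" = 0.08),
  "Tuna Salad" = c("tuna" = 0.60, "mayonnaise" = 0.15, "celery" = 0.15,
                   "onions" = 0.10),
  "Pasta Primavera" = c("pasta" = 0.50, "zucchini" = 0.15, "tomatoes" = 0.15,
                        "bell peppers" = 0.10, "olive oil" = 0.05,
                        "parmesan" = 0.05),
  "Beef Chili" = c("ground beef" = 0.40, "kidney beans" = 0.25,
                   "tomatoes" = 0.20, "onions" = 0.10, "olive oil" = 0.05),
  "Shrimp Scampi" = c("shrimp" = 0.60, "butter" = 0.12, "pasta" = 0.10,
                      "lemon juice" = 0.10, "garlic" = 0.08),
  "Stuffed Bell Peppers" = c("bell peppers" = 0.40, "rice" = 0.25,
                             "ground beef" = 0.25, "tomatoes" = 0.10),
  "Avocado Toast" = c("whole wheat bread" = 0.50, "avocado" = 0.45,
                      "lemon juice" = 0.05),
  "Berry Smoothie" = c("blueberries" = 0.30, "strawberries" = 0.20,
                       "banana" = 0.20, "greek yogurt" = 0.20, "milk" = 0.10),
  "Lentil Curry" = c("lentils" = 0.50, "coconut milk" = 0.25, "tomatoes" = 0.15,
                     "onions" = 0.07, "garlic" = 0.03),
  "Fruit Salad" = c("apple" = 0.30, "banana" = 0.25, "strawberries" = 0.25,
                    "blueberries" = 0.20)
)

# Category -> typical macronutrient panel per 100 g (protein, fat,
# carbohydrate, fiber). Panels are plausible, not authoritative; the study
# design needs internally consistent numbers, not database fidelity.
FOOD_CATEGORIES <- list(
  oil       = c(protein = 0,  fat = 100, carbohydrate = 0,  fiber = 0),
  meat      = c(protein = 23, fat = 8,   carbohydrate = 0,  fiber = 0),
  fish      = c(protein = 21, fat = 9,   carbohydrate = 0,  fiber = 0),
  egg       = c(protein = 13, fat = 10,  carbohydrate = 1,  fiber = 0),
  dairy     = c(protein = 6,  fat = 8,   carbohydrate = 5,  fiber = 0),
  cheese    = c(protein = 22, fat = 28,  carbohydrate = 2,  fiber = 0),
  grain     = c(protein = 11, fat = 3,   carbohydrate = 68, fiber = 8),
  legume    = c(protein = 19, fat = 4,   carbohydrate = 55, fiber = 12),
  vegetable = c(protein = 2,  fat = 0.3, carbohydrate = 6,  fiber = 2),
  fruit     = c(protein = 1,  fat = 0.3, carbohydrate = 14, fiber = 2.5),
  sweetener = c(protein = 0.3, fat = 0,  carbohydrate = 80, fiber = 0.2),
  condiment = c(protein = 2,  fat = 20,  carbohydrate = 8,  fiber = 0.5),
  herb      = c(protein = 3,  fat = 0.7, carbohydrate = 7,  fiber = 3),
  liquid    = c(protein = 0.5, fat = 5,  carbohydrate = 4,  fiber = 0)
)

BASIC_LEXICON <- c(
  "olive oil" = "oil", "sesame oil" = "oil", "butter" = "oil",
  "chicken breast" = "meat", "turkey breast" = "meat", "ground beef" = "meat",
  "beef sirloin" = "meat",
  "salmon fillet" = "fish", "tuna" = "fish", "shrimp" = "fish",
  "eggs" = "egg",
  "milk" = "dairy", "greek yogurt" = "dairy", "cream cheese" = "cheese",
  "cheddar cheese" = "cheese", "mozzarella" = "cheese", "parmesan" = "cheese",
  "feta cheese" = "cheese",
  "rolled oats" = "grain", "steel-cut oats" = "grain", "whole wheat flour" = "grain",
  "flour" = "grain", "whole wheat bread" = "grain", "rice" = "grain",
  "pasta" = "grain", "quinoa" = "grain", "granola" = "grain",
  "lentils" = "legume", "chickpeas" = "legume", "kidney beans" = "legume",
  "tomatoes" = "vegetable", "onions" = "vegetable", "bell peppers" = "vegetable",
  "zucchini" = "vegetable", "eggplant" = "vegetable", "mushrooms" = "vegetable",
  "carrots" = "vegetable", "cucumber" = "vegetable", "romaine lettuce" = "vegetable",
  "lettuce" = "vegetable", "spinach" = "vegetable", "broccoli" = "vegetable",
  "celery" = "vegetable", "potatoes" = "vegetable", "garlic" = "vegetable",
  "avocado" = "fruit", "banana" = "fruit", "apple" = "fruit",
  "blueberries" = "fruit", "strawberries" = "fruit", "lemon juice" = "fruit",
  "honey" = "sweetener", "maple syrup" = "sweetener", "sugar" = "sweetener",
  "salt" = "condiment", "black pepper" = "condiment", "soy sauce" = "condiment",
  "mayonnaise" = "condiment", "tahini" = "condiment",
  "basil" = "herb", "parsley" = "herb",
  "marsala wine" = "liquid", "coconut milk" = "liquid"
)

#' Mass-error model for simulated decompositions
#'
#' @param type `"none"` (exact masses), `"additive_noise"` (independent
#'   Gaussian noise of `sd_g` grams per part) or `"systematic_overestimate"`
#'   (every part inflated by `fraction`).
#' @param sd_g noise standard deviation in grams (additive model).
#' @param fraction inflation fraction (systematic model), e.g. 0.30.
#' @return object of class `mass_error_model`.
#' @export
mass_error_model <- function(type = c("none", "additive_noise",
                                      "systematic_overestimate"),
                             sd_g = 10, fraction = 0.30) {
  type <- match.arg(type)
  if (sd_g < 0 || fraction < 0) {
    md_stop("mealdecomp_value_error", "sd_g and fraction must be non-negative")
  }
  structure(list(type = type, sd_g = sd_g, fraction = fraction),
            class = "mass_error_model")
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions this generator emulates: 15 plans,
#' about 7 ingredients each (so roughly a hundred ingredient slots), a
#' compound-ingredient prevalence of 0.32, and a mock model that finds 90%
#' of true compounds while passing over 90% of basics.
#'
#' @param n_plans number of meal plans (default 15).
#' @param ingredients_per_plan inclusive range `c(min, max)` of ingredients
#'   per plan (default 5-9).
#' @param compound_prevalence probability that an ingredient slot is a
#'   compound dish (default 0.32).
#' @param sensitivity probability a true compound is predicted compound.
#' @param specificity probability a true basic is left unflagged.
#' @param mass_error a [mass_error_model()].
#' @param seasoning_inclusion_prob probability a predicted decomposition
#'   gains explicit seasoning parts (salt/pepper/sugar with positive mass).
#' @param seed mandatory integer master seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_plans = 15,
                              ingredients_per_plan = c(5, 9),
                              compound_prevalence = 0.32,
                              sensitivity = 0.9,
                              specificity = 0.9,
                              mass_error = mass_error_model("none"),
                              seasoning_inclusion_prob = 0,
                              seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    md_stop("mealdecomp_config_error", "seed is mandatory")
  }
  probs <- c(compound_prevalence = compound_prevalence,
             sensitivity = sensitivity, specificity = specificity,
             seasoning_inclusion_prob = seasoning_inclusion_prob)
  bad <- probs < 0 | probs > 1
  if (compound_prevalence <= 0 || compound_prevalence >= 1) {
    md_stop("mealdecomp_config_error", "compound_prevalence must be in (0, 1)")
  }
  if (any(bad)) {
    md_stop("mealdecomp_config_error", sprintf(
      "probabilities out of [0, 1]: %s", paste(names(probs)[bad], collapse = ", ")))
  }
  if (n_plans < 1 || length(ingredients_per_plan) != 2 ||
      ingredients_per_plan[1] < 1 ||
      ingredients_per_plan[2] < ingredients_per_plan[1]) {
    md_stop("mealdecomp_config_error", "invalid plan-size settings")
  }
  stopifnot(inherits(mass_error, "mass_error_model"))
  structure(
    list(n_plans = as.integer(n_plans),
         ingredients_per_plan = as.integer(ingredients_per_plan),
         compound_prevalence = compound_prevalence,
         sensitivity = sensitivity, specificity = specificity,
         mass_error = mass_error,
         seasoning_inclusion_prob = seasoning_inclusion_prob,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Split `total` integer grams over `fractions` (summing to 1) with exact
# total preservation (largest-remainder rounding) and a 1 g floor per part.
split_mass <- function(total, fractions) {
  raw <- total * fractions
  base <- pmax(1, floor(raw))
  deficit <- round(total - sum(base))
  if (deficit > 0) {
    rem <- raw - floor(raw)
    ord <- order(rem, decreasing = TRUE)
    add <- rep(floor(deficit / length(base)), length(base))
    extra <- deficit - sum(add)
    if (extra > 0) add[ord[seq_len(extra)]] <- add[ord[seq_len(extra)]] + 1
    base <- base + add
  } else if (deficit < 0) {
    # floors forced the sum above the total; shave from the largest parts
    for (k in seq_len(-deficit)) {
      i <- which.max(base)
      if (base[i] > 1) base[i] <- base[i] - 1
    }
  }
  setNames(as.numeric(base), names(fractions))
}

#' Generate a labeled plan set with known ground truth
#'
#' Deterministic for a given seed. Compound ingredients are drawn from the
#' built-in dish lexicon with portion masses on a 10 g grid (120-400 g);
#' their reference decompositions split the portion over the dish's part
#' fractions in whole grams summing exactly to the portion mass (mass
#' conservation holds by construction). Basic ingredients are drawn from the
#' basic-ingredient pool, all of which resolve in the fixture store from
#' [generate_food_store()].
#'
#' @param config a [simulation_config()].
#' @return object of class `labeled_plan_set`: `plans` (list of
#'   [meal_plan()]), `truth` (list of label vectors per plan, values
#'   `"compound"`/`"basic"`), `true_decompositions` (per plan, a list of
#'   [decomposition()] keyed by compound name).
#' @export
generate_plan_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  compounds <- names(COMPOUND_LEXICON)
  basics <- setdiff(names(BASIC_LEXICON), c("salt", "black pepper", "sugar"))
  with_seed(combine_seed(config$seed, 101L), {
    plans <- vector("list", config$n_plans)
    truth <- vector("list", config$n_plans)
    decomps <- vector("list", config$n_plans)
    meal_types <- rep(MEAL_TYPES, length.out = config$n_plans)
    for (p in seq_len(config$n_plans)) {
      n_range <- seq(config$ingredients_per_plan[1], config$ingredients_per_plan[2])
      n_items <- if (length(n_range) == 1) n_range else sample(n_range, 1)
      is_comp <- runif(n_items) < config$compound_prevalence
      n_comp <- sum(is_comp)
      if (n_comp > length(compounds) || (n_items - n_comp) > length(basics)) {
        md_stop("mealdecomp_config_error",
                "plan larger than the lexicon supports")
      }
      comp_names <- sample(compounds, n_comp)
      basic_names <- sample(basics, n_items - n_comp)
      items <- vector("list", n_items)
      labels <- character(n_items)
      plan_decomps <- list()
      ci <- 0L; bi <- 0L
      for (k in seq_len(n_items)) {
        if (is_comp[k]) {
          ci <- ci + 1L
          nm <- comp_names[ci]
          mass <- sample(seq(120, 400, by = 10), 1)
          items[[k]] <- meal_item(nm, mass)
          labels[k] <- "compound"
          plan_decomps[[nm]] <- decomposition(
            nm, split_mass(mass, COMPOUND_LEXICON[[nm]]))
        } else {
          bi <- bi + 1L
          nm <- basic_names[bi]
          mass <- sample(seq(20, 250, by = 5), 1)
          items[[k]] <- meal_item(nm, mass)
          labels[k] <- "basic"
        }
      }
      pid <- sprintf("plan-%02d", p)
      plans[[p]] <- meal_plan(meal_types[p], items, pid)
      truth[[p]] <- setNames(labels, vapply(items, `[[`, character(1), "name"))
      decomps[[p]] <- plan_decomps
      names(plans)[p] <- names(truth)[p] <- names(decomps)[p] <- pid
    }
    structure(list(plans = plans, truth = truth, true_decompositions = decomps,
                   config = config),
              class = "labeled_plan_set")
  })
}

#' @export
print.labeled_plan_set <- function(x, ...) {
  n_items <- sum(vapply(x$plans, function(p) length(p$items), integer(1)))
  n_comp <- sum(vapply(x$truth, function(t) sum(t == "compound"), integer(1)))
  cat(sprintf("<labeled_plan_set> %d plan(s), %d ingredient(s), %d compound (%.0f%%)\n",
              length(x$plans), n_items, n_comp, 100 * n_comp / n_items))
  invisible(x)
}

perturb_parts <- function(parts, model) {
  out <- switch(model$type,
    none = parts,
    additive_noise = parts + rnorm(length(parts), 0, model$sd_g),
    systematic_overestimate = parts * (1 + model$fraction)
  )
  # integer-gram style with a 1 g floor, matching typical model output
  if (model$type != "none") {
    out <- round(out)
    out[out < 1] <- 1
  }
  out
}

#' Simulate model predictions over a labeled plan set
#'
#' Each true compound is predicted with probability `sensitivity`; each true
#' basic is falsely flagged with probability `1 - specificity`. Predicted
#' decompositions perturb the reference parts under the configured
#' mass-error model (falsely flagged basics get an invented two-part split
#' of their portion). With probability `seasoning_inclusion_prob` a
#' decomposition gains explicit seasoning masses (1-3 g salt, 1-2 g pepper
#' or 1-10 g sugar). Deterministic per seed.
#'
#' @param plan_set a [generate_plan_set()] result.
#' @param config a [simulation_config()]; defaults to the one the plan set
#'   was generated under.
#' @param seed_offset offset added to the config seed so several simulated
#'   "models" can share one plan set.
#' @return object of class `simulated_predictions`: per plan, `predicted`
#'   (character vector of predicted compound names) and `decompositions`
#'   (list of [decomposition()]).
#' @export
simulate_predictions <- function(plan_set, config = plan_set$config,
                                 seed_offset = 0L) {
  stopifnot(inherits(plan_set, "labeled_plan_set"),
            inherits(config, "simulation_config"))
  with_seed(combine_seed(config$seed, 211L + seed_offset), {
    out <- lapply(names(plan_set$plans), function(pid) {
      truth <- plan_set$truth[[pid]]
      plan <- plan_set$plans[[pid]]
      masses <- setNames(vapply(plan$items, `[[`, numeric(1), "portion_mass_g"),
                         names(truth))
      predicted <- character(0)
      decomps <- list()
      for (nm in names(truth)) {
        is_comp <- truth[[nm]] == "compound"
        hit <- if (is_comp) runif(1) < config$sensitivity
               else runif(1) < (1 - config$specificity)
        if (!hit) next
        predicted <- c(predicted, nm)
        parts <- if (is_comp) {
          plan_set$true_decompositions[[pid]][[nm]]$parts
        } else {
          # invented decomposition of a basic: exact two-way split into the
          # ingredient itself plus a padding fat (both resolve in the store)
          half <- max(1, floor(masses[[nm]] / 2))
          filler <- if (nm == "olive oil") "butter" else "olive oil"
          setNames(c(half, max(1, masses[[nm]] - half)), c(nm, filler))
        }
        parts <- perturb_parts(parts, config$mass_error)
        if (runif(1) < config$seasoning_inclusion_prob) {
          seasoning <- c(salt = sample(1:3, 1), "black pepper" = sample(1:2, 1),
                         sugar = sample(1:10, 1))
          picked <- sample(names(seasoning), sample(1:2, 1))
          parts <- c(parts, seasoning[picked])
        }
        decomps[[nm]] <- decomposition(nm, parts)
      }
      list(predicted = predicted, decompositions = decomps)
    })
    names(out) <- names(plan_set$plans)
    structure(out, class = "simulated_predictions")
  })
}

#' Generate a fixture food store for the basic-ingredient lexicon
#'
#' Every basic ingredient gets at least one tier-1 record (SR Legacy or
#' Foundation) unless it falls in the `fallback_fraction` of ingredients
#' deliberately given only FNDDS/Branded records, to exercise the subset
#' hierarchy's fallback path. A `duplicate_fraction` of ingredients receive a
#' second record with an identical description under a different fdcId (the
#' description-collision case a live repository exhibits). Nutrient panels
#' are per 100 g, drawn around the ingredient's category profile.
#'
#' @param lexicon named character vector mapping basic-ingredient name to a
#'   category of `FOOD_CATEGORIES`; defaults to the built-in pool.
#' @param seed integer seed.
#' @param fallback_fraction fraction of ingredients with no tier-1 record.
#' @param duplicate_fraction fraction of ingredients with a duplicated
#'   description.
#' @return a [food_store()].
#' @export
generate_food_store <- function(lexicon = BASIC_LEXICON, seed = 1,
                                fallback_fraction = 0.08,
                                duplicate_fraction = 0.05) {
  if (length(lexicon) == 0) {
    md_stop("mealdecomp_config_error", "lexicon must be non-empty")
  }
  with_seed(combine_seed(seed, 307L), {
    n <- length(lexicon)
    fallback <- runif(n) < fallback_fraction
    duplicate <- runif(n) < duplicate_fraction
    records <- list()
    next_id <- 100001
    for (i in seq_len(n)) {
      nm <- names(lexicon)[i]
      cat_profile <- FOOD_CATEGORIES[[lexicon[[i]]]]
      panel <- cat_profile * runif(length(cat_profile), 0.85, 1.15)
      desc1 <- paste0(toupper(substr(nm, 1, 1)), substr(nm, 2, nchar(nm)), ", raw")
      types <- if (fallback[i]) c("FNDDS", "Branded") else c("SR Legacy", "Foundation")
      for (ty in types) {
        records[[length(records) + 1]] <-
          food_record(next_id, desc1, ty, nutrients = panel * runif(1, 0.97, 1.03))
        next_id <- next_id + 1
      }
      if (duplicate[i]) {
        records[[length(records) + 1]] <-
          food_record(next_id, desc1, "Branded", nutrients = panel)
        next_id <- next_id + 1
      }
    }
    food_store(records)
  })
}

#' Realized compound prevalence of a plan set
#' @param plan_set a [generate_plan_set()] result.
#' @return fraction of ingredient slots labeled compound.
#' @export
realized_prevalence <- function(plan_set) {
  labs <- unlist(plan_set$truth, use.names = FALSE)
  mean(labs == "compound")
}
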