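# Study orchestration: generation -> decomposition -> subset -> mapping ->
# nutrients -> aggregation -> evaluation, for each configured backend, with
# optional persistence of every intermediate artifact. Offline mode (the
# default and the only mode the test suite exercises) drives the
# deterministic mock backend from synthetic ground truth; live mode is an
# opt-in contract for real endpoints and requires an API key and request
# pacing per schedule_requests().

#' Default mock-backend roster
#'
#' Three simulated models mirroring the structure of a three-model
#' comparison: two strong "large" models and a weaker "small" one with
#' noisier masses and more frequent seasoning output.
#' @noRd
default_backends <- function() {
  list(
    "model-large-a" = list(sensitivity = 0.95, specificity = 0.95,
                           mass_error = mass_error_model("none"),
                           seasoning_inclusion_prob = 0.065),
    "model-large-b" = list(sensitivity = 0.90, specificity = 0.93,
                           mass_error = mass_error_model("additive_noise", sd_g = 6),
                           seasoning_inclusion_prob = 0.097),
    "model-small"   = list(sensitivity = 0.70, specificity = 0.85,
                           mass_error = mass_error_model("additive_noise", sd_g = 15),
                           seasoning_inclusion_prob = 0.129)
  )
}

#' Study configuration
#'
#' @param mode `"offline"` (synthetic inputs + mock backend; default) or
#'   `"live"` (real endpoints; requires `api_key`, excluded from tests).
#' @param backends named list of backend settings; each element holds
#'   `sensitivity`, `specificity`, `mass_error` (a [mass_error_model()]) and
#'   `seasoning_inclusion_prob` for the mock that stands in for that model.
#' @param n_plans,ingredients_per_plan,compound_prevalence passed to
#'   [simulation_config()].
#' @param n_evaluators number of ground-truth raters (scores are pooled
#'   across them; default 3).
#' @param evaluator_noise probability an evaluator's label flips relative to
#'   the generating truth (default 0: all raters agree with truth).
#' @param food_store a [food_store()], a path to a JSON fixture, or
#'   `"synthetic"` to generate one from the lexicon (default).
#' @param epsilon mass-match tolerance in grams (see [classify_mass()]).
#' @param overestimation_threshold ratio above which a compound is flagged
#'   (see [flag_overestimation()]).
#' @param ci_level confidence level for score intervals.
#' @param alpha significance level for paired comparisons.
#' @param seasoning_denominator `"common"` (count of compounds predicted by
#'   every backend; default) or `"own"` (each backend's own decomposition
#'   count).
#' @param malformed_rate probability the mock emits an undelimited response
#'   (exercises the retry path).
#' @param master_seed integer master seed; per-stage seeds are derived from
#'   it by fixed offsets.
#' @param out_dir directory for persisted intermediates (`NULL` = keep in
#'   memory only).
#' @param api_key live-mode API key.
#' @param limit_per_hour live-mode request limit (pacing via
#'   [schedule_requests()]).
#' @return object of class `study_config`.
#' @export
study_config <- function(mode = c("offline", "live"),
                         backends = default_backends(),
                         n_plans = 15,
                         ingredients_per_plan = c(5, 9),
                         compound_prevalence = 0.32,
                         n_evaluators = 3,
                         evaluator_noise = 0,
                         food_store = "synthetic",
                         epsilon = 0.5,
                         overestimation_threshold = 1.25,
                         ci_level = 0.95,
                         alpha = 0.05,
                         seasoning_denominator = c("common", "own"),
                         malformed_rate = 0,
                         master_seed = 1,
                         out_dir = NULL,
                         api_key = NULL,
                         limit_per_hour = 1000) {
  structure(
    list(mode = match.arg(mode), backends = backends, n_plans = n_plans,
         ingredients_per_plan = ingredients_per_plan,
         compound_prevalence = compound_prevalence,
         n_evaluators = n_evaluators, evaluator_noise = evaluator_noise,
         food_store = food_store, epsilon = epsilon,
         overestimation_threshold = overestimation_threshold,
         ci_level = ci_level, alpha = alpha,
         seasoning_denominator = match.arg(seasoning_denominator),
         malformed_rate = malformed_rate, master_seed = master_seed,
         out_dir = out_dir, api_key = api_key, limit_per_hour = limit_per_hour),
    class = "study_config"
  )
}

#' Validate a study configuration
#'
#' Checks every invariant and reports all violations at once (never just the
#' first). On success returns the configuration with defaults materialized;
#' on failure raises a `mealdecomp_config_error` whose `errors` field lists
#' every problem.
#'
#' @param config a [study_config()].
#' @return the validated config, invisibly.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "study_config"))
  errors <- character(0)
  err <- function(msg) errors <<- c(errors, msg)

  if (!config$mode %in% c("offline", "live")) err("mode must be 'offline' or 'live'")
  if (config$mode == "live" && is.null(config$api_key)) {
    err("live mode requires an api_key setting")
  }
  if (config$mode == "offline" &&
      !(inherits(config$food_store, "food_store") ||
        identical(config$food_store, "synthetic") ||
        (is.character(config$food_store) && file.exists(config$food_store)))) {
    err("offline mode requires a fixture store: a food_store object, an existing JSON path, or 'synthetic'")
  }
  if (length(config$backends) < 1 || is.null(names(config$backends)) ||
      any(!nzchar(names(config$backends)))) {
    err("backends must be a non-empty named list")
  } else {
    for (nm in names(config$backends)) {
      b <- config$backends[[nm]]
      for (fld in c("sensitivity", "specificity")) {
        v <- b[[fld]]
        if (is.null(v) || !is.numeric(v) || v < 0 || v > 1) {
          err(sprintf("backend '%s': %s must be in [0, 1]", nm, fld))
        }
      }
      if (!inherits(b$mass_error %||% mass_error_model("none"), "mass_error_model")) {
        err(sprintf("backend '%s': mass_error must be a mass_error_model", nm))
      }
    }
  }
  if (!is.numeric(config$n_plans) || config$n_plans < 1) err("n_plans must be >= 1")
  if (!is.numeric(config$n_evaluators) || config$n_evaluators < 1) {
    err("n_evaluators must be >= 1")
  }
  if (config$evaluator_noise < 0 || config$evaluator_noise > 1) {
    err("evaluator_noise must be in [0, 1]")
  }
  if (config$compound_prevalence <= 0 || config$compound_prevalence >= 1) {
    err("compound_prevalence must be in (0, 1)")
  }
  if (config$epsilon < 0) err("epsilon must be non-negative")
  if (config$overestimation_threshold <= 1) {
    err("overestimation_threshold must exceed 1")
  }
  if (config$ci_level <= 0 || config$ci_level >= 1) err("ci_level must be in (0, 1)")
  if (config$alpha <= 0 || config$alpha >= 1) err("alpha must be in (0, 1)")
  if (config$malformed_rate < 0 || config$malformed_rate > 1) {
    err("malformed_rate must be in [0, 1]")
  }
  if (!is.numeric(config$master_seed) || length(config$master_seed) != 1 ||
      is.na(config$master_seed)) {
    err("master_seed must be a single integer")
  }
  if (config$mode == "live" && config$limit_per_hour <= 0) {
    err("limit_per_hour must be positive in live mode")
  }
  if (length(errors) > 0) {
    md_stop("mealdecomp_config_error",
            paste0("invalid study configuration:\n- ",
                   paste(errors, collapse = "\n- ")),
            errors = errors)
  }
  invisible(config)
}

resolve_store <- function(config) {
  if (inherits(config$food_store, "food_store")) return(config$food_store)
  if (identical(config$food_store, "synthetic")) {
    return(generate_food_store(seed = combine_seed(config$master_seed, 2L)))
  }
  read_food_store(config$food_store)
}

# Pick the record the mock mapping step should answer with: exact
# normalized-description prefix match first, else the first candidate
# (candidates are already ordered by tier then fdcId).
pick_best_record <- function(part_name, candidates) {
  if (length(candidates) == 0) return(NULL)
  targets <- normalize_ingredient_name(
    vapply(candidates, `[[`, character(1), "description"))
  want <- normalize_ingredient_name(part_name)
  hit <- which(startsWith(targets, want))
  candidates[[if (length(hit)) hit[1] else 1]]
}

run_decomposition_stage <- function(plan_set, preds, config, backend_seed) {
  failures <- list()
  parsed <- lapply(names(plan_set$plans), function(pid) {
    plan <- plan_set$plans[[pid]]
    prompt <- render_prompt("decomposition", list(meal_plan = plan))
    request <- list(kind = "decomposition", prompt = prompt,
                    context = list(decompositions = unname(preds[[pid]]$decompositions)))
    payload <- NULL
    for (attempt in 1:2) {  # one re-ask on extraction failure, then fail the item
      resp <- mock_backend(request, combine_seed(backend_seed, attempt - 1L),
                           malformed_rate = config$malformed_rate)
      payload <- tryCatch(extract_delimited_payload(resp$raw_text, "decomposition"),
                          mealdecomp_extraction_error = function(e) NULL)
      if (!is.null(payload)) break
    }
    if (is.null(payload)) {
      failures[[pid]] <<- "extraction failed after retry"
      return(list())
    }
    parse_decomposition_payload(payload)
  })
  names(parsed) <- names(plan_set$plans)
  list(decompositions = parsed, failures = failures)
}

run_mapping_stage <- function(decomps_by_plan, store, config, backend_seed) {
  policy <- subset_policy()
  unmapped <- character(0)
  cache <- new.env(parent = emptyenv())  # part name -> fdc_id (or NA)
  map_part <- function(part_name) {
    key <- normalize_ingredient_name(part_name)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cands <- withCallingHandlers(
      build_subset(part_name, store, policy),
      mealdecomp_match_warning = function(w) invokeRestart("muffleWarning")
    )
    if (length(cands) == 0) {
      unmapped <<- c(unmapped, part_name)
      cache[[key]] <- NA_real_
      return(NA_real_)
    }
    best <- pick_best_record(part_name, cands)
    prompt <- render_prompt("mapping",
                            list(food_item = part_name, food_list = cands))
    resp <- mock_backend(list(kind = "mapping", prompt = prompt,
                              context = list(fdc_id = best$fdc_id)),
                         backend_seed, malformed_rate = 0)
    fdc <- parse_fdcid_payload(maybe_extract_payload(resp$raw_text, "mapping"))
    cache[[key]] <- fdc
    fdc
  }
  totals <- lapply(decomps_by_plan, function(decomps) {
    lapply(decomps, function(d) {
      scaled <- list()
      mapping <- numeric(0)
      for (nm in names(d$parts)) {
        fdc <- map_part(nm)
        if (is.na(fdc)) next
        mapping[nm] <- fdc
        scaled[[length(scaled) + 1]] <-
          scale_profile(get_nutrients(fdc, store), d$parts[[nm]], nm)
      }
      total <- aggregate_compound(scaled, d$compound_name)
      list(total = total, mapping = mapping)
    })
  })
  list(totals = totals, unmapped = unique(unmapped))
}

make_evaluator_truth <- function(plan_set, n_evaluators, noise, seed) {
  with_seed(combine_seed(seed, 401L), {
    lapply(seq_len(n_evaluators), function(e) {
      lapply(names(plan_set$truth), function(pid) {
        labels <- plan_set$truth[[pid]]
        if (noise > 0) {
          flip <- runif(length(labels)) < noise
          labels[flip] <- ifelse(labels[flip] == "compound", "basic", "compound")
        }
        ground_truth_labels(sprintf("evaluator-%d", e), pid, labels)
      }) |> setNames(names(plan_set$truth))
    }) |> setNames(sprintf("evaluator-%d", seq_len(n_evaluators)))
  })
}

#' Run the full study
#'
#' Executes all stages in order for each configured backend: plan
#' generation, compound identification/decomposition through the backend and
#' payload parser, food-store subset creation and mapping, nutrient scaling
#' and aggregation, decomposition metrics, and the statistical evaluation.
#' Every intermediate is kept in the returned `artifacts` and, when
#' `out_dir` is set, persisted with a manifest before the report is
#' computed, so the report stage can be re-run from disk (see
#' [read_study_artifacts()] and [report_from_artifacts()]).
#'
#' @param config a [study_config()] (validated via [validate_config()]).
#' @return object of class `study_report`; its `artifacts` field holds all
#'   intermediates.
#' @export
run_study <- function(config = study_config()) {
  validate_config(config)
  if (config$mode == "live") {
    md_stop("mealdecomp_config_error", paste(
      "live mode requires external endpoints and is not executed by this",
      "function; use the backend contract directly with pacing from",
      "schedule_requests()"))
  }
  store <- resolve_store(config)
  sim_base <- simulation_config(
    n_plans = config$n_plans,
    ingredients_per_plan = config$ingredients_per_plan,
    compound_prevalence = config$compound_prevalence,
    seed = combine_seed(config$master_seed, 1L)
  )
  plan_set <- generate_plan_set(sim_base)

  backends <- names(config$backends)
  per_backend <- list()
  for (j in seq_along(backends)) {
    b <- config$backends[[j]]
    sim_b <- simulation_config(
      n_plans = config$n_plans,
      ingredients_per_plan = config$ingredients_per_plan,
      compound_prevalence = config$compound_prevalence,
      sensitivity = b$sensitivity, specificity = b$specificity,
      mass_error = b$mass_error %||% mass_error_model("none"),
      seasoning_inclusion_prob = b$seasoning_inclusion_prob %||% 0,
      seed = sim_base$seed
    )
    preds <- simulate_predictions(plan_set, sim_b, seed_offset = 17L * j)
    backend_seed <- combine_seed(config$master_seed, 1000L + j)
    dec <- run_decomposition_stage(plan_set, preds, config, backend_seed)
    mapped <- run_mapping_stage(dec$decompositions, store, config, backend_seed)
    per_backend[[backends[j]]] <- list(
      decompositions = dec$decompositions,
      failures = dec$failures,
      totals = mapped$totals,
      unmapped = mapped$unmapped
    )
  }

  evaluators <- make_evaluator_truth(plan_set, config$n_evaluators,
                                     config$evaluator_noise, config$master_seed)
  artifacts <- list(
    config = config, plan_set = plan_set,
    plans_html = lapply(plan_set$plans, write_meal_plan),
    store_size = length(store),
    per_backend = per_backend, evaluators = evaluators
  )
  report <- report_from_artifacts(artifacts)
  if (!is.null(config$out_dir)) write_study_artifacts(artifacts, config$out_dir)
  report
}

backend_scores <- function(artifacts, backend) {
  config <- artifacts$config
  plan_ids <- names(artifacts$plan_set$plans)
  decomps <- artifacts$per_backend[[backend]]$decompositions
  lapply(artifacts$evaluators, function(ev_truth) {
    acc <- f1 <- setNames(numeric(length(plan_ids)), plan_ids)
    conf_total <- 0
    for (pid in plan_ids) {
      predicted <- vapply(decomps[[pid]], `[[`, character(1), "compound_name")
      cc <- confusion(ev_truth[[pid]], predicted)
      m <- metrics_from_confusion(cc)
      acc[pid] <- m$accuracy
      f1[pid] <- m$f1
      conf_total <- conf_total + cc$tp + cc$fp + cc$fn + cc$tn
    }
    list(accuracy = acc, f1 = f1, confusion_total = conf_total)
  })
}

#' Compute the study report from persisted or in-memory artifacts
#'
#' Pure function of the artifacts: re-running it on artifacts read back from
#' disk reproduces the report of the original run exactly.
#'
#' @param artifacts the `artifacts` field of a [run_study()] report, or the
#'   result of [read_study_artifacts()].
#' @return object of class `study_report`.
#' @export
report_from_artifacts <- function(artifacts) {
  config <- artifacts$config
  plan_set <- artifacts$plan_set
  backends <- names(artifacts$per_backend)
  plan_ids <- names(plan_set$plans)
  plan_mass <- lapply(plan_set$plans, function(p) {
    setNames(vapply(p$items, `[[`, numeric(1), "portion_mass_g"),
             normalize_ingredient_name(plan_ingredients(p)))
  })

  # --- decomposition metrics per backend ---
  qualify <- function(pid, nm) paste(pid, normalize_ingredient_name(nm), sep = "::")
  decomp_keys <- lapply(backends, function(bk) {
    unlist(lapply(plan_ids, function(pid) {
      vapply(artifacts$per_backend[[bk]]$decompositions[[pid]],
             function(d) qualify(pid, d$compound_name), character(1))
    }), use.names = FALSE)
  })
  names(decomp_keys) <- backends
  common_keys <- Reduce(intersect, decomp_keys)

  mass_tables <- list()
  seasoning <- list()
  macros <- list()
  flags <- list()
  for (bk in backends) {
    outcomes <- list()
    flagged <- character(0)
    all_decomps <- list()
    common_decomps <- list()
    totals_flat <- list()
    for (pid in plan_ids) {
      for (d in artifacts$per_backend[[bk]]$decompositions[[pid]]) {
        key <- normalize_ingredient_name(d$compound_name)
        cmass <- plan_mass[[pid]][key]
        all_decomps[[length(all_decomps) + 1]] <- d
        if (qualify(pid, d$compound_name) %in% common_keys) {
          common_decomps[[length(common_decomps) + 1]] <- d
        }
        if (is.na(cmass)) next  # hallucinated compound: no reference mass
        outcomes[[length(outcomes) + 1]] <- classify_mass(
          cmass, decomposition_total_g(d), config$epsilon, d$compound_name)
        fl <- flag_overestimation(cmass, decomposition_total_g(d),
                                  config$overestimation_threshold, d$compound_name)
        if (fl$flagged) flagged <- c(flagged, d$compound_name)
      }
      tt <- artifacts$per_backend[[bk]]$totals[[pid]]
      for (t in tt) totals_flat[[length(totals_flat) + 1]] <- t$total
    }
    mass_tables[[bk]] <- if (length(outcomes)) match_rate_summary(outcomes) else
      c(match = NA_real_, exceeded = NA_real_, under = NA_real_)
    denom_set <- if (config$seasoning_denominator == "common") common_decomps else all_decomps
    denom <- length(denom_set)
    seasoning[[bk]] <- if (denom > 0) {
      seasoning_rate(denom_set, denominator = denom)
    } else {
      structure(list(seasoning_set = c("salt", "pepper", "sugar"),
                     n_included_with_quantity = 0, denominator = 0, rate = NA_real_),
                class = "seasoning_report")
    }
    macros[bk] <- list(
      if (length(totals_flat)) summarize_macronutrients(totals_flat) else NULL)
    flags[[bk]] <- unique(flagged)
  }

  # --- evaluation ---
  scores <- lapply(backends, function(bk) backend_scores(artifacts, bk))
  names(scores) <- backends

  metric_table <- function(metric) {
    rows <- list()
    for (bk in backends) {
      per_ev <- scores[[bk]]
      for (ev in names(per_ev)) {
        ci <- mean_ci(per_ev[[ev]][[metric]], config$ci_level)
        rows[[length(rows) + 1]] <- data.frame(
          backend = bk, evaluator = ev, mean = ci$mean,
          ci_low = ci$ci_low, ci_high = ci$ci_high, stringsAsFactors = FALSE)
      }
      pooled <- pool_evaluators(lapply(per_ev, `[[`, metric))
      ci <- mean_ci(pooled, config$ci_level)
      rows[[length(rows) + 1]] <- data.frame(
        backend = bk, evaluator = "overall", mean = ci$mean,
        ci_low = ci$ci_low, ci_high = ci$ci_high, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  pairwise <- list()
  if (length(backends) >= 2) {
    combos <- utils::combn(backends, 2, simplify = FALSE)
    for (metric in c("accuracy", "f1")) {
      for (cb in combos) {
        pa <- pool_evaluators(lapply(scores[[cb[1]]], `[[`, metric))
        pb <- pool_evaluators(lapply(scores[[cb[2]]], `[[`, metric))
        pairwise[[paste(metric, cb[1], "vs", cb[2])]] <-
          paired_compare(pa, pb, config$alpha)
      }
    }
  }

  confusion_totals <- vapply(backends, function(bk) {
    sum(vapply(scores[[bk]], `[[`, numeric(1), "confusion_total"))
  }, numeric(1))

  structure(
    list(
      accuracy_table = metric_table("accuracy"),
      f1_table = metric_table("f1"),
      mass_match = mass_tables,
      overestimated = flags,
      seasoning = seasoning,
      macronutrients = macros,
      pairwise = pairwise,
      confusion_totals = confusion_totals,
      n_common_compounds = length(common_keys),
      scores = scores,
      artifacts = artifacts
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, digits = 3, ...) {
  cat("Compound-ingredient identification study\n")
  cat(sprintf("  backends: %s\n", paste(names(x$mass_match), collapse = ", ")))
  cat(sprintf("  plans: %d, evaluators: %d, common compounds: %d\n\n",
              length(x$artifacts$plan_set$plans), length(x$artifacts$evaluators),
              x$n_common_compounds))
  fmt_tab <- function(tab, label) {
    cat(label, "(mean, CI):\n")
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-14s %-12s %.3f (%.2f-%.2f)\n", tab$backend[i],
                  tab$evaluator[i], tab$mean[i], tab$ci_low[i], tab$ci_high[i]))
    }
    cat("\n")
  }
  fmt_tab(x$accuracy_table, "Accuracy")
  fmt_tab(x$f1_table, "F1-score")
  cat("Mass conservation (match / exceeded / under):\n")
  for (bk in names(x$mass_match)) {
    mm <- x$mass_match[[bk]]
    cat(sprintf("  %-14s %.0f%% / %.0f%% / %.0f%%\n", bk,
                100 * mm["match"], 100 * mm["exceeded"], 100 * mm["under"]))
  }
  cat("\nSeasoning inclusion (explicit quantity):\n")
  for (bk in names(x$seasoning)) {
    s <- x$seasoning[[bk]]
    cat(sprintf("  %-14s %s%% (%d of %d)\n", bk,
                ifelse(is.na(s$rate), "NA", num_chr(s$rate)),
                s$n_included_with_quantity, s$denominator))
  }
  if (length(x$pairwise)) {
    cat("\nPairwise comparisons:\n")
    for (nm in names(x$pairwise)) {
      pc <- x$pairwise[[nm]]
      cat(sprintf("  %-40s %s p = %.3g\n", nm, pc$test_kind, pc$p_value))
    }
  }
  invisible(x)
}

#' @export
summary.study_report <- function(object, ...) {
  list(accuracy = object$accuracy_table, f1 = object$f1_table,
       mass_match = object$mass_match,
       pairwise_p = vapply(object$pairwise, `[[`, numeric(1), "p_value"))
}

#' Persist study artifacts to a directory
#'
#' One JSON document per stage plus a `manifest.json`; artifacts round-trip
#' exactly through [read_study_artifacts()].
#'
#' @param artifacts the artifacts of a run.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_artifacts <- function(artifacts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(plan_set = "plan_set.json", plans_html = "plans_html.json",
             per_backend = "per_backend.json", evaluators = "evaluators.json",
             config = "config.json")
  for (nm in names(files)) {
    writeLines(jsonlite::serializeJSON(artifacts[[nm]], digits = NA),
               file.path(dir, files[[nm]]))
  }
  manifest <- list(
    package = "mealdecomp",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = as.list(files),
    store_size = artifacts$store_size,
    backends = names(artifacts$per_backend)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read persisted study artifacts
#'
#' @param dir directory written by [write_study_artifacts()].
#' @return the artifacts list; feed to [report_from_artifacts()] to re-run
#'   the report stage.
#' @export
read_study_artifacts <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  out <- lapply(manifest$stages, function(f) {
    jsonlite::unserializeJSON(paste(readLines(file.path(dir, f), warn = FALSE),
                                    collapse = "\n"))
  })
  out$store_size <- manifest$store_size
  out
}
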