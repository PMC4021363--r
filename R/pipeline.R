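#' Run the full two-wave dietary pattern stability pipeline
#'
#' Executes, in order: (optional) energy-residual adjustment of food
#' intakes, backwards-elimination screening of food groups against every
#' response in both waves with the cross-wave retention rule, pattern-count
#' selection by cross-validated PRESS and Van der Voet's test in each wave
#' (the final count is the largest k supported in both waves),
#' exploratory RRR per wave, confirmatory scoring in both directions, and
#' the cross-wave stability report. The run is a pure function of the input
#' tables and the configuration (including its seed).
#'
#' @param intake_wave1,intake_wave2 Intake tables (aligned participants).
#' @param response_wave1,response_wave2 Response tables (aligned with the
#'   intakes of the same wave).
#' @param config A [pipeline_config()].
#' @return An object of class `rrr_pipeline`: `selection`
#'   (`food_selection`), `press` (list of `press_curve` per wave),
#'   `chosen_k`, `fit_wave1`, `fit_wave2`, `stability`
#'   (`stability_report`, `NULL` when `chosen_k` is 0), `log` (character
#'   vector of stage messages), `config`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_participants = 150, seed = 11))
#' cfg <- pipeline_config(cv_n_splits = 40, n_randomizations = 199, seed = 11)
#' res <- run_pipeline(cohort$intake_wave1, cohort$response_wave1,
#'                     cohort$intake_wave2, cohort$response_wave2, cfg)
#' @export
run_pipeline <- function(intake_wave1, response_wave1,
                         intake_wave2, response_wave2,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  check_aligned_ids(intake_wave1, response_wave1, "wave-1 tables")
  check_aligned_ids(intake_wave2, response_wave2, "wave-2 tables")
  check_aligned_ids(intake_wave1, intake_wave2, "the two waves")
  log <- character()
  note <- function(...) {
    msg <- paste0(...)
    log[[length(log) + 1]] <<- msg
    msg
  }

  if (isTRUE(config$energy_adjust)) {
    intake_wave1 <- energy_adjust(intake_wave1)
    intake_wave2 <- energy_adjust(intake_wave2)
    note("energy-adjusted food intakes by the residual method")
  }

  sw1 <- screen_foods_wave(intake_wave1, response_wave1, config$alpha_backwards)
  sw2 <- screen_foods_wave(intake_wave2, response_wave2, config$alpha_backwards)
  selection <- select_food_groups(sw1, sw2,
                                  min_responses = config$min_responses_retained,
                                  wave_rule = config$wave_rule)
  retained <- selection$retained_foods
  note("screening retained ", length(retained), " of ", nrow(selection$counts),
       " food groups: ", paste(sort(retained), collapse = ", "))
  if (length(retained) < 2) {
    abort(paste0("screening retained fewer than 2 food groups (",
                 length(retained), "); cannot fit patterns"))
  }

  q <- ncol(table_matrix(response_wave1, drop_energy = FALSE))
  k_max <- min(length(retained), q, config$k_max)
  seed1 <- if (is.null(config$seed)) NULL else (config$seed %% 1000003L) * 2L + 1L
  seed2 <- if (is.null(config$seed)) NULL else (config$seed %% 1000003L) * 2L + 2L
  press <- list(
    wave1 = press_curve(intake_wave1, response_wave1, k_max = k_max,
                        n_splits = config$cv_n_splits,
                        test_fraction = config$cv_test_fraction,
                        n_randomizations = config$n_randomizations,
                        alpha = config$vandervoet_alpha,
                        seed = seed1, foods = retained),
    wave2 = press_curve(intake_wave2, response_wave2, k_max = k_max,
                        n_splits = config$cv_n_splits,
                        test_fraction = config$cv_test_fraction,
                        n_randomizations = config$n_randomizations,
                        alpha = config$vandervoet_alpha,
                        seed = seed2, foods = retained)
  )
  chosen_k <- min(press$wave1$chosen_k, press$wave2$chosen_k)
  note("cross-validation chose k = ", press$wave1$chosen_k, " (wave 1) and k = ",
       press$wave2$chosen_k, " (wave 2); final k = ", chosen_k)

  if (chosen_k == 0) {
    note("no dietary pattern predicts the responses better than the mean; stopping")
    return(structure(list(selection = selection, press = press, chosen_k = 0L,
                          fit_wave1 = NULL, fit_wave2 = NULL, stability = NULL,
                          log = log, config = config),
                     class = "rrr_pipeline"))
  }

  fit1 <- fit_rrr(intake_wave1, response_wave1, k = chosen_k, foods = retained)
  fit2 <- fit_rrr(intake_wave2, response_wave2, k = chosen_k, foods = retained)
  note("fitted exploratory RRR models with k = ", chosen_k, " in both waves")
  stab <- stability_report(fit1, fit2, intake_wave1, intake_wave2,
                           highlight_threshold = config$weight_highlight_threshold,
                           standardize_by = config$confirmatory_standardize)
  note("built cross-wave stability report")

  structure(list(selection = selection, press = press, chosen_k = chosen_k,
                 fit_wave1 = fit1, fit_wave2 = fit2, stability = stab,
                 log = log, config = config),
            class = "rrr_pipeline")
}

#' @export
print.rrr_pipeline <- function(x, ...) {
  cat("Two-wave dietary pattern stability pipeline\n")
  for (msg in x$log) cat(" -", msg, "\n")
  if (x$chosen_k > 0) print(x$stability)
  invisible(x)
}

fmt_num <- function(m, digits) formatC(round(m, digits), format = "f", digits = digits)

#' Write the pattern report files for a pipeline run
#'
#' Emits, under `dir`: the screening indicator table, the PRESS/selection
#' curves per wave, and — when patterns were found — per-wave weight tables
#' with high-weight flags (2 decimals), explained-variation blocks per
#' response plus all-responses/all-foods rows (1 decimal), the cross-wave
#' correlation matrix, the food-level Spearman table, and a plain-text
#' summary. With `chosen_k = 0` only the selection and PRESS tables plus a
#' note are written.
#'
#' @param result An `rrr_pipeline`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_pattern_report <- function(result, dir) {
  stopifnot(inherits(result, "rrr_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(df, p, progress = FALSE)
    paths[[length(paths) + 1]] <<- p
  }
  put(result$selection$counts, "food_selection.csv")
  put(result$selection$map, "food_selection_map.csv")
  put(dplyr::bind_rows(wave1 = result$press$wave1$curve,
                       wave2 = result$press$wave2$curve, .id = "wave"),
      "press_curves.csv")
  summary_path <- file.path(dir, "summary.txt")
  if (result$chosen_k == 0) {
    writeLines(c(result$log,
                 "No dietary pattern predicted the responses better than the training mean."),
               summary_path)
    return(invisible(c(paths, summary_path)))
  }
  for (w in c("wave1", "wave2")) {
    fit <- result[[paste0("fit_", w)]]
    td <- tidy(fit, threshold = result$config$weight_highlight_threshold)
    td$weight <- as.numeric(fmt_num(td$weight, 2))
    put(td, paste0("pattern_weights_", w, ".csv"))
    ev <- fit$explained
    ev <- ev %>% mutate(across(-"term", ~as.numeric(fmt_num(.x, 1))))
    put(ev, paste0("explained_variation_", w, ".csv"))
  }
  cm <- result$stability$cor_matrix
  put(bind_cols(tibble(score = rownames(cm)),
                as_tibble(as.data.frame(round(cm, 3)))),
      "stability_correlations.csv")
  put(result$stability$correlations, "stability_correlations_long.csv")
  put(result$stability$food_tracking, "food_tracking_spearman.csv")
  lab <- result$stability$structure %>% select(-"shared_high")
  put(lab, "pattern_structure.csv")
  writeLines(c(result$log, "",
               paste0("factor labels wave1: ",
                      paste(result$stability$labels$wave1$label, collapse = " | ")),
               paste0("factor labels wave2: ",
                      paste(result$stability$labels$wave2$label, collapse = " | "))),
             summary_path)
  invisible(c(paths, summary_path))
}
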