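#' Backwards elimination of food-group predictors for one response
#'
#' Iteratively fits a multiple linear regression (with intercept) of the
#' response on the current predictor set and drops the predictor with the
#' largest coefficient p-value while that p-value exceeds `alpha`, stopping
#' when every remaining predictor is significant or the set is empty. When
#' two predictors tie on the maximal p-value the later column is dropped, so
#' the procedure is deterministic given the column order.
#'
#' @param data Data frame holding the response and predictor columns.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns; defaults to all
#'   variable columns except the response.
#' @param alpha Retention threshold on coefficient p-values.
#' @param standardize_x Standardize predictors first (default). p-values are
#'   scale-invariant, so this only affects reported coefficients.
#' @return A list of class `backward_fit`: `retained` (character),
#'   `log` (tibble with `step`, `dropped`, `p_value`, `n_remaining`),
#'   `alpha`, `response`.
#' @export
backward_eliminate <- function(data, response, predictors = NULL,
                               alpha = 0.05, standardize_x = TRUE) {
  if (!response %in% names(data)) abort(paste0("response column not found: ", response))
  if (is.null(predictors)) {
    predictors <- setdiff(names(data), c(META_COLS, ENERGY_COL, response))
  }
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1]")
  y <- data[[response]]
  X <- table_matrix(data, predictors)
  if (standardize_x) X <- scale(X)
  n <- nrow(X)
  if (n <= ncol(X) + 1) abort("need n > p + 1 observations for backwards elimination")

  current <- colnames(X)
  log <- list()
  step <- 0L
  repeat {
    if (length(current) == 0) break
    Xi <- cbind(`(Intercept)` = 1, X[, current, drop = FALSE])
    fit <- lm.fit(Xi, y)
    df_res <- n - ncol(Xi)
    if (df_res <= 0) abort("no residual degrees of freedom")
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / df_res
    xtx_inv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(sigma2 * diag(xtx_inv))
    tval <- fit$coefficients / se
    pval <- 2 * pt(-abs(tval), df_res)
    pv <- pval[-1]                       # drop intercept
    names(pv) <- current
    worst <- max(pv)
    if (worst <= alpha) break
    # ties on the maximal p-value: drop the later column
    drop_idx <- max(which(pv >= worst - 1e-15))
    step <- step + 1L
    log[[step]] <- tibble(step = step, dropped = current[drop_idx],
                          p_value = unname(pv[drop_idx]),
                          n_remaining = length(current) - 1L)
    current <- current[-drop_idx]
  }
  structure(list(
    retained = current,
    log = if (length(log)) bind_rows(log) else
      tibble(step = integer(), dropped = character(),
             p_value = numeric(), n_remaining = integer()),
    alpha = alpha, response = response
  ), class = "backward_fit")
}

#' Screen food groups against every response in one wave
#'
#' Runs [backward_eliminate()] of each risk-factor response on the
#' (standardized) food-group intakes of one wave.
#'
#' @param intake Intake table for the wave.
#' @param response_panel Response table for the wave (aligned participants).
#' @param alpha Retention threshold.
#' @return A list of class `wave_screen`: `foods` (the food universe),
#'   `sets` (named list: response -> retained foods), `logs` (named list of
#'   elimination logs), `wave`.
#' @export
screen_foods_wave <- function(intake, response_panel, alpha = 0.05) {
  check_aligned_ids(intake, response_panel, "intake and response tables")
  X <- table_matrix(intake)
  foods <- colnames(X)
  Y <- table_matrix(response_panel, drop_energy = FALSE)
  dat <- as_tibble(as.data.frame(cbind(X, Y)))
  sets <- list(); logs <- list()
  for (r in colnames(Y)) {
    bf <- backward_eliminate(dat, r, predictors = foods, alpha = alpha)
    sets[[r]] <- bf$retained
    logs[[r]] <- bf$log
  }
  structure(list(foods = foods, sets = sets, logs = logs,
                 wave = if ("wave" %in% names(intake)) as.character(intake$wave[1]) else NA_character_),
            class = "wave_screen")
}

#' Cross-wave food-group retention rule
#'
#' A food group is retained for the final pattern analysis iff it appears in
#' the backwards-selected predictor sets of at least `min_responses`
#' responses in at least one wave (`wave_rule = "either"`, the default), or
#' in both waves (`wave_rule = "both"`). The default `min_responses = 3`
#' reads "more than two responses" as >= 3.
#'
#' @param screen_wave1,screen_wave2 `wave_screen` objects for the two waves,
#'   over the same food universe.
#' @param min_responses Minimum number of responses a food must survive.
#' @param wave_rule `"either"` or `"both"`.
#' @return A list of class `food_selection`: `map` (tibble: `food`,
#'   `response`, `wave`, `retained`), `counts` (tibble: `food`,
#'   `n_responses_w1`, `n_responses_w2`, `retained`), `retained_foods`.
#' @export
select_food_groups <- function(screen_wave1, screen_wave2,
                               min_responses = 3,
                               wave_rule = c("either", "both")) {
  wave_rule <- match.arg(wave_rule)
  stopifnot(inherits(screen_wave1, "wave_screen"), inherits(screen_wave2, "wave_screen"))
  if (!setequal(screen_wave1$foods, screen_wave2$foods)) {
    abort("the two waves screen different food universes")
  }
  if (min_responses < 1) abort("min_responses must be >= 1")
  foods <- screen_wave1$foods
  map <- purrr::map_dfr(list(w1 = screen_wave1, w2 = screen_wave2), function(sw) {
    purrr::map_dfr(names(sw$sets), function(r) {
      tibble(food = foods, response = r, retained = foods %in% sw$sets[[r]])
    })
  }, .id = "wave_id") %>%
    mutate(wave = ifelse(.data$wave_id == "w1", "wave1", "wave2")) %>%
    select("food", "response", "wave", "retained")
  counts <- map %>%
    group_by(.data$food, .data$wave) %>%
    summarise(n_responses = sum(.data$retained), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "wave", values_from = "n_responses",
                       names_prefix = "n_responses_") %>%
    rename(n_responses_w1 = "n_responses_wave1", n_responses_w2 = "n_responses_wave2")
  hit1 <- counts$n_responses_w1 >= min_responses
  hit2 <- counts$n_responses_w2 >= min_responses
  counts$retained <- if (wave_rule == "either") hit1 | hit2 else hit1 & hit2
  structure(list(
    map = map, counts = counts,
    retained_foods = counts$food[counts$retained],
    min_responses = min_responses, wave_rule = wave_rule
  ), class = "food_selection")
}

#' @export
print.food_selection <- function(x, ...) {
  cat("Food-group screening:", length(x$retained_foods), "of",
      nrow(x$counts), "foods retained (>=", x$min_responses,
      "responses,", x$wave_rule, "wave)\n")
  cat(paste(sort(x$retained_foods), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname select_food_groups
#' @param x A `food_selection`.
#' @param ... Unused.
#' @export
tidy.food_selection <- function(x, ...) x$counts

#' @rdname select_food_groups
#' @export
glance.food_selection <- function(x, ...) {
  tibble(n_foods = nrow(x$counts),
         n_retained = length(x$retained_foods),
         min_responses = x$min_responses,
         wave_rule = x$wave_rule)
}
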