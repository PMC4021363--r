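#' Default food-group marginal specifications
#'
#' Per-food marginal shapes for the synthetic generator: zero-inflation
#' probability, log-scale spread and target median (g/day), chosen to mimic
#' the right-skewed, partially zero-inflated intake distributions typical of
#' elderly Dutch cohorts (episodically consumed foods such as wine or fatty
#' fish have a zero median and heavy upper tail; staples such as bread and
#' energy-free beverages are always consumed). `p90_g_per_day` anchors the
#' scale of zero-median foods.
#'
#' @return A tibble with columns `food`, `zero_inflation_pi`,
#'   `log_scale_sigma`, `median_g_per_day`, `p90_g_per_day`.
#' @export
default_intake_specs <- function() {
  tibble::tribble(
    ~food,                        ~zero_inflation_pi, ~log_scale_sigma, ~median_g_per_day, ~p90_g_per_day,
    "low_fibre_bread",            0.20, 0.90,  20, 113,
    "high_fibre_bread",           0.08, 0.50,  99, 183,
    "low_fibre_cereals",          0.30, 0.80,   8,  41,
    "high_fibre_cereals",         0.60, 1.00,   0,  13,
    "fruits",                     0.00, 0.60, 143, 328,
    "fruit_juices",               0.55, 1.00,   0, 120,
    "high_fat_meat",              0.15, 0.60,  29,  61,
    "fatty_fish",                 0.60, 1.00,   0,  18,
    "eggs",                       0.05, 0.60,  16,  35,
    "cheese",                     0.00, 0.60,  29,  65,
    "high_fat_milk_products",     0.10, 0.90, 109, 450,
    "unhealthy_fats",             0.00, 0.60,  33,  71,
    "ready_to_eat_meals",         0.65, 1.00,   0,  10,
    "energy_free_beverages",      0.00, 0.40, 856, 1375,
    "sugar_and_sweets",           0.00, 0.60,  51, 109,
    "sugar_sweetened_beverages",  0.55, 1.00,   0,  71,
    "beer",                       0.55, 1.10,   0, 149,
    "wine",                       0.60, 1.00,   0,  50,
    "strong_alcoholic_beverages", 0.25, 1.00,  10, 100
  )
}

#' Default risk-factor calibration targets
#'
#' Target means and SDs (natural units) for the six cardiovascular risk
#' factors used as RRR responses: BMI (kg/m^2), total and HDL cholesterol
#' (mmol/l), systolic and diastolic blood pressure (mmHg), uric acid (mmol/l).
#'
#' @return A tibble with columns `response`, `mean`, `sd`.
#' @export
default_response_calibration <- function() {
  tibble::tribble(
    ~response,           ~mean,  ~sd,
    "bmi",                25.7,  3.0,
    "total_cholesterol",   6.13, 1.07,
    "hdl_cholesterol",     1.11, 0.26,
    "systolic_bp",       150.0, 20.2,
    "diastolic_bp",       85.5, 11.1,
    "uric_acid",           0.36, 0.07
  )
}

#' Default true pattern weights for the synthetic cohort
#'
#' Three mutually orthogonal unit-norm weight vectors over the 19 default
#' food groups, sketching a "(low in) cereal fibre" pattern, an "alcohol"
#' pattern and a weaker mixed pattern; their active food sets are disjoint,
#' which makes orthogonality exact and gives screening tests a known
#' active/inactive split.
#'
#' @return A 19 x 3 matrix with food rownames; columns have unit norm.
#' @export
default_true_weights <- function() {
  foods <- default_intake_specs()$food
  w <- matrix(0, length(foods), 3, dimnames = list(foods, paste0("pattern", 1:3)))
  w[c("high_fibre_bread", "high_fibre_cereals", "fruit_juices",
      "sugar_sweetened_beverages"), 1] <- c(-0.62, -0.52, 0.45, 0.38)
  w[c("beer", "wine", "strong_alcoholic_beverages"), 2] <- c(0.58, 0.52, 0.63)
  w[c("cheese", "fatty_fish", "low_fibre_cereals"), 3] <- c(0.60, 0.55, -0.58)
  sweep(w, 2, sqrt(colSums(w^2)), "/")
}

#' Default response loadings for the synthetic cohort
#'
#' Loadings of the six risk factors on the three latent patterns, scaled so
#' that (with unit response noise) the first extracted pattern explains a few
#' percent of risk-factor variation — the magnitude regime in which RRR
#' dietary-pattern analyses operate — with pattern strength decreasing from
#' pattern 1 to pattern 3. The columns are mutually orthogonal with squared
#' norms 0.72, 0.45 and 0.22: orthogonality in response space makes the
#' latent patterns identified (the population RRR factors coincide with the
#' generating pattern directions), and the distinct norms order them, with
#' relative strengths mirroring the roughly 4:2.5:1.7 explained-variation
#' ratio typical of published RRR dietary-pattern analyses.
#'
#' @return A 6 x 3 matrix with response rownames.
#' @export
default_response_loadings <- function() {
  resp <- default_response_calibration()$response
  l <- matrix(c(
    # pattern1  pattern2  pattern3
     0.35,      0.30,      0.30,    # bmi
     0.33,      0.25,     -0.30,    # total cholesterol
     0.30,      0.30,      0.25,    # hdl cholesterol
     0.35,     -0.30,     -0.25,    # systolic bp
     0.35,     -0.25,      0.30,    # diastolic bp
     0.33,     -0.30,     -0.30    # uric acid
  ), nrow = 6, byrow = TRUE,
  dimnames = list(resp, paste0("pattern", 1:3)))
  # exact column orthogonality (rounding above leaves ~1e-3 residuals)
  q <- qr.Q(qr(l))
  for (j in 1:3) if (sum(q[, j] * l[, j]) < 0) q[, j] <- -q[, j]
  q <- sweep(q, 2, sqrt(c(0.72, 0.45, 0.22)) / sqrt(colSums(q^2)), "*")
  dimnames(q) <- dimnames(l)
  q
}

#' Configuration for the synthetic two-wave cohort generator
#'
#' Bundles and validates all parameters of the generator. Defaults describe a
#' cohort of 467 elderly men measured twice five years apart: 19 food groups,
#' 6 risk-factor responses, 3 latent dietary patterns with cross-wave latent
#' tracking correlations of 0.6/0.5/0.35, skewed zero-inflated intake
#' marginals and risk factors calibrated to realistic means/SDs.
#'
#' @param n_participants Number of participants per wave.
#' @param n_foods Number of food groups.
#' @param n_responses Number of risk-factor responses.
#' @param n_true_patterns Number of latent diet-risk patterns.
#' @param true_weights foods x patterns matrix; columns must be mutually
#'   orthogonal with unit norm.
#' @param response_loadings responses x patterns loading matrix.
#' @param tracking_rho Per-pattern latent cross-wave correlation in [0, 1]
#'   (recycled if scalar).
#' @param response_noise_sd Per-response residual SD on the latent (unit
#'   loading) scale (recycled).
#' @param intake_noise_sd Per-food residual SD on the latent intake scale
#'   (recycled).
#' @param intake_specs Tibble of per-food marginal specs
#'   (see [default_intake_specs()]).
#' @param response_calibration Tibble of per-response target mean/SD.
#' @param intake_scale `"skewed"` applies the exponential marginal transform
#'   and zero inflation; `"identity"` emits the latent intake scale directly
#'   (useful for exact-recovery checks).
#' @param whiten_latents If `TRUE` (default) realized latent scores are
#'   symmetrically whitened within each wave (sample covariance exactly the
#'   identity) and the wave-2 innovation is drawn orthogonal to wave 1, so
#'   realized per-pattern cross-wave correlations equal `tracking_rho`
#'   exactly; if `FALSE`, plain correlated Gaussian pairs are drawn and all
#'   moments hold up to sampling error.
#' @param energy_calibration List with `mean` and `sd` per wave for total
#'   energy intake (kJ/day).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_participants = 467,
                             n_foods = 19,
                             n_responses = 6,
                             n_true_patterns = 3,
                             true_weights = NULL,
                             response_loadings = NULL,
                             tracking_rho = c(0.60, 0.50, 0.35),
                             response_noise_sd = 1,
                             intake_noise_sd = 0.7,
                             intake_specs = NULL,
                             response_calibration = NULL,
                             intake_scale = c("skewed", "identity"),
                             whiten_latents = TRUE,
                             energy_calibration = list(
                               wave1 = c(mean = 9430, sd = 2052),
                               wave2 = c(mean = 8586, sd = 1962)),
                             seed = NULL) {
  intake_scale <- match.arg(intake_scale)
  if (n_true_patterns > min(n_foods, n_responses)) {
    abort("n_true_patterns must not exceed min(n_foods, n_responses)")
  }
  if (is.null(true_weights)) {
    if (n_foods == 19 && n_true_patterns <= 3) {
      true_weights <- default_true_weights()[, seq_len(n_true_patterns), drop = FALSE]
    } else {
      # deterministic orthonormal columns via QR of a fixed rotation
      base <- outer(seq_len(n_foods), seq_len(n_true_patterns),
                    function(i, k) sin(i * k + k^2))
      true_weights <- qr.Q(qr(base))
      rownames(true_weights) <- paste0("food_", sprintf("%02d", seq_len(n_foods)))
    }
  }
  true_weights <- as.matrix(true_weights)
  if (nrow(true_weights) != n_foods || ncol(true_weights) != n_true_patterns) {
    abort("true_weights must be n_foods x n_true_patterns")
  }
  g <- crossprod(true_weights)
  if (max(abs(g - diag(diag(g)))) > 1e-8) {
    abort("true_weights columns must be mutually orthogonal")
  }
  true_weights <- sweep(true_weights, 2, sqrt(diag(g)), "/")
  if (is.null(response_loadings)) {
    if (n_responses == 6 && n_true_patterns <= 3) {
      response_loadings <- default_response_loadings()[, seq_len(n_true_patterns), drop = FALSE]
    } else {
      response_loadings <- matrix(0.25, n_responses, n_true_patterns,
                                  dimnames = list(paste0("response_", seq_len(n_responses)),
                                                  paste0("pattern", seq_len(n_true_patterns))))
    }
  }
  response_loadings <- as.matrix(response_loadings)
  if (nrow(response_loadings) != n_responses || ncol(response_loadings) != n_true_patterns) {
    abort("response_loadings must be n_responses x n_true_patterns")
  }
  if (is.null(rownames(response_loadings))) {
    rownames(response_loadings) <- paste0("response_", seq_len(n_responses))
  }
  if (is.null(colnames(response_loadings))) {
    colnames(response_loadings) <- paste0("pattern", seq_len(n_true_patterns))
  }
  tracking_rho <- rep_len(tracking_rho, n_true_patterns)
  if (any(tracking_rho < 0 | tracking_rho > 1)) abort("tracking_rho must lie in [0, 1]")
  if (is.null(intake_specs)) {
    if (n_foods == 19) {
      intake_specs <- default_intake_specs()
    } else {
      intake_specs <- tibble(
        food = rownames(true_weights),
        zero_inflation_pi = 0, log_scale_sigma = 0.6,
        median_g_per_day = 50, p90_g_per_day = 150)
    }
  }
  if (!all(c("food", "zero_inflation_pi", "log_scale_sigma", "median_g_per_day") %in%
           names(intake_specs)) || nrow(intake_specs) != n_foods) {
    abort("intake_specs must cover every food with pi, sigma and median columns")
  }
  if (any(intake_specs$zero_inflation_pi < 0 | intake_specs$zero_inflation_pi > 1)) {
    abort("zero_inflation_pi must lie in [0, 1]")
  }
  if (any(intake_specs$log_scale_sigma <= 0)) abort("log_scale_sigma must be positive")
  if (any(intake_specs$median_g_per_day < 0)) abort("median_g_per_day must be nonnegative")
  if (is.null(response_calibration)) {
    if (n_responses == 6) {
      response_calibration <- default_response_calibration()
    } else {
      response_calibration <- tibble(response = rownames(response_loadings),
                                     mean = 0, sd = 1)
    }
  }
  rownames(true_weights) <- intake_specs$food
  rownames(response_loadings) <- response_calibration$response
  structure(list(
    n_participants = n_participants, n_foods = n_foods,
    n_responses = n_responses, n_true_patterns = n_true_patterns,
    true_weights = true_weights, response_loadings = response_loadings,
    tracking_rho = tracking_rho,
    response_noise_sd = rep_len(response_noise_sd, n_responses),
    intake_noise_sd = rep_len(intake_noise_sd, n_foods),
    intake_specs = as_tibble(intake_specs),
    response_calibration = as_tibble(response_calibration),
    intake_scale = intake_scale, whiten_latents = whiten_latents,
    energy_calibration = energy_calibration, seed = seed
  ), class = "synthetic_config")
}

# Symmetric whitening: returns Z with sample covariance exactly I.
whiten <- function(z) {
  s <- crossprod(scale(z, scale = FALSE)) / (nrow(z) - 1)
  e <- eigen(s, symmetric = TRUE)
  zc <- scale(z, scale = FALSE)
  zc %*% e$vectors %*% diag(1 / sqrt(e$values), ncol(z)) %*% t(e$vectors)
}

#' Map latent intake values to skewed, zero-inflated g/day intakes
#'
#' Applies, per food column, a monotone exponential transform of the
#' standardized latent value, anchored so the column median (or, for
#' zero-median foods, the 90th percentile) matches the spec target, then
#' censors the lowest `zero_inflation_pi` fraction of values to zero.
#' Censoring is deterministic quantile censoring given the draw, so ranks
#' among non-zero values are preserved.
#'
#' @param latent_values Numeric matrix, participants x foods, on the latent
#'   scale; column names must match `intake_specs$food` if present.
#' @param intake_specs Per-food marginal specs (see [default_intake_specs()]).
#' @return Nonnegative matrix of intakes in g/day.
#' @export
apply_intake_scale <- function(latent_values, intake_specs) {
  latent_values <- as.matrix(latent_values)
  specs <- as.data.frame(intake_specs)
  if (!is.null(colnames(latent_values))) {
    if (!all(colnames(latent_values) %in% specs$food)) {
      abort("intake_specs must cover every food column")
    }
    specs <- specs[match(colnames(latent_values), specs$food), ]
  } else if (nrow(specs) != ncol(latent_values)) {
    abort("intake_specs must cover every food column")
  }
  if (any(specs$median_g_per_day < 0)) abort("median_g_per_day must be nonnegative")
  n <- nrow(latent_values)
  out <- latent_values
  for (j in seq_len(ncol(out))) {
    z <- out[, j]
    zs <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
    raw <- exp(specs$log_scale_sigma[j] * zs)
    med <- specs$median_g_per_day[j]
    if (med > 0) {
      col <- med * raw / median(raw)
    } else {
      p90 <- specs$p90_g_per_day[j]
      anchor <- if (!is.null(p90) && is.finite(p90) && p90 > 0) p90 else 1
      col <- anchor * raw / quantile(raw, 0.9, names = FALSE)
    }
    n_zero <- round(specs$zero_inflation_pi[j] * n)
    if (n_zero > 0) col[order(col)[seq_len(n_zero)]] <- 0
    out[, j] <- col
  }
  colnames(out) <- specs$food
  out
}

#' Generate a synthetic two-wave cohort with known dietary patterns
#'
#' Draws per-pattern latent scores for both waves as correlated Gaussian
#' pairs (correlation `tracking_rho`), builds latent food intakes as the
#' linear pattern signal plus independent per-wave noise, maps them through
#' the skewed marginal transform, and builds risk-factor responses as linear
#' functions of the latents plus noise, rescaled to the calibration targets.
#' Everything is reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_cohort` with elements `intake_wave1`,
#'   `intake_wave2` (tibbles: participant_id, wave, food columns, energy_kj),
#'   `response_wave1`, `response_wave2` (tibbles: participant_id, wave,
#'   response columns), and `truth` (latent scores per wave, true weights,
#'   response loadings, realized per-pattern cross-wave correlations).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_participants = 100, seed = 1))
#' dim(cohort$intake_wave1)
#' cohort$truth$realized_tracking
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_participants
  K <- config$n_true_patterns
  with_seed_if(config$seed, {
    z1 <- matrix(rnorm(n * K), n, K)
    e2 <- matrix(rnorm(n * K), n, K)
    if (config$whiten_latents) {
      # variance-targeted construction: whiten wave-1 scores, build the wave-2
      # innovation orthogonal to them and white, so the realized per-pattern
      # cross-wave correlation equals tracking_rho exactly
      z1 <- whiten(z1)
      e2 <- whiten(lm.fit(cbind(1, z1), e2)$residuals)
      z2 <- sweep(z1, 2, config$tracking_rho, "*") +
        sweep(e2, 2, sqrt(1 - config$tracking_rho^2), "*")
    } else {
      z2 <- sweep(z1, 2, config$tracking_rho, "*") +
        sweep(e2, 2, sqrt(1 - config$tracking_rho^2), "*")
    }
    colnames(z1) <- colnames(z2) <- colnames(config$true_weights)
    ids <- sprintf("P%04d", seq_len(n))

    build_wave <- function(z, wave, energy_cal) {
      p <- config$n_foods
      q <- config$n_responses
      lat <- z %*% t(config$true_weights) +
        matrix(rnorm(n * p), n, p) %*% diag(config$intake_noise_sd, p)
      colnames(lat) <- rownames(config$true_weights)
      intake <- if (config$intake_scale == "skewed") {
        apply_intake_scale(lat, config$intake_specs)
      } else lat
      yraw <- z %*% t(config$response_loadings) +
        matrix(rnorm(n * q), n, q) %*% diag(config$response_noise_sd, q)
      cal <- config$response_calibration
      y <- sweep(sweep(scale(yraw), 2, cal$sd, "*"), 2, cal$mean, "+")
      colnames(y) <- cal$response
      tot <- rowSums(scale(lat))
      tot <- if (sd(tot) > 0) (tot - mean(tot)) / sd(tot) else tot
      energy <- energy_cal[["mean"]] +
        energy_cal[["sd"]] * (0.55 * tot + sqrt(1 - 0.55^2) * rnorm(n))
      energy <- pmax(energy, 500)
      list(
        intake = bind_cols(tibble(participant_id = ids, wave = wave),
                           as_tibble(as.data.frame(intake)),
                           tibble(energy_kj = energy)),
        response = bind_cols(tibble(participant_id = ids, wave = wave),
                             as_tibble(as.data.frame(y))),
        latent_intake = lat
      )
    }
    w1 <- build_wave(z1, "wave1", config$energy_calibration$wave1)
    w2 <- build_wave(z2, "wave2", config$energy_calibration$wave2)

    realized <- vapply(seq_len(K), function(k) cor(z1[, k], z2[, k]), numeric(1))
    names(realized) <- colnames(z1)
    structure(list(
      intake_wave1 = w1$intake, intake_wave2 = w2$intake,
      response_wave1 = w1$response, response_wave2 = w2$response,
      truth = list(latent_scores = list(wave1 = z1, wave2 = z2),
                   latent_intake = list(wave1 = w1$latent_intake,
                                        wave2 = w2$latent_intake),
                   true_weights = config$true_weights,
                   response_loadings = config$response_loadings,
                   realized_tracking = realized),
      config = config
    ), class = "synthetic_cohort")
  })
}

#' Append pure-noise food groups to an intake table
#'
#' Adds `n_noise` food columns that are independent of everything else:
#' skewed, partially zero-inflated transforms of pure Gaussian noise. Used to
#' emulate a wider a-priori food-group list in which most groups carry no
#' pattern signal, the regime in which cross-validated pattern selection is
#' expected to deteriorate.
#'
#' @param intake An intake table.
#' @param n_noise Number of noise food columns to append.
#' @param seed Integer seed for the noise draws.
#' @return The intake table with `noise_food_*` columns appended (before any
#'   `energy_kj` column).
#' @export
add_noise_foods <- function(intake, n_noise, seed = NULL) {
  n <- nrow(intake)
  with_seed_if(seed, {
    lat <- matrix(rnorm(n * n_noise), n, n_noise,
                  dimnames = list(NULL, paste0("noise_food_", seq_len(n_noise))))
    specs <- tibble(
      food = colnames(lat),
      zero_inflation_pi = rep(c(0, 0.3, 0.6), length.out = n_noise),
      log_scale_sigma = rep(c(0.5, 0.8, 1.0), length.out = n_noise),
      median_g_per_day = rep(c(50, 10, 0), length.out = n_noise),
      p90_g_per_day = rep(c(150, 40, 30), length.out = n_noise))
    noise <- apply_intake_scale(lat, specs)
    out <- bind_cols(as_tibble(intake), as_tibble(as.data.frame(noise)))
    if (ENERGY_COL %in% names(out)) {
      out <- out[c(setdiff(names(out), ENERGY_COL), ENERGY_COL)]
    }
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic two-wave cohort:", x$config$n_participants, "participants,",
      x$config$n_foods, "food groups,", x$config$n_responses, "responses,",
      x$config$n_true_patterns, "latent patterns\n")
  cat("Realized cross-wave latent tracking:",
      paste(sprintf("%.3f", x$truth$realized_tracking), collapse = ", "), "\n")
  invisible(x)
}
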