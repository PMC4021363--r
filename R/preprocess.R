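#' Compute body mass index
#'
#' @param weight_kg Body weight in kilograms (> 0).
#' @param height_m Standing height in metres (> 0).
#' @return BMI in kg/m^2, vectorised over the inputs.
#' @examples
#' compute_bmi(80, 1.79)
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_m)) ||
      any(weight_kg <= 0) || any(height_m <= 0)) {
    abort("weight_kg and height_m must be positive and finite")
  }
  weight_kg / height_m^2
}

#' Standardize the variable columns of a participant table
#'
#' Centers and scales each variable column to mean 0 and sample standard
#' deviation 1 (the n - 1 convention, used consistently throughout the
#' package). The column means and SDs are stored so the same scaling can be
#' applied to another wave's data, which fixed-weight confirmatory scoring
#' needs.
#'
#' @param data A data frame of participants by variables. `participant_id`,
#'   `wave` and `energy_kj` columns are carried along as metadata, not scaled.
#' @param cols Optional character vector restricting which columns to scale.
#' @return An object of class `std_matrix`: a list with `values` (numeric
#'   matrix of z-scores), `center`, `scale` (named vectors), and `wave`.
#' @examples
#' standardize(data.frame(a = c(1, 2, 3), b = c(2, 4, 8)))
#' @export
standardize <- function(data, cols = NULL) {
  m <- table_matrix(data, cols)
  if (nrow(m) < 2) abort("need at least 2 rows to standardize")
  ctr <- colMeans(m)
  scl <- col_sds(m)
  bad <- names(scl)[scl == 0 | !is.finite(scl)]
  if (length(bad) > 0) {
    abort(paste0("constant column(s) cannot be standardized: ",
                 paste(bad, collapse = ", ")))
  }
  z <- sweep(sweep(m, 2, ctr, "-"), 2, scl, "/")
  structure(
    list(values = z, center = ctr, scale = scl,
         wave = if ("wave" %in% names(data)) as.character(data$wave[1]) else NA_character_,
         participant_id = if ("participant_id" %in% names(data)) data$participant_id else NULL),
    class = "std_matrix"
  )
}

#' Apply a stored standardization to new data
#'
#' @param std A `std_matrix` whose center/scale should be reused.
#' @param data New data containing the same variable columns.
#' @return Numeric matrix of z-scores on `std`'s scale.
#' @export
apply_standardization <- function(std, data) {
  stopifnot(inherits(std, "std_matrix"))
  m <- table_matrix(data, names(std$center))
  sweep(sweep(m, 2, std$center, "-"), 2, std$scale, "/")
}

#' Invert a standardization
#'
#' @param std A `std_matrix`.
#' @param values Matrix of z-scores (defaults to `std$values`).
#' @return Matrix on the original scale.
#' @export
unstandardize <- function(std, values = std$values) {
  stopifnot(inherits(std, "std_matrix"))
  sweep(sweep(values, 2, std$scale, "*"), 2, std$center, "+")
}

#' @export
print.std_matrix <- function(x, ...) {
  cat("Standardized matrix:", nrow(x$values), "participants x",
      ncol(x$values), "variables",
      if (!is.na(x$wave)) paste0("(wave ", x$wave, ")") else "", "\n")
  invisible(x)
}

#' Energy-adjust food-group intakes by the residual method
#'
#' Replaces each intake column by the residual from a simple linear regression
#' of intake on total energy, plus the intake mean, so units (g/day) and the
#' column mean are preserved while the linear association with energy is
#' removed. Used as a sensitivity analysis before pattern extraction.
#'
#' @param data An intake table with food columns and an `energy_kj` column
#'   (or supply `energy` directly).
#' @param energy Optional numeric vector of energy intakes (kJ/day) overriding
#'   the `energy_kj` column.
#' @return A tibble with the same shape as `data`, food columns replaced by
#'   energy-adjusted values.
#' @examples
#' d <- data.frame(bread = c(100, 150, 120, 90), energy_kj = c(8000, 10000, 9000, 7000))
#' energy_adjust(d)
#' @export
energy_adjust <- function(data, energy = NULL) {
  if (is.null(energy)) {
    if (!ENERGY_COL %in% names(data)) abort("no energy_kj column and no energy vector given")
    energy <- data[[ENERGY_COL]]
  }
  if (any(!is.finite(energy)) || any(energy <= 0)) abort("energy must be positive and finite")
  if (sd(energy) == 0) abort("energy is constant; residual adjustment undefined")
  m <- table_matrix(data)
  e <- cbind(1, energy)
  fit <- lm.fit(e, m)
  adj <- sweep(as.matrix(fit$residuals), 2, colMeans(m), "+")
  out <- as_tibble(data)
  out[colnames(m)] <- as.data.frame(adj)
  out
}

#' Cross-wave descriptive statistics for food-group intakes
#'
#' For each food column, reports the median and 10th/90th percentiles per wave
#' and the Spearman rank correlation between waves on paired participants.
#' Spearman is used because food-group intakes are right-skewed and often
#' zero-inflated; ties (pervasive with zero inflation) get average ranks.
#' Quantiles use linear interpolation between order statistics (type 7).
#' A food with zero variance in either wave gets `NA` correlation, not 0.
#'
#' @param intake_wave1,intake_wave2 Intake tables with identical food columns
#'   and aligned participants.
#' @return A tibble with one row per food: `food`, `median_w1`, `p10_w1`,
#'   `p90_w1`, `median_w2`, `p10_w2`, `p90_w2`, `spearman_rho`.
#' @export
cross_wave_descriptives <- function(intake_wave1, intake_wave2) {
  check_aligned_ids(intake_wave1, intake_wave2, "intake waves")
  m1 <- table_matrix(intake_wave1)
  m2 <- table_matrix(intake_wave2)
  if (!identical(colnames(m1), colnames(m2))) {
    abort("intake waves must have identical food columns in the same order")
  }
  if (nrow(m1) != nrow(m2)) abort("intake waves must have the same participants")
  purrr::map_dfr(colnames(m1), function(f) {
    x <- m1[, f]; y <- m2[, f]
    rho <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y, method = "spearman")
    tibble(
      food = f,
      median_w1 = median(x), p10_w1 = quantile(x, 0.10, names = FALSE),
      p90_w1 = quantile(x, 0.90, names = FALSE),
      median_w2 = median(y), p10_w2 = quantile(y, 0.10, names = FALSE),
      p90_w2 = quantile(y, 0.90, names = FALSE),
      spearman_rho = rho
    )
  })
}
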