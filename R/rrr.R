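#' Fit a reduced rank regression dietary pattern model
#'
#' Extracts `k` dietary patterns: linear combinations of (standardized)
#' food-group intakes that maximize the explained variation in a set of
#' (standardized) risk-factor responses. Computation follows the redundancy
#' analysis route: OLS fitted responses are computed, their covariance is
#' eigendecomposed, and pattern weights are the OLS coefficient matrix times
#' the response eigenvectors. Participant scores are z-scores (mean 0, sample
#' SD 1) and the stored weights are in the scaling that reproduces those
#' z-scores exactly from standardized intakes. Each factor's sign is fixed by
#' making its largest-magnitude food weight positive.
#'
#' Both predictor and response tables are standardized to mean 0 / SD 1
#' (sample SD) before fitting, so the per-response explained variation of a
#' factor is 100 times the squared correlation of the factor score with that
#' response.
#'
#' @param intake Data frame of food-group intakes (participants x foods;
#'   `participant_id`, `wave`, `energy_kj` columns are ignored as predictors),
#'   or a `std_matrix` from [standardize()].
#' @param response Data frame of risk-factor responses, or a `std_matrix`.
#' @param k Number of patterns to extract, `1 <= k <= min(#foods, #responses)`.
#' @param foods,responses Optional character vectors restricting the columns
#'   used.
#' @return An object of class `rrr_fit` with elements `weights` (foods x k,
#'   z-score scaling), `loadings` (foods x k correlation scaling),
#'   `response_loadings` (responses x k, orthonormal columns), `eigenvalues`,
#'   `scores` (tibble of training z-scores), `explained` (tibble, see
#'   [explained_variation()]), the training standardization parameters, and
#'   dimensions.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_participants = 150, seed = 7))
#' fit <- fit_rrr(cohort$intake_wave1, cohort$response_wave1, k = 3)
#' fit
#' @export
fit_rrr <- function(intake, response, k, foods = NULL, responses = NULL) {
  xs <- if (inherits(intake, "std_matrix")) intake else standardize(intake, foods)
  ys <- if (inherits(response, "std_matrix")) response else standardize(response, responses)
  X <- xs$values
  Y <- ys$values
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) abort("intake and response tables must have the same participants")
  if (k < 1 || k > min(p, q)) abort("k must satisfy 1 <= k <= min(#foods, #responses)")
  if (n <= p) abort("need more participants than food groups (n > p) for OLS")

  xtx <- crossprod(X)
  cond <- kappa(xtx, exact = FALSE)
  B <- tryCatch(solve(xtx, crossprod(X, Y)), error = function(e) NULL)
  if (is.null(B) || cond > 1e12) {
    abort(paste0("predictor cross-product matrix is (near-)singular; ",
                 "condition number ", format(cond, digits = 3)))
  }
  Yhat <- X %*% B
  eg <- eigen(crossprod(Yhat) / (n - 1), symmetric = TRUE)
  rank_yhat <- sum(eg$values > max(eg$values, 0) * 1e-10)
  if (k > rank_yhat) {
    abort(paste0("k = ", k, " exceeds the rank of the fitted responses (", rank_yhat, ")"))
  }
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  lambda <- eg$values[seq_len(k)]
  alpha_w <- B %*% v
  t_raw <- X %*% alpha_w
  sdt <- col_sds(t_raw)
  if (any(sdt == 0)) abort("degenerate factor with zero score variance")
  weights <- sweep(alpha_w, 2, sdt, "/")
  scores <- sweep(t_raw, 2, sdt, "/")
  # sign convention: largest-|weight| food positive per factor
  flip <- vapply(seq_len(k), function(j) {
    i <- which.max(abs(weights[, j]))
    if (weights[i, j] < 0) -1 else 1
  }, numeric(1))
  weights <- sweep(weights, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  v <- sweep(v, 2, flip, "*")
  dimnames(weights) <- list(colnames(X), paste0("factor", seq_len(k)))
  colnames(scores) <- colnames(weights)
  dimnames(v) <- list(colnames(Y), colnames(weights))
  loadings <- cor(X, scores)

  fit <- structure(list(
    weights = weights, loadings = loadings, response_loadings = v,
    eigenvalues = lambda, k = k, n = n, p = p, q = q,
    x_center = xs$center, x_scale = xs$scale,
    y_center = ys$center, y_scale = ys$scale,
    wave = xs$wave, cond = cond,
    scores = bind_cols(
      if (!is.null(xs$participant_id)) tibble(participant_id = xs$participant_id) else NULL,
      as_tibble(as.data.frame(scores))),
    X = X, Y = Y
  ), class = "rrr_fit")
  fit$explained <- explained_variation(fit)
  fit$labels <- label_patterns(fit)
  fit
}

# Score matrix (participants x k) from a fit.
score_matrix <- function(fit) {
  as.matrix(fit$scores[paste0("factor", seq_len(fit$k))])
}

#' Project new intake data onto fitted dietary patterns
#'
#' Standardizes the new intake table and multiplies by the model's pattern
#' weights; because the weights carry the z-score scaling of the training
#' fit, projecting the training table itself reproduces the stored training
#' z-scores exactly.
#'
#' @param fit An `rrr_fit`.
#' @param intake New intake table containing the model's food columns.
#' @param standardize_by `"data"` (default) standardizes the new table by its
#'   own means/SDs; `"training"` reuses the model's stored parameters.
#' @return Tibble of scores (participants x k), with `participant_id` when
#'   available.
#' @export
project_scores <- function(fit, intake, standardize_by = c("data", "training")) {
  stopifnot(inherits(fit, "rrr_fit"))
  standardize_by <- match.arg(standardize_by)
  foods <- rownames(fit$weights)
  if (standardize_by == "data") {
    xs <- standardize(intake, foods)
    Z <- xs$values
  } else {
    Z <- apply_standardization(
      structure(list(center = fit$x_center, scale = fit$x_scale), class = "std_matrix"),
      intake)
  }
  sc <- Z %*% fit$weights
  bind_cols(
    if (is.data.frame(intake) && "participant_id" %in% names(intake))
      tibble(participant_id = intake$participant_id) else NULL,
    as_tibble(as.data.frame(sc)))
}

#' Explained variation of dietary patterns
#'
#' For each factor and response, 100 times the squared correlation of the
#' factor z-score with the (standardized) response; summary rows give the
#' mean over all responses ("all_responses") and the mean squared correlation
#' of the factor score with every food column ("all_foods"). A `total`
#' column sums across factors. Summed over a full-rank set of factors, the
#' per-response column equals 100 times the OLS R-squared of that response
#' on the foods.
#'
#' @param fit An `rrr_fit`.
#' @param intake,response Optional tables to evaluate on; default is the
#'   training data stored in the fit.
#' @return A tibble with columns `term`, `factor1` ... `factork`, `total`.
#' @export
explained_variation <- function(fit, intake = NULL, response = NULL) {
  stopifnot(inherits(fit, "rrr_fit"))
  if (is.null(intake)) {
    X <- fit$X
    S <- score_matrix(fit)
  } else {
    X <- standardize(intake, rownames(fit$weights))$values
    S <- X %*% fit$weights
  }
  Y <- if (is.null(response)) fit$Y else
    standardize(response, rownames(fit$response_loadings))$values
  ry <- cor(Y, S)^2 * 100   # responses x k
  rx <- cor(X, S)^2 * 100   # foods x k
  cells <- rbind(ry, all_responses = colMeans(ry), all_foods = colMeans(rx))
  out <- as_tibble(as.data.frame(cells))
  names(out) <- paste0("factor", seq_len(ncol(cells)))
  bind_cols(tibble(term = rownames(cells)), out,
            tibble(total = unname(rowSums(cells))))
}

#' Label dietary patterns and flag high-weight foods
#'
#' Flags foods whose weight magnitude strictly exceeds the threshold
#' (the conventional |w| > 0.10 rule) and names each factor after its
#' largest-magnitude food, prefixed "(low in) " when that weight is negative.
#'
#' @param fit An `rrr_fit`.
#' @param threshold Highlight threshold on |weight| (strict inequality).
#' @return A tibble with one row per factor: `factor`, `label`,
#'   `high_weight_foods` (list column of tibbles with `food`, `weight`).
#' @export
label_patterns <- function(fit, threshold = 0.10) {
  stopifnot(inherits(fit, "rrr_fit"))
  w <- fit$weights
  purrr::map_dfr(seq_len(ncol(w)), function(j) {
    wj <- w[, j]
    i <- which.max(abs(wj))
    label <- if (wj[i] < 0) paste0("(low in) ", names(wj)[i]) else names(wj)[i]
    hi <- which(abs(wj) > threshold)
    tibble(factor = colnames(w)[j], label = label,
           high_weight_foods = list(tibble(food = names(wj)[hi],
                                           weight = unname(wj[hi]))))
  })
}

#' @export
print.rrr_fit <- function(x, ...) {
  cat("Reduced rank regression fit:", x$k, "pattern(s),",
      x$n, "participants,", x$p, "food groups,", x$q, "responses\n")
  ev <- x$explained
  allr <- ev[ev$term == "all_responses", ]
  allf <- ev[ev$term == "all_foods", ]
  cat("Explained variation, all responses (%):",
      paste(sprintf("%.1f", unlist(allr[paste0("factor", seq_len(x$k))])), collapse = ", "),
      sprintf("(total %.1f)\n", allr$total))
  cat("Explained variation, all foods (%):   ",
      paste(sprintf("%.1f", unlist(allf[paste0("factor", seq_len(x$k))])), collapse = ", "),
      sprintf("(total %.1f)\n", allf$total))
  for (j in seq_len(x$k)) cat("  ", x$labels$factor[j], ": ", x$labels$label[j], "\n", sep = "")
  invisible(x)
}

#' Tidy a reduced rank regression fit
#'
#' @param x An `rrr_fit`.
#' @param scaling `"weights"` (z-score/regression scaling, default) or
#'   `"loadings"` (correlation scaling).
#' @param threshold Highlight threshold for the `high_weight` flag.
#' @param ... Unused.
#' @return A tibble with one row per food x factor: `food`, `factor`,
#'   `weight`, `high_weight`.
#' @export
tidy.rrr_fit <- function(x, scaling = c("weights", "loadings"),
                         threshold = 0.10, ...) {
  scaling <- match.arg(scaling)
  m <- if (scaling == "weights") x$weights else x$loadings
  as_tibble(as.data.frame(m)) %>%
    mutate(food = rownames(m)) %>%
    tidyr::pivot_longer(-"food", names_to = "factor", values_to = "weight") %>%
    mutate(high_weight = abs(.data$weight) > threshold) %>%
    arrange(.data$factor, dplyr::desc(abs(.data$weight)))
}

#' Glance at a reduced rank regression fit
#'
#' @param x An `rrr_fit`.
#' @param ... Unused.
#' @return A one-row tibble with dimensions, leading eigenvalue and total
#'   explained variation in responses and foods.
#' @export
glance.rrr_fit <- function(x, ...) {
  ev <- x$explained
  tibble(n = x$n, n_foods = x$p, n_responses = x$q, k = x$k,
         eigenvalue_1 = x$eigenvalues[1],
         explained_responses_pct = ev$total[ev$term == "all_responses"],
         explained_foods_pct = ev$total[ev$term == "all_foods"])
}

#' Plot pattern weights of a reduced rank regression fit
#'
#' @param object An `rrr_fit`.
#' @param threshold Highlight threshold drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot of weights by food, faceted by factor.
#' @export
autoplot.rrr_fit <- function(object, threshold = 0.10, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = stats::reorder(.data$food, .data$weight),
                 y = .data$weight, fill = .data$high_weight)) +
    geom_col() +
    geom_hline(yintercept = c(-threshold, threshold), linetype = 2, colour = "grey40") +
    coord_flip() +
    facet_wrap(~factor) +
    labs(x = NULL, y = "pattern weight", fill = paste0("|w| > ", threshold)) +
    theme_minimal()
}
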