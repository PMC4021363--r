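#' Confirmatory (fixed-weight) pattern scores
#'
#' Applies the pattern weights fixed in one wave to the standardized intake
#' data of another wave, then rescales each score to SD 1 so correlations are
#' comparable across exploratory and confirmatory blocks. By default the
#' intake table is standardized by its own means/SDs; set
#' `standardize_by = "training"` to reuse the weight wave's parameters.
#'
#' @param fit An `rrr_fit` providing the fixed weights (the "loading wave").
#' @param intake Intake table of the "diet wave" to score.
#' @param standardize_by `"data"` (default) or `"training"`.
#' @return A tibble of scores with attributes `loading_wave` and `diet_wave`.
#' @export
confirmatory_score <- function(fit, intake, standardize_by = c("data", "training")) {
  standardize_by <- match.arg(standardize_by)
  sc <- project_scores(fit, intake, standardize_by = standardize_by)
  fac <- paste0("factor", seq_len(fit$k))
  for (f in fac) {
    s <- sc[[f]]
    sc[[f]] <- (s - mean(s)) / sd(s)
  }
  attr(sc, "loading_wave") <- fit$wave
  attr(sc, "diet_wave") <- if (is.data.frame(intake) && "wave" %in% names(intake))
    as.character(intake$wave[1]) else NA_character_
  sc
}

#' Align factor signs of one fitted model to another
#'
#' Factor signs in RRR are arbitrary; for cross-wave comparison each wave-B
#' factor is flipped iff the dot product of its weight vector with the
#' index-matched wave-A factor's weights is negative.
#'
#' @param fit_a,fit_b `rrr_fit` objects over the same food universe with the
#'   same k.
#' @return Numeric vector of +1/-1 per factor of `fit_b`.
#' @export
align_signs <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "rrr_fit"), inherits(fit_b, "rrr_fit"))
  if (!identical(rownames(fit_a$weights), rownames(fit_b$weights))) {
    abort("models must share the same food universe")
  }
  if (fit_a$k != fit_b$k) abort("models must have the same number of factors")
  d <- diag(crossprod(fit_a$weights, fit_b$weights))
  ifelse(d < 0, -1, 1)
}

# Apply a sign vector to a fitted model's factors.
flip_factors <- function(fit, signs) {
  fit$weights <- sweep(fit$weights, 2, signs, "*")
  fit$loadings <- sweep(fit$loadings, 2, signs, "*")
  fit$response_loadings <- sweep(fit$response_loadings, 2, signs, "*")
  fac <- paste0("factor", seq_len(fit$k))
  for (j in seq_along(fac)) fit$scores[[fac[j]]] <- fit$scores[[fac[j]]] * signs[j]
  fit$labels <- label_patterns(fit)
  fit
}

#' Match factors across two fitted models by weight-vector cosine
#'
#' Diagnostic helper: finds the factor permutation maximizing the total
#' absolute cosine similarity between weight vectors. Cross-wave reporting
#' matches factors by index; this reveals when that convention mispairs.
#'
#' @param fit_a,fit_b `rrr_fit` objects over the same food universe.
#' @return Tibble with `factor_a`, `factor_b`, `abs_cosine`.
#' @export
match_factors <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "rrr_fit"), inherits(fit_b, "rrr_fit"))
  k <- min(fit_a$k, fit_b$k)
  cs <- abs(crossprod(fit_a$weights[, seq_len(k), drop = FALSE],
                      fit_b$weights[, seq_len(k), drop = FALSE])) /
    outer(sqrt(colSums(fit_a$weights[, seq_len(k), drop = FALSE]^2)),
          sqrt(colSums(fit_b$weights[, seq_len(k), drop = FALSE]^2)))
  perms <- permutations(k)
  tot <- apply(perms, 1, function(pp) sum(cs[cbind(seq_len(k), pp)]))
  best <- perms[which.max(tot), ]
  tibble(factor_a = paste0("factor", seq_len(k)),
         factor_b = paste0("factor", best),
         abs_cosine = cs[cbind(seq_len(k), best)])
}

#' Fisher-z confidence interval for a Pearson correlation
#'
#' @param r Sample correlation(s), |r| < 1.
#' @param n Sample size(s), n > 3.
#' @param level Confidence level (default 0.95).
#' @return Tibble with columns `r`, `n`, `lower`, `upper`.
#' @examples
#' fisher_ci(0.47, 467)
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (any(abs(r) >= 1)) abort("|r| must be < 1 for the Fisher-z interval")
  if (any(n <= 3)) abort("n must exceed 3 for the Fisher-z interval")
  z <- atanh(r)
  zc <- qnorm(1 - (1 - level) / 2)
  half <- zc / sqrt(n - 3)
  tibble(r = r, n = n, lower = tanh(z - half), upper = tanh(z + half))
}

#' Cross-wave stability report for dietary patterns
#'
#' Assembles the full exploratory/confirmatory comparison between two waves:
#' wave-2 factors are sign-aligned to wave-1, confirmatory scores are
#' computed in both directions (diet of one wave, weights of the other), and
#' the Pearson correlation matrix over all score blocks is reported with
#' two-sided p-values and Fisher-z confidence intervals, together with a
#' per-factor structural comparison (high-weight food overlap and weight
#' sign agreement) and the per-food cross-wave Spearman table.
#'
#' @param fit_wave1,fit_wave2 `rrr_fit` objects for the two waves (same k,
#'   same foods).
#' @param intake_wave1,intake_wave2 The intake tables the fits were trained
#'   on (aligned participants across waves).
#' @param conf_level Confidence level for the Fisher intervals.
#' @param highlight_threshold |weight| threshold for the structural
#'   comparison.
#' @param standardize_by Standardization reference for confirmatory scoring
#'   (see [confirmatory_score()]).
#' @return An object of class `stability_report`: `correlations` (long
#'   tibble: `score_a`, `score_b`, `r`, `p_value`, `lower`, `upper`),
#'   `cor_matrix`, `structure` (per-factor tibble), `food_tracking`
#'   (Spearman table), `signs` (alignment applied to wave 2), `labels`.
#' @export
stability_report <- function(fit_wave1, fit_wave2, intake_wave1, intake_wave2,
                             conf_level = 0.95, highlight_threshold = 0.10,
                             standardize_by = c("data", "training")) {
  standardize_by <- match.arg(standardize_by)
  signs <- align_signs(fit_wave1, fit_wave2)
  fit_wave2 <- flip_factors(fit_wave2, signs)
  k <- fit_wave1$k
  fac <- paste0("factor", seq_len(k))

  blocks <- list(
    exploratory_w1 = as.matrix(fit_wave1$scores[fac]),
    exploratory_w2 = as.matrix(fit_wave2$scores[fac]),
    confirmatory_d2_l1 = as.matrix(
      confirmatory_score(fit_wave1, intake_wave2, standardize_by)[fac]),
    confirmatory_d1_l2 = as.matrix(
      confirmatory_score(fit_wave2, intake_wave1, standardize_by)[fac])
  )
  all_scores <- do.call(cbind, purrr::imap(blocks, function(m, nm) {
    colnames(m) <- paste0(nm, ".", fac)
    m
  }))
  n <- nrow(all_scores)
  cm <- cor(all_scores)
  nm <- colnames(cm)
  pairs <- which(upper.tri(cm, diag = TRUE), arr.ind = TRUE)
  correlations <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    r <- cm[a, b]
    if (a == b) {
      tibble(score_a = nm[a], score_b = nm[b], r = 1,
             p_value = 0, lower = 1, upper = 1)
    } else {
      ci <- if (abs(r) < 1) fisher_ci(r, n, conf_level) else
        tibble(lower = r, upper = r)
      tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
      tibble(score_a = nm[a], score_b = nm[b], r = r,
             p_value = 2 * pt(-abs(tstat), n - 2),
             lower = ci$lower, upper = ci$upper)
    }
  })

  hi_set <- function(fit, j) {
    w <- fit$weights[, j]
    names(w)[abs(w) > highlight_threshold]
  }
  structure_cmp <- purrr::map_dfr(seq_len(k), function(j) {
    h1 <- hi_set(fit_wave1, j); h2 <- hi_set(fit_wave2, j)
    shared <- intersect(h1, h2)
    agree <- if (length(shared)) {
      mean(sign(fit_wave1$weights[shared, j]) == sign(fit_wave2$weights[shared, j]))
    } else NA_real_
    tibble(factor = fac[j],
           label_w1 = fit_wave1$labels$label[j],
           label_w2 = fit_wave2$labels$label[j],
           n_high_w1 = length(h1), n_high_w2 = length(h2),
           shared_high = list(shared),
           n_shared = length(shared),
           sign_agreement = agree)
  })

  structure(list(
    correlations = correlations, cor_matrix = cm,
    structure = structure_cmp,
    food_tracking = cross_wave_descriptives(intake_wave1, intake_wave2),
    signs = signs, n = n, conf_level = conf_level,
    labels = list(wave1 = fit_wave1$labels, wave2 = fit_wave2$labels)
  ), class = "stability_report")
}

# Convenience accessor: one entry of the correlation matrix.
stability_cor <- function(report, a, b) {
  report$cor_matrix[a, b]
}

#' @export
print.stability_report <- function(x, ...) {
  k <- sum(startsWith(colnames(x$cor_matrix), "exploratory_w1"))
  cat("Cross-wave pattern stability (n =", x$n, "participants,", k, "factors)\n")
  cat("Exploratory wave1 x exploratory wave2 (matched factors):\n")
  for (j in seq_len(k)) {
    a <- paste0("exploratory_w1.factor", j)
    b <- paste0("exploratory_w2.factor", j)
    row <- x$correlations[x$correlations$score_a == a & x$correlations$score_b == b |
                          x$correlations$score_a == b & x$correlations$score_b == a, ]
    cat(sprintf("  factor%d: r = %.2f (%.0f%% CI %.2f-%.2f)\n", j, row$r,
                100 * x$conf_level, row$lower, row$upper))
  }
  invisible(x)
}

#' @rdname stability_report
#' @param x A `stability_report`.
#' @param ... Unused.
#' @export
tidy.stability_report <- function(x, ...) x$correlations

#' Plot a cross-wave stability correlation matrix
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot heat map of the score correlation matrix.
#' @export
autoplot.stability_report <- function(object, ...) {
  cm <- object$cor_matrix
  df <- as_tibble(as.data.frame(cm)) %>%
    mutate(score_a = rownames(cm)) %>%
    tidyr::pivot_longer(-"score_a", names_to = "score_b", values_to = "r")
  ggplot(df, aes(x = .data$score_a, y = .data$score_b, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
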