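#' Cross-validated PRESS curve for pattern-count selection
#'
#' Monte-Carlo cross-validation: `n_splits` independent random holdouts of a
#' `test_fraction` of participants. On each split the rank-k regression of
#' standardized responses on standardized foods is fitted on the training
#' rows for every k in 0..k_max (k = 0 predicts the training mean, i.e. 0 on
#' the standardized scale), held-out standardized responses are predicted,
#' and squared errors are accumulated per held-out cell
#' (participant x response). PRESS_k is the sum over all splits and cells.
#' Van der Voet's paired sign-flip randomization test then compares each k's
#' per-cell errors against those of the PRESS-minimizing k, and the chosen
#' pattern count is the smallest k whose PRESS is not significantly worse
#' than the minimum.
#'
#' @param intake Food-group intake table (data frame).
#' @param response Risk-factor table (data frame).
#' @param k_max Largest pattern count to evaluate; default `min(p, q)`.
#' @param n_splits Number of random test sets.
#' @param test_fraction Fraction of participants held out per split.
#' @param n_randomizations Sign-flip draws for each Van der Voet test.
#' @param alpha Significance level used by [choose_n_patterns()].
#' @param seed Integer seed making splits and randomization reproducible.
#' @param foods,responses Optional column subsets.
#' @return An object of class `press_curve`: `curve` (tibble with `k`,
#'   `press`, `p_value`), `chosen_k`, `k_min` (the PRESS minimizer),
#'   `cell_errors` (list of per-cell squared-error vectors per k), and the
#'   settings used.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_participants = 120, seed = 3))
#' pc <- press_curve(cohort$intake_wave1, cohort$response_wave1,
#'                   k_max = 3, n_splits = 30, n_randomizations = 199, seed = 3)
#' pc
#' @export
press_curve <- function(intake, response, k_max = NULL,
                        n_splits = 1000, test_fraction = 0.1,
                        n_randomizations = 2000, alpha = 0.10,
                        seed = NULL, foods = NULL, responses = NULL) {
  X <- table_matrix(intake, foods)
  Y <- table_matrix(response, responses, drop_energy = FALSE)
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) abort("intake and response tables must have the same participants")
  if (is.null(k_max)) k_max <- min(p, q)
  if (k_max > min(p, q)) abort("k_max must not exceed min(#foods, #responses)")
  n_test <- max(1L, round(test_fraction * n))
  n_train <- n - n_test
  if (n_train <= p) {
    abort(paste0("training rows (", n_train, ") must exceed the number of foods (",
                 p, "); lower test_fraction or reduce predictors"))
  }

  with_seed_if(seed, {
    len <- n_splits * n_test * q
    errs <- lapply(seq_len(k_max + 1), function(i) numeric(len))
    pos <- 0L
    for (s in seq_len(n_splits)) {
      te <- sample.int(n, n_test)
      Xtr <- X[-te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      Ytr <- Y[-te, , drop = FALSE]; Yte <- Y[te, , drop = FALSE]
      xm <- colMeans(Xtr); xs <- col_sds(Xtr)
      ym <- colMeans(Ytr); ys <- col_sds(Ytr)
      keep <- xs > 0                       # a food constant in training carries no signal
      ys[ys == 0] <- 1
      Ztr <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, xm[keep], "-"), 2, xs[keep], "/")
      Zte <- sweep(sweep(Xte[, keep, drop = FALSE], 2, xm[keep], "-"), 2, xs[keep], "/")
      Wtr <- sweep(sweep(Ytr, 2, ym, "-"), 2, ys, "/")
      Wte <- sweep(sweep(Yte, 2, ym, "-"), 2, ys, "/")
      fit <- lm.fit(Ztr, Wtr)
      B <- fit$coefficients
      if (is.matrix(B)) B[is.na(B)] <- 0 else B[is.na(B)] <- 0
      B <- as.matrix(B)
      Yhat_tr <- Ztr %*% B
      V <- eigen(crossprod(Yhat_tr) / (n_train - 1), symmetric = TRUE)$vectors
      Yhat_te <- Zte %*% B
      idx <- pos + seq_len(n_test * q)
      errs[[1]][idx] <- as.numeric(Wte^2)
      for (k in seq_len(k_max)) {
        Vk <- V[, seq_len(k), drop = FALSE]
        pred <- Yhat_te %*% Vk %*% t(Vk)
        errs[[k + 1]][idx] <- as.numeric((Wte - pred)^2)
      }
      pos <- pos + n_test * q
    }
    press <- vapply(errs, sum, numeric(1))
    k_min <- which.min(press) - 1L
    pvals <- vapply(seq_along(errs), function(i) {
      # PRESS values equal to the minimum at double precision are tied, not
      # "worse": skip the randomization test for them
      if (press[i] - press[k_min + 1L] <= 1e-12 * max(press)) return(1)
      vandervoet_test(errs[[i]], errs[[k_min + 1L]],
                      n_randomizations = n_randomizations)$p_value
    }, numeric(1))
    curve <- tibble(k = 0:k_max, press = press, p_value = pvals)
    out <- structure(list(
      curve = curve, k_min = k_min, cell_errors = errs,
      n = n, n_splits = n_splits, test_fraction = test_fraction,
      n_randomizations = n_randomizations, alpha = alpha
    ), class = "press_curve")
    out$chosen_k <- choose_n_patterns(out, alpha)
    out
  })
}

#' Van der Voet's paired randomization test on squared prediction errors
#'
#' Tests whether two models have equal predictive ability by comparing
#' paired per-cell squared prediction errors. The statistic is the mean
#' paired difference; its null distribution is built by independently
#' flipping the sign of each paired difference, and the p-value uses the
#' add-one estimator `p = (1 + #randomizations with |T*| >= |T|) /
#' (1 + n_randomizations)`.
#'
#' @param errors_a,errors_b Paired vectors of squared prediction errors.
#' @param n_randomizations Number of sign-flip draws.
#' @param seed Optional seed (omit to draw from the current RNG stream, as
#'   [press_curve()] does).
#' @return A list with `statistic` (mean difference `errors_a - errors_b`)
#'   and `p_value`.
#' @export
vandervoet_test <- function(errors_a, errors_b, n_randomizations = 2000,
                            seed = NULL) {
  if (length(errors_a) != length(errors_b)) {
    abort("paired error vectors must have equal length")
  }
  d <- errors_a - errors_b
  len <- length(d)
  t_obs <- mean(d)
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1))
  }
  with_seed_if(seed, {
    count <- 0L
    remaining <- n_randomizations
    chunk <- max(1L, min(n_randomizations, floor(5e6 / len)))
    tol <- 1e-12 * max(abs(d))
    while (remaining > 0L) {
      nc <- min(chunk, remaining)
      s <- matrix((runif(nc * len) < 0.5) * 2 - 1, nc, len)
      t_star <- as.numeric(s %*% d) / len
      count <- count + sum(abs(t_star) >= abs(t_obs) - tol)
      remaining <- remaining - nc
    }
    list(statistic = t_obs, p_value = (1 + count) / (1 + n_randomizations))
  })
}

#' Choose the number of dietary patterns from a PRESS curve
#'
#' Returns the smallest k whose PRESS is not significantly worse than the
#' PRESS minimum (Van der Voet p-value >= alpha). k = 0 means no pattern
#' predicts the responses better than the training mean.
#'
#' @param curve A `press_curve`.
#' @param alpha Significance level (default 0.10).
#' @return Integer chosen k (never larger than the PRESS minimizer).
#' @export
choose_n_patterns <- function(curve, alpha = 0.10) {
  stopifnot(inherits(curve, "press_curve"))
  ok <- curve$curve$k[curve$curve$p_value >= alpha]
  as.integer(min(ok))
}

#' @export
print.press_curve <- function(x, ...) {
  cat("PRESS curve over", x$n_splits, "random splits (test fraction",
      x$test_fraction, "):\n")
  print(as.data.frame(x$curve), row.names = FALSE)
  cat("PRESS minimized at k =", x$k_min, "; chosen k =", x$chosen_k,
      "(alpha =", x$alpha, ")\n")
  invisible(x)
}

#' @rdname press_curve
#' @param x A `press_curve`.
#' @param ... Unused.
#' @export
tidy.press_curve <- function(x, ...) x$curve

#' Plot a PRESS curve
#'
#' @param object A `press_curve`.
#' @param ... Unused.
#' @return A ggplot of PRESS against pattern count, with the chosen k marked.
#' @export
autoplot.press_curve <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$k, y = .data$press)) +
    geom_line() + geom_point() +
    geom_point(data = object$curve[object$curve$k == object$chosen_k, ],
               colour = "red", size = 3) +
    labs(x = "number of patterns k", y = "PRESS",
         title = paste0("Chosen k = ", object$chosen_k)) +
    theme_minimal()
}
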