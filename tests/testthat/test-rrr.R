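test_that("with one response the factor score is the standardized OLS fit", {
  inst <- random_instance(1, n = 80, p = 6, q = 1)
  fit <- fit_rrr(inst$intake, inst$response, k = 1)
  X <- scale(as.matrix(inst$intake))
  y <- scale(as.matrix(inst$response))[, 1]
  fitted <- X %*% solve(crossprod(X), crossprod(X, y))
  expect_equal(abs(cor(fit$scores$factor1, fitted))[1, 1], 1, tolerance = 1e-12)
})

test_that("responses inside the predictor span are fully explained", {
  withr::with_seed(2, {
    X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  })
  d <- tibble::as_tibble(as.data.frame(X))
  fit <- fit_rrr(d, d, k = 4)
  ev <- fit$explained
  resp_rows <- !(ev$term %in% c("all_responses", "all_foods"))
  expect_equal(ev$total[resp_rows], rep(100, 4), tolerance = 1e-8)
})

test_that("explained variation is conserved and scores are orthogonal z-scores", {
  for (s in 1:5) {
    inst <- random_instance(s)
    fit <- fit_rrr(inst$intake, inst$response, k = 3)
    X <- scale(as.matrix(inst$intake)); Y <- scale(as.matrix(inst$response))
    r2 <- vapply(seq_len(ncol(Y)), function(j) {
      f <- lm.fit(cbind(1, X), Y[, j])
      1 - sum(f$residuals^2) / sum(Y[, j]^2)
    }, numeric(1))
    ev <- fit$explained
    resp_rows <- !(ev$term %in% c("all_responses", "all_foods"))
    expect_equal(ev$total[resp_rows], 100 * r2, tolerance = 1e-8)

    S <- as.matrix(fit$scores[paste0("factor", 1:3)])
    cc <- cor(S)
    expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
    expect_equal(unname(colMeans(S)), rep(0, 3), tolerance = 1e-10)
    expect_equal(unname(apply(S, 2, sd)), rep(1, 3), tolerance = 1e-10)
    expect_true(all(diff(fit$eigenvalues) <= 1e-12))
    expect_equal(crossprod(fit$response_loadings), diag(3),
                 tolerance = 1e-10, ignore_attr = TRUE)
    # the all-responses row is the arithmetic mean of the response rows
    expect_equal(unlist(ev[ev$term == "all_responses", paste0("factor", 1:3)]),
                 colMeans(as.matrix(ev[resp_rows, paste0("factor", 1:3)])),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("factor-1 weights agree with the generalized-eigenvector oracle", {
  for (s in 1:5) {
    inst <- random_instance(s)
    fit <- fit_rrr(inst$intake, inst$response, k = 1)
    a_star <- rrr_factor1_geneig(as.matrix(inst$intake), as.matrix(inst$response))
    expect_gte(abs_cosine(fit$weights[, 1], a_star), 0.999999)
  }
})

test_that("column permutations and reflections act equivariantly", {
  inst <- random_instance(7)
  fit <- fit_rrr(inst$intake, inst$response, k = 2)

  perm <- c(3, 1, 5, 2, 4)
  fit_p <- fit_rrr(inst$intake[, perm], inst$response, k = 2)
  expect_equal(fit_p$weights, fit$weights[perm, ], tolerance = 1e-10)
  expect_equal(fit_p$scores, fit$scores, tolerance = 1e-10)

  neg <- inst$intake
  neg$x2 <- -neg$x2
  fit_n <- fit_rrr(neg, inst$response, k = 2)
  expect_equal(fit_n$scores, fit$scores, tolerance = 1e-10)
  expect_equal(fit_n$weights["x2", ], -fit$weights["x2", ], tolerance = 1e-10)
  expect_equal(fit_n$weights[-2, ], fit$weights[-2, ], tolerance = 1e-10)
})

test_that("the sign convention makes the dominant food positive", {
  for (s in 1:4) {
    inst <- random_instance(s + 20)
    fit <- fit_rrr(inst$intake, inst$response, k = 3)
    for (j in 1:3) {
      wj <- fit$weights[, j]
      expect_gt(wj[which.max(abs(wj))], 0)
    }
  }
})

test_that("projection reproduces training scores and single-food patterns", {
  co <- small_cohort(seed = 9, n = 100)
  fit <- fit_rrr(co$intake_wave1, co$response_wave1, k = 2)
  again <- project_scores(fit, co$intake_wave1)
  expect_equal(again$factor1, fit$scores$factor1, tolerance = 1e-12)
  expect_equal(again$factor2, fit$scores$factor2, tolerance = 1e-12)

  # a hand-built single-food pattern scores as that food's z-score
  fit1 <- fit
  fit1$weights[] <- 0
  fit1$weights["cheese", 1] <- 1
  sc <- project_scores(fit1, co$intake_wave1)
  z <- as.numeric(scale(co$intake_wave1$cheese))
  expect_equal(sc$factor1, z, tolerance = 1e-12)

  expect_error(project_scores(fit, co$intake_wave1[, 1:5]), "missing")
})

test_that("fit guards its preconditions", {
  inst <- random_instance(3, n = 30, p = 5, q = 3)
  expect_error(fit_rrr(inst$intake, inst$response, k = 4), "k must satisfy")
  expect_error(fit_rrr(inst$intake[1:4, ], inst$response[1:4, ], k = 1), "n > p")
  dup <- inst$intake
  dup$x5 <- dup$x1                    # exactly collinear
  expect_error(fit_rrr(dup, inst$response, k = 1), "singular")
})

test_that("labelling flags strictly above threshold and names the dominant food", {
  co <- small_cohort(seed = 5, n = 120)
  fit <- fit_rrr(co$intake_wave1, co$response_wave1, k = 2)
  w1 <- fit$weights[, 1]
  top <- names(w1)[which.max(abs(w1))]
  lab <- label_patterns(fit, threshold = 0.10)
  expect_equal(lab$label[1], top)
  expect_setequal(lab$high_weight_foods[[1]]$food, names(w1)[abs(w1) > 0.10])

  # a weight exactly at the threshold is not flagged
  thr <- max(abs(w1))
  lab2 <- label_patterns(fit, threshold = thr)
  expect_equal(nrow(lab2$high_weight_foods[[1]]), 0)
  expect_equal(lab2$label[1], top)    # label produced even with no flags

  # after a sign flip the label gains the "(low in)" prefix
  flipped <- fit
  flipped$weights <- -flipped$weights
  lab3 <- label_patterns(flipped)
  expect_equal(lab3$label[1], paste0("(low in) ", top))
})

test_that("tidy, glance and autoplot expose the fit", {
  co <- small_cohort(seed = 5, n = 120)
  fit <- fit_rrr(co$intake_wave1, co$response_wave1, k = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 19 * 2)
  expect_named(td, c("food", "factor", "weight", "high_weight"))
  expect_equal(tidy(fit, scaling = "loadings")$weight[1] == td$weight[1], FALSE)
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_s3_class(autoplot(fit), "ggplot")
})
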