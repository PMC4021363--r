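test_that("same-wave confirmatory scores are the exploratory scores", {
  co <- small_cohort(seed = 1, n = 120)
  fit <- fit_rrr(co$intake_wave1, co$response_wave1, k = 3)
  conf <- confirmatory_score(fit, co$intake_wave1)
  for (j in 1:3) {
    f <- paste0("factor", j)
    expect_equal(conf[[f]], fit$scores[[f]], tolerance = 1e-12)
    expect_equal(cor(conf[[f]], fit$scores[[f]]), 1, tolerance = 1e-12)
  }
  expect_equal(unname(sapply(conf[paste0("factor", 1:3)], sd)), rep(1, 3),
               tolerance = 1e-12)
})

test_that("sign alignment repairs reflections and never changes |r|", {
  co <- small_cohort(seed = 2, n = 120)
  fit1 <- fit_rrr(co$intake_wave1, co$response_wave1, k = 2)
  fit2 <- fit_rrr(co$intake_wave2, co$response_wave2, k = 2)

  expect_equal(unname(align_signs(fit1, fit1)), c(1, 1))

  neg <- fit2
  neg$weights <- -neg$weights
  s <- align_signs(fit2, neg)
  expect_equal(unname(s), c(-1, -1))
  for (j in 1:2) {
    expect_equal(abs_cosine(fit2$weights[, j], s[j] * neg$weights[, j]), 1)
  }

  r_base <- cor(fit1$scores$factor1, fit2$scores$factor1)
  expect_equal(abs(cor(fit1$scores$factor1, -fit2$scores$factor1)), abs(r_base))
})

test_that("factor matching by |cosine| finds the permutation", {
  co <- small_cohort(seed = 3, n = 120)
  fit <- fit_rrr(co$intake_wave1, co$response_wave1, k = 3)
  swapped <- fit
  swapped$weights <- fit$weights[, c(2, 3, 1)]
  mm <- match_factors(fit, swapped)
  expect_equal(mm$factor_b, paste0("factor", c(3, 1, 2)))
  expect_equal(mm$abs_cosine, rep(1, 3), tolerance = 1e-12)
})

test_that("Fisher-z intervals match the closed form and reject edge cases", {
  ci <- fisher_ci(0.47, 467)
  expect_equal(ci$lower, tanh(atanh(0.47) - qnorm(0.975) / sqrt(464)), tolerance = 1e-12)
  expect_equal(round(ci$lower, 3), 0.396)
  expect_equal(round(ci$upper, 3), 0.538)

  ci0 <- fisher_ci(0, 10003)
  expect_equal(ci0$lower, -0.0196, tolerance = 1e-3)
  expect_equal(ci0$upper, -ci0$lower, tolerance = 1e-12)

  withr::with_seed(4, {
    rs <- runif(20, -0.95, 0.95)
    cis <- fisher_ci(rs, 50)
    expect_true(all(cis$lower < rs & rs < cis$upper))
  })
  expect_error(fisher_ci(1, 100), "< 1")
  expect_error(fisher_ci(0.5, 3), "exceed 3")
})

test_that("a noise-free perfectly tracked cohort gives unit cross-wave correlations", {
  co <- exact_cohort(seed = 5, rho = c(1, 1, 1))
  fit1 <- fit_rrr(co$intake_wave1, co$response_wave1, k = 3)
  fit2 <- fit_rrr(co$intake_wave2, co$response_wave2, k = 3)
  rep <- stability_report(fit1, fit2, co$intake_wave1, co$intake_wave2)
  cm <- rep$cor_matrix
  for (j in 1:3) {
    expect_equal(abs(cm[paste0("exploratory_w1.factor", j),
                        paste0("exploratory_w2.factor", j)]), 1, tolerance = 1e-8)
  }
  expect_equal(abs(cm["exploratory_w1.factor1", "confirmatory_d2_l1.factor1"]),
               1, tolerance = 1e-8)
})

test_that("the report carries all four score blocks and same-wave identities", {
  co <- small_cohort(seed = 6, n = 140)
  fit1 <- fit_rrr(co$intake_wave1, co$response_wave1, k = 2)
  fit2 <- fit_rrr(co$intake_wave2, co$response_wave2, k = 2)
  rep <- stability_report(fit1, fit2, co$intake_wave1, co$intake_wave2)
  blocks <- c("exploratory_w1", "exploratory_w2",
              "confirmatory_d2_l1", "confirmatory_d1_l2")
  expect_setequal(unique(sub("\\.factor[0-9]+$", "", colnames(rep$cor_matrix))), blocks)
  expect_equal(dim(rep$cor_matrix), c(8, 8))
  expect_equal(unname(diag(rep$cor_matrix)), rep(1, 8))
  expect_equal(rep$cor_matrix, t(rep$cor_matrix))
  # CIs contain r
  off <- rep$correlations[rep$correlations$score_a != rep$correlations$score_b, ]
  expect_true(all(off$lower <= off$r & off$r <= off$upper))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_equal(nrow(rep$food_tracking), 19)
  expect_equal(nrow(rep$structure), 2)
})

test_that("the report is invariant under factor sign flips of the wave-2 model", {
  co <- small_cohort(seed = 7, n = 140)
  fit1 <- fit_rrr(co$intake_wave1, co$response_wave1, k = 2)
  fit2 <- fit_rrr(co$intake_wave2, co$response_wave2, k = 2)
  rep_a <- stability_report(fit1, fit2, co$intake_wave1, co$intake_wave2)

  flipped <- fit2
  flipped$weights <- sweep(fit2$weights, 2, c(-1, 1), "*")
  flipped$loadings <- sweep(fit2$loadings, 2, c(-1, 1), "*")
  flipped$response_loadings <- sweep(fit2$response_loadings, 2, c(-1, 1), "*")
  flipped$scores$factor1 <- -fit2$scores$factor1
  rep_b <- stability_report(fit1, flipped, co$intake_wave1, co$intake_wave2)
  expect_equal(rep_b$cor_matrix, rep_a$cor_matrix, tolerance = 1e-10)
})

test_that("cross-wave correlation increases with latent tracking", {
  mean_r <- sapply(c(0.2, 0.5, 0.8), function(rho) {
    mean(sapply(1:8, function(s) {
      co <- strong_cohort(seed = s, n = 250, rho = rep(rho, 3))
      f1 <- fit_rrr(co$intake_wave1, co$response_wave1, k = 1)
      f2 <- fit_rrr(co$intake_wave2, co$response_wave2, k = 1)
      s2 <- align_signs(f1, f2)[1]
      cor(f1$scores$factor1, s2 * f2$scores$factor1)
    }))
  })
  expect_true(all(diff(mean_r) > 0))
  expect_true(all(mean_r > 0 & mean_r < 1))
})
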