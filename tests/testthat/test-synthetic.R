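test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_true_patterns = 7), "n_true_patterns")
  w <- default_true_weights()
  w[, 2] <- w[, 1] + w[, 2]              # break orthogonality
  expect_error(synthetic_config(true_weights = w), "orthogonal")
  specs <- default_intake_specs()
  specs$zero_inflation_pi[3] <- 1.2
  expect_error(synthetic_config(intake_specs = specs), "zero_inflation_pi")
  specs <- default_intake_specs()
  specs$median_g_per_day[1] <- -5
  expect_error(synthetic_config(intake_specs = specs), "median_g_per_day")
  expect_silent(synthetic_config(seed = 1))
})

test_that("generated cohorts have the declared dimensions and are reproducible", {
  cfg <- synthetic_config(seed = 42)
  co <- generate_cohort(cfg)
  expect_equal(dim(co$intake_wave1), c(467, 2 + 19 + 1))   # id, wave, foods, energy
  expect_equal(dim(co$response_wave1), c(467, 2 + 6))
  expect_equal(ncol(co$truth$true_weights), 3)
  expect_identical(co$intake_wave1$participant_id, co$intake_wave2$participant_id)

  co2 <- generate_cohort(synthetic_config(seed = 42))
  expect_identical(co, co2)
  co3 <- generate_cohort(synthetic_config(seed = 43))
  expect_false(identical(co3$intake_wave1, co$intake_wave1))
})

test_that("perfect tracking makes the two waves' latent scores identical", {
  co <- generate_cohort(synthetic_config(n_participants = 80, tracking_rho = 1, seed = 5))
  expect_equal(co$truth$latent_scores$wave1, co$truth$latent_scores$wave2,
               tolerance = 1e-12)
  expect_equal(unname(co$truth$realized_tracking), rep(1, 3), tolerance = 1e-10)
})

test_that("intake medians land on their targets for non-dominant zero inflation", {
  co <- generate_cohort(synthetic_config(seed = 7))
  specs <- default_intake_specs()
  m <- as.matrix(co$intake_wave1[specs$food])
  ok <- specs$zero_inflation_pi < 0.5
  meds <- apply(m[, ok], 2, median)
  expect_true(all(abs(meds - specs$median_g_per_day[ok]) <=
                    0.1 * specs$median_g_per_day[ok] + 1e-9))
  expect_true(all(m >= 0))
})

test_that("realized latent tracking matches the target", {
  # variance-targeted construction: exact at default settings ...
  devs <- sapply(1:20, function(s) {
    co <- generate_cohort(synthetic_config(seed = s))
    co$truth$realized_tracking - c(0.60, 0.50, 0.35)
  })
  expect_lt(max(abs(devs)), 1e-10)
  # ... and within sampling error for plain correlated Gaussian draws
  devs_raw <- sapply(1:20, function(s) {
    co <- generate_cohort(synthetic_config(seed = s, whiten_latents = FALSE))
    co$truth$realized_tracking - c(0.60, 0.50, 0.35)
  })
  # 60 sample correlations at n = 467; allow ~3.5 sd of sampling noise
  expect_lt(max(abs(devs_raw)), 0.15)
  expect_lt(mean(abs(devs_raw)), 0.05)
})

test_that("the marginal transform censors, preserves ranks, and guards bad specs", {
  set.seed(1)
  lat <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  specs <- tibble::tibble(food = c("a", "b", "c"),
                          zero_inflation_pi = c(0, 1, 0.3),
                          log_scale_sigma = c(0.5, 0.8, 1.0),
                          median_g_per_day = c(50, 10, 0),
                          p90_g_per_day = c(150, 30, 40))
  out <- apply_intake_scale(lat, specs)
  expect_true(all(out[, "a"] > 0))                       # pi = 0: no zeros
  expect_true(all(out[, "b"] == 0))                      # pi = 1: all zero
  expect_equal(mean(out[, "c"] == 0), 0.3)
  expect_equal(cor(lat[, "a"], out[, "a"], method = "spearman"), 1)
  expect_equal(median(out[, "a"]), 50)
  expect_equal(unname(quantile(out[, "c"], 0.9)), 40, tolerance = 1e-9)

  specs$median_g_per_day[1] <- -1
  expect_error(apply_intake_scale(lat, specs), "nonnegative")
})

test_that("zero noise on the identity scale gives exact recovery and 100% explained variance", {
  co <- exact_cohort(seed = 3)
  fit <- fit_rrr(co$intake_wave1, co$response_wave1, k = 3)
  ev <- fit$explained
  resp_rows <- !(ev$term %in% c("all_responses", "all_foods"))
  expect_equal(ev$total[resp_rows], rep(100, 4), tolerance = 1e-8)
  cs <- vapply(1:3, function(j)
    abs_cosine(fit$weights[, j], co$truth$true_weights[, j]), numeric(1))
  expect_equal(cs, rep(1, 3), tolerance = 1e-8)
})

test_that("noise foods are independent additions with skewed marginals", {
  co <- small_cohort(seed = 2, n = 120)
  aug <- add_noise_foods(co$intake_wave1, 17, seed = 9)
  expect_equal(ncol(aug), ncol(co$intake_wave1) + 17)
  expect_identical(names(aug)[ncol(aug)], "energy_kj")
  expect_true(all(as.matrix(aug[paste0("noise_food_", 1:17)]) >= 0))
  aug2 <- add_noise_foods(co$intake_wave1, 17, seed = 9)
  expect_identical(aug, aug2)
})
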