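make_screen_data <- function(seed, n = 400, p = 5, beta = c(2, 0, 0, 0, 0),
                             noise_sd = 0.5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- as.numeric(X %*% beta + rnorm(n, 0, noise_sd))
    tibble::as_tibble(as.data.frame(X)) %>% dplyr::mutate(y = y)
  })
}

test_that("backwards elimination isolates the true predictor", {
  runs <- lapply(1:20, function(s) {
    d <- make_screen_data(s, noise_sd = 0.1)
    backward_eliminate(d, "y", alpha = 0.05)$retained
  })
  # the signal variable always survives; noise variables are retained only at
  # the multiplicity rate (4 chances at alpha = 0.05 per run)
  expect_true(all(vapply(runs, function(r) "x1" %in% r, logical(1))))
  extras <- vapply(runs, function(r) length(setdiff(r, "x1")), numeric(1))
  expect_lt(mean(extras), 4 * 0.05 * 3)
  expect_gte(mean(extras == 0), 0.6)
})

test_that("alpha = 1 retains everything; a null response is mostly emptied", {
  d <- make_screen_data(1)
  bf <- backward_eliminate(d, "y", alpha = 1)
  expect_setequal(bf$retained, paste0("x", 1:5))
  expect_equal(nrow(bf$log), 0)

  sizes <- sapply(1:20, function(s) {
    d <- make_screen_data(s, beta = rep(0, 5))
    length(backward_eliminate(d, "y", alpha = 0.001)$retained)
  })
  expect_gte(mean(sizes == 0), 0.9)   # per-predictor false retention ~ p * alpha
})

test_that("the elimination log replays to the final set and the fit is deterministic", {
  d <- make_screen_data(3, beta = c(1.5, 0.8, 0, 0, 0), noise_sd = 2)
  bf <- backward_eliminate(d, "y", alpha = 0.05)
  replay <- setdiff(paste0("x", 1:5), bf$log$dropped)
  expect_setequal(bf$retained, replay)
  expect_true(all(bf$log$p_value > 0.05))
  expect_identical(bf, backward_eliminate(d, "y", alpha = 0.05))
  expect_error(backward_eliminate(d[1:5, ], "y"), "n > p")
})

test_that("retained sets are monotone in alpha", {
  d <- make_screen_data(4, beta = c(1, 0.5, 0.2, 0, 0), noise_sd = 3)
  sets <- lapply(c(0.001, 0.05, 0.5, 1), function(a)
    backward_eliminate(d, "y", alpha = a)$retained)
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

fake_screen <- function(sets, foods, wave) {
  structure(list(foods = foods, sets = sets, logs = list(), wave = wave),
            class = "wave_screen")
}

test_that("the cross-wave retention rule counts responses per wave", {
  foods <- c("a", "b", "c", "d")
  resp <- paste0("y", 1:6)
  # a: 3 responses in wave 1 only; b: exactly 2 in both; c: 1 and 4; d: none
  s1 <- fake_screen(list(y1 = c("a", "b", "c"), y2 = c("a", "b"), y3 = "a",
                         y4 = character(), y5 = character(), y6 = character()),
                    foods, "wave1")
  s2 <- fake_screen(list(y1 = c("b", "c"), y2 = c("b", "c"), y3 = "c",
                         y4 = "c", y5 = character(), y6 = character()),
                    foods, "wave2")
  sel <- select_food_groups(s1, s2, min_responses = 3)
  expect_setequal(sel$retained_foods, c("a", "c"))

  sel_both <- select_food_groups(s1, s2, min_responses = 3, wave_rule = "both")
  expect_equal(length(sel_both$retained_foods), 0)

  sel1 <- select_food_groups(s1, s2, min_responses = 1)
  expect_setequal(sel1$retained_foods, c("a", "b", "c"))   # union of all sets

  # monotone nonincreasing in min_responses
  sizes <- sapply(1:5, function(m)
    length(select_food_groups(s1, s2, min_responses = m)$retained_foods))
  expect_true(all(diff(sizes) <= 0))

  s2_bad <- fake_screen(s2$sets, c("a", "b", "c", "e"), "wave2")
  expect_error(select_food_groups(s1, s2_bad), "universe")
})

test_that("wave screening runs per response over standardized foods", {
  co <- strong_cohort(seed = 8, n = 250)
  sw <- screen_foods_wave(co$intake_wave1, co$response_wave1, alpha = 0.05)
  expect_named(sw$sets, names(co$response_wave1)[-(1:2)])
  expect_setequal(sw$foods, default_intake_specs()$food)
  expect_true(all(unlist(sw$sets) %in% sw$foods))
})
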