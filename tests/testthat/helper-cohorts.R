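# Shared fixture builders. Everything is generated in code at test time.

# Small default-shaped cohort for fast end-to-end tests.
small_cohort <- function(seed = 1, n = 150, ...) {
  generate_cohort(synthetic_config(n_participants = n, seed = seed, ...))
}

# Noise-free cohort with as many foods as patterns on the identity intake
# scale: the regime where pattern recovery and explained variation are exact.
# Response loadings have orthogonal columns AND equal row norms, so that
# standardizing the responses does not re-mix the patterns.
exact_cohort <- function(seed = 1, n = 200, rho = c(0.6, 0.5, 0.35)) {
  signs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  loadings <- sweep(signs, 2, c(0.8, 0.6, 0.45), "*")
  generate_cohort(synthetic_config(
    n_participants = n, n_foods = 3, n_responses = 4, n_true_patterns = 3,
    response_loadings = loadings,
    tracking_rho = rho, response_noise_sd = 0, intake_noise_sd = 0,
    intake_scale = "identity", seed = seed))
}

# Strong-signal cohort: latent patterns well above the realistic default
# strength, for tests of machinery rather than of power.
strong_cohort <- function(seed = 1, n = 300, rho = c(0.9, 0.85, 0.8),
                          intake_noise_sd = 0.4) {
  l0 <- default_response_loadings()
  l <- sweep(l0, 2, sqrt(c(3, 2, 1.2)) / sqrt(colSums(l0^2)), "*")
  generate_cohort(synthetic_config(
    n_participants = n, seed = seed, tracking_rho = rho,
    response_loadings = l, intake_noise_sd = intake_noise_sd))
}

# Random regression instance for oracle checks.
random_instance <- function(seed, n = 60, p = 5, q = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    B <- matrix(rnorm(p * q), p, q)
    Y <- X %*% B + matrix(rnorm(n * q), n, q) * 2
    colnames(Y) <- paste0("y", 1:q)
    list(intake = tibble::as_tibble(as.data.frame(X)),
         response = tibble::as_tibble(as.data.frame(Y)))
  })
}

# Independent oracle: first-factor weights as the top generalized eigenvector
# of (S_xy S_yx, S_xx), computed by Cholesky whitening + symmetric eigen.
rrr_factor1_geneig <- function(X, Y) {
  X <- scale(X); Y <- scale(Y)
  n <- nrow(X)
  sxx <- crossprod(X) / (n - 1)
  sxy <- crossprod(X, Y) / (n - 1)
  R <- chol(sxx)
  M <- t(solve(R)) %*% sxy %*% t(sxy) %*% solve(R)
  u <- eigen((M + t(M)) / 2, symmetric = TRUE)$vectors[, 1]
  backsolve(R, u)
}

abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

# Numeric variable block of a participant table (ids/wave/energy dropped).
table_matrix_for_test <- function(data) {
  as.matrix(as.data.frame(data)[setdiff(names(data),
                                        c("participant_id", "wave", "energy_kj"))])
}

# Mean best-assignment |cosine| between estimated and true weight columns.
mean_recovery_cosine <- function(west, wtrue) {
  k <- ncol(wtrue)
  cs <- abs(crossprod(west, wtrue)) /
    outer(sqrt(colSums(west^2)), sqrt(colSums(wtrue^2)))
  perms <- rbind(1:k)
  if (k > 1) {
    perms <- as.matrix(expand.grid(rep(list(1:k), k)))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == k), , drop = FALSE]
  }
  tot <- apply(perms, 1, function(pp) sum(cs[cbind(1:k, pp)]))
  best <- perms[which.max(tot), ]
  mean(cs[cbind(1:k, best)])
}
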