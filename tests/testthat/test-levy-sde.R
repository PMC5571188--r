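test_that("stable increments have the stated distributional properties", {
  ns <- noise_spec(1, 1)
  x <- sample_stable_increments(ns, dt = 1, n = 1e5, seed = 4)
  expect_lt(abs(stats::median(x)), 0.02)          # symmetry
  # self-similarity: increments over dt = 4 match 4^{1/alpha}-scaled
  # unit increments in distribution
  for (alpha in c(0.5, 1.5)) {
    nsa <- noise_spec(alpha, 1)
    a <- sample_stable_increments(nsa, dt = 4, n = 1e4, seed = 5)
    b <- 4^(1 / alpha) *
      sample_stable_increments(nsa, dt = 1, n = 1e4, seed = 6)
    expect_gt(suppressWarnings(stats::ks.test(a, b))$p.value, 0.01)
  }
  # tail index: Hill estimator on |draws| recovers alpha = 0.5
  y <- abs(sample_stable_increments(noise_spec(0.5, 1), 1, 1e5, seed = 7))
  y <- sort(y, decreasing = TRUE)
  k <- 1000L
  hill <- 1 / mean(log(y[1:k]) - log(y[k + 1L]))
  expect_lt(abs(hill - 0.5), 0.05)
  expect_error(noise_spec(2.3, 1), "alpha")
  expect_error(noise_spec(0.5, -1), "psi")
})

test_that("zero-noise paths reduce to the deterministic flow", {
  fld <- ref_field()
  ns <- noise_spec(1.5, 1e-12)   # effectively deterministic
  ens <- simulate_paths(fld, ns, x0 = 0.9, T = 100, dt = 0.01, seed = 1)
  xT <- ens$states[nrow(ens$states), 1]
  expect_lt(abs(xT - (1 - 0.2 / 0.85)), 1e-3)
  # against an independent RK4 oracle at intermediate time
  rk <- rk4_trajectory(fld$fun, 0.9, T = 10, dt = 1e-3)
  i10 <- which.min(abs(ens$times - 10))
  expect_lt(abs(ens$states[i10, 1] - rk[length(rk)]), 1e-3)
  # a start below x_A decays toward the savanna state
  ens2 <- simulate_paths(fld, ns, x0 = 0.19, T = 100, dt = 0.01, seed = 1)
  x2 <- ens2$states[, 1]
  # monotone decay while the state is large against the residual noise
  expect_true(all(diff(x2[ens2$times <= 30]) < 0))
  expect_lt(abs(x2[length(x2)]), 0.01)
})

test_that("weak noise keeps most paths in the forest well", {
  fld <- ref_field()
  ns <- noise_spec(1.5, 0.01)
  ens <- simulate_paths(fld, ns, x0 = 0.35, T = 50, dt = 0.01,
                        n_paths = 200, seed = 3)
  final <- ens$states[nrow(ens$states), ]
  expect_gt(mean(final > fld$x_A), 0.9)
})

test_that("path ensembles are reproducible with stable per-path streams", {
  fld <- ref_field()
  ns <- noise_spec(1.5, 0.05)
  e1 <- simulate_paths(fld, ns, 0.6, T = 2, dt = 0.01, n_paths = 5,
                       seed = 42)
  e2 <- simulate_paths(fld, ns, 0.6, T = 2, dt = 0.01, n_paths = 5,
                       seed = 42)
  expect_identical(e1$states, e2$states)
  # enlarging the ensemble leaves earlier paths untouched
  e3 <- simulate_paths(fld, ns, 0.6, T = 2, dt = 0.01, n_paths = 8,
                       seed = 42)
  expect_identical(e3$states[, 1:5], e1$states)
  expect_false(identical(e1$states[, 1], e1$states[, 2]))
})

test_that("Monte Carlo exit time matches the closed-form stable exit law", {
  ns <- noise_spec(1, 1)
  expect_identical(
    mc_mean_exit_time(NULL, ns, c(-1, 1), x0 = 1)$estimate, 0)
  res <- mc_mean_exit_time(NULL, ns, c(-1, 1), x0 = 0, n_paths = 3000,
                           dt = 1e-3, T = 50, seed = 9)
  expect_lt(abs(res$estimate - stable_exit_time_exact(0, 1)),
            3 * res$stderr)
  expect_lt(res$n_censored, 10)
})

test_that("halving dt moves the exit-time estimate by less than 2 pooled stderr", {
  ns <- noise_spec(1.5, 1)
  a <- mc_mean_exit_time(NULL, ns, c(-1, 1), 0, n_paths = 3000,
                         dt = 2e-3, T = 50, seed = 10)
  b <- mc_mean_exit_time(NULL, ns, c(-1, 1), 0, n_paths = 3000,
                         dt = 1e-3, T = 50, seed = 11)
  expect_lt(abs(a$estimate - b$estimate),
            2 * sqrt(a$stderr^2 + b$stderr^2))
})

test_that("exit time at the forest state decreases with noise intensity", {
  fld <- ref_field()
  xF <- 1 - 0.2 / 0.85
  D <- c(fld$x_A, 1.2524)
  lo <- mc_mean_exit_time(fld, noise_spec(1.5, 0.1), D, xF,
                          n_paths = 400, dt = 2e-3, T = 100, seed = 12)
  hi <- mc_mean_exit_time(fld, noise_spec(1.5, 1), D, xF,
                          n_paths = 400, dt = 2e-3, T = 100, seed = 12)
  expect_lt(hi$estimate, lo$estimate)
})

test_that("escape probability estimator handles degenerate targets", {
  ns <- noise_spec(0.5, 1)
  # target covering everything the path can land on: certain escape
  res <- mc_escape_probability(NULL, ns, c(-1, 1), c(-1e12, 1e12), 0,
                               n_paths = 500, dt = 1e-3, T = 50,
                               seed = 13)
  expect_equal(res$estimate, 1)
  # empty target: never counted
  res0 <- mc_escape_probability(NULL, ns, c(-1, 1), c(0, 0), 0,
                                n_paths = 500, dt = 1e-3, T = 50,
                                seed = 13)
  expect_equal(res0$estimate, 0)
  expect_error(mc_escape_probability(NULL, ns, c(-1, 1), c(1, 2), -1),
               "x0")
})
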