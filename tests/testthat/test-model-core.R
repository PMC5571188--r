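test_that("Filippov interval matches closed-form arithmetic", {
  fi <- filippov_interval(vegetation_params())
  expect_equal(fi$lower, -0.06, tolerance = 1e-12)
  expect_equal(fi$upper, 0.1185, tolerance = 1e-12)
  # convexification parameter endpoints hit the one-sided limits
  expect_equal(fi$value(0), -0.06)
  expect_equal(fi$value(1), 0.1185)
  expect_error(fi$value(1.5))
  # 0 lies in the set: solutions may stay on the boundary
  expect_true(fi$lower <= 0 && 0 <= fi$upper)
  # generic parameters: [-D xc, G(1-xc)xc - D xc]
  p2 <- vegetation_params(G = 0.4, D = 0.2, x_crit = 0.25)
  fi2 <- filippov_interval(p2)
  expect_equal(fi2$lower, -0.05)
  expect_equal(fi2$upper, 0.4 * 0.75 * 0.25 - 0.05)
})

test_that("evaluate_field returns branches off the boundary and a set on it", {
  p <- vegetation_params()
  expect_s3_class(evaluate_field(0.3, p), "filippov_interval")
  expect_equal(evaluate_field(0, p), 0)
  expect_equal(evaluate_field(0.5, p), -0.85 * 0.25 + 0.65 * 0.5)
  expect_equal(evaluate_field(0.2, p), -0.04)
  # jump size at the boundary equals the width of the Filippov interval
  fi <- filippov_interval(p)
  eps <- 1e-9
  jump <- evaluate_field(0.3 + eps, p) - evaluate_field(0.3 - eps, p)
  expect_equal(jump, fi$upper - fi$lower, tolerance = 1e-6)
  expect_error(evaluate_field(c(0.2, 0.3), p), "boundary")
  expect_error(evaluate_field(NA_real_, p))
  expect_error(evaluate_field(-0.1, p))
})

test_that("equilibria are the exact one-sided roots", {
  p <- vegetation_params()
  eq <- equilibria(p)
  expect_equal(eq$x, c(0, 1 - 0.2 / 0.85))
  expect_equal(eq$x[2], 0.76470588235, tolerance = 1e-10)
  expect_equal(equilibria(vegetation_params(G = 0.4, D = 0.2))$x[2], 0.5)
  # property: one-sided fields vanish at their equilibria for random
  # admissible parameters
  set.seed(7)
  for (i in 1:50) {
    G <- runif(1, 0.3, 2); D <- runif(1, 0.05, G * 0.9)
    xc <- runif(1, 0.01, (1 - D / G) * 0.99)
    pp <- vegetation_params(G, D, xc)
    fld <- piecewise_field(pp)
    expect_equal(fld$f_plus(pp$x_F), 0, tolerance = 1e-14)
    expect_identical(fld$f_minus(0), 0)
  }
})

test_that("parameter validation enforces the admissible range", {
  expect_error(vegetation_params(G = 0.2, D = 0.2), "G > D")
  expect_error(vegetation_params(G = 0.85, D = -0.1), "G > D")
  expect_error(vegetation_params(x_crit = 0), "x_crit")
  expect_warning(vegetation_params(G = 0.85, D = 0.2, x_crit = 0.8),
                 "forest state absent")
})

test_that("switching boundary classification matches sign analysis", {
  expect_identical(classify_switch(vegetation_params()),
                   "repelling-sliding")
  # forest state below the threshold: growth branch also negative at
  # the boundary, flow crosses transversally
  p_dry <- suppressWarnings(vegetation_params(x_crit = 0.9))
  expect_identical(classify_switch(p_dry), "transversal")
  # sign-flipped field: both sides flow into the boundary
  p <- vegetation_params()
  fld <- piecewise_field(p)
  flipped <- list(f_minus = function(x) -fld$f_minus(x),
                  f_plus = function(x) -fld$f_plus(x),
                  sigma = p$x_crit)
  expect_identical(classify_switch(flipped), "attracting-sliding")
})

test_that("classification agrees with brute-force sign conditions on 1000 random fields", {
  brute <- function(vm, vp) {
    # projections onto the normal of h(x) = xb - x; the branch on the
    # h > 0 side (below the boundary) plays the role of the upper field
    n_fm <- -vp; n_fp <- -vm
    if (n_fm * n_fp > 0) return("transversal")
    if (n_fm > 0 && n_fp < 0) return("attracting-sliding")
    "repelling-sliding"
  }
  for (s in 1:1000) {
    sf <- random_two_well_field(s)
    expect_identical(classify_switch(sf), sf$class_truth)
    expect_identical(brute(sf$f_minus(sf$sigma), sf$f_plus(sf$sigma)),
                     sf$class_truth)
  }
})

test_that("all three analytic branches satisfy the differential inclusion", {
  p <- vegetation_params()
  sol <- analytic_solutions(p)
  fld <- piecewise_field(p)
  expect_equal(sol$decay_branch(0), 0.3)
  expect_true(all(sol$constant_branch(seq(0, 10, 0.5)) == 0.3))
  expect_true(all(diff(sol$decay_branch(seq(0, 10, 0.1))) < 0))
  h <- 1e-5
  ts <- seq(0.1, 10, length.out = 60)
  # growth branch against the upper field (valid where x > x_crit)
  for (C1 in c(-2, 0, 3)) {
    xs <- sol$tanh_branch(ts, C1)
    dx <- (sol$tanh_branch(ts + h, C1) - sol$tanh_branch(ts - h, C1)) /
      (2 * h)
    expect_lt(max(abs(dx - fld$f_plus(xs))), 1e-8)
  }
  # decay branch against the lower field
  xs <- sol$decay_branch(ts)
  dx <- (sol$decay_branch(ts + h) - sol$decay_branch(ts - h)) / (2 * h)
  expect_lt(max(abs(dx - fld$f_minus(xs))), 1e-8)
  # constant branch: derivative 0, admissible because 0 is in the
  # Filippov set at the boundary
  fi <- filippov_interval(p)
  expect_true(fi$lower <= 0 && 0 <= fi$upper)
})
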