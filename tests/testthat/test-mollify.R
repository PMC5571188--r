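test_that("Gaussian mollifier is a unit-mass kernel with finite moments", {
  eps <- 0.08
  mass <- stats::integrate(gaussian_mollifier, -10 * eps, 10 * eps,
                           epsilon = eps, rel.tol = 1e-13)$value
  expect_equal(mass, 1, tolerance = 1e-10)
  expect_equal(gaussian_mollifier(0, 0.08), 1 / (0.08 * sqrt(pi)))
  for (k in seq(2, 8, by = 2)) {
    mom <- stats::integrate(function(s) s^k * gaussian_mollifier(s, 1),
                            -20, 20, rel.tol = 1e-10)$value
    expect_true(is.finite(mom) && mom > 0)
  }
  expect_error(gaussian_mollifier(0, -1), "positive")
  expect_error(mollifier_spec(0.08, c(0.1, 0.5), c(0.05, 0.4)),
               "inside U")
})

test_that("convolved drift vanishes at the reported unstable equilibrium", {
  spec <- mollifier_presets()[["0.08"]]
  expect_lt(abs(convolved_drift(0.2676, spec)), 1e-3)
  expect_error(convolved_drift(0.5, spec), "U_eps")
})

test_that("convolution converges to the raw field as epsilon shrinks", {
  # small-epsilon spec away from the switch: A* ~ f_plus + O(eps^2)
  sp <- mollifier_spec(0.005, c(0.25, 0.45), c(0.27, 0.43))
  f_plus <- function(x) -0.85 * x^2 + 0.65 * x
  expect_lt(abs(convolved_drift(0.35, sp) - f_plus(0.35)), 1e-4)
  # junction continuity at the left edge of the 0.08 window
  expect_lt(abs(convolved_drift(0.177, mollifier_presets()[["0.08"]]) -
                  (-0.2 * 0.177)), 2e-2)
  # sup-distance to the raw field decreases along the preset sequence,
  # excluding a neighbourhood of the switch
  grid <- c(seq(0.05, 0.25, 0.01), seq(0.35, 0.6, 0.01))
  raw <- function(x) ifelse(x > 0.3, f_plus(x), -0.2 * x)
  sups <- vapply(c("0.08", "0.05", "0.025"), function(key) {
    fld <- ref_field(key)
    max(abs(fld$fun(grid) - raw(grid)))
  }, numeric(1))
  expect_true(all(diff(sups) < 0))
})

test_that("mollified fields have the printed unstable equilibria", {
  xa <- vapply(c("0.08", "0.05", "0.025"),
               function(k) ref_field(k)$x_A, numeric(1))
  expect_equal(round(unname(xa), 2), c(0.27, 0.28, 0.29))
  expect_equal(round(xa[["0.08"]], 4), 0.2676)
  # ordering toward the switch as epsilon shrinks
  expect_true(xa[["0.08"]] < xa[["0.05"]] &&
              xa[["0.05"]] < xa[["0.025"]] && xa[["0.025"]] < 0.3)
})

test_that("mollified field is smooth inside U_eps and exact outside", {
  for (key in c("0.08", "0.05", "0.025")) {
    fld <- ref_field(key)
    ue <- fld$spec$U_eps
    # exact raw branches outside the window
    expect_equal(fld$fun(ue[2] + 0.01),
                 -0.85 * (ue[2] + 0.01)^2 + 0.65 * (ue[2] + 0.01))
    expect_equal(fld$fun(ue[1] - 0.01), -0.2 * (ue[1] - 0.01))
    # second differences bounded and without isolated spikes
    xs <- seq(ue[1], ue[2], length.out = 201)
    d2 <- diff(fld$fun(xs), differences = 2)
    med <- stats::median(abs(d2))
    expect_lt(max(abs(d2)), 10 * max(med, 1e-8))
  }
})

test_that("adaptive quadrature agrees with a dense Riemann-sum oracle", {
  spec <- mollifier_presets()[["0.08"]]
  fplus <- function(x) -0.85 * x^2 + 0.65 * x
  riemann <- function(x) {
    n <- 1e5
    t1 <- seq(spec$U[1], 0.3, length.out = n)
    t2 <- seq(0.3, spec$U[2], length.out = n)
    sum(-0.2 * t1 * gaussian_mollifier(x - t1, spec$epsilon)) *
      (t1[2] - t1[1]) +
      sum(fplus(t2) * gaussian_mollifier(x - t2, spec$epsilon)) *
      (t2[2] - t2[1])
  }
  set.seed(11)
  for (x in runif(12, spec$U_eps[1], spec$U_eps[2]))
    expect_lt(abs(convolved_drift(x, spec) - riemann(x)), 1e-6)
})

test_that("root finding matches the closed-form convolution oracle on synthetic fields", {
  eps <- 0.001
  n_checked <- 0
  for (s in 1:60) {
    sf <- random_two_well_field(s)
    if (sf$class_truth != "repelling-sliding") next
    co <- sf$coefficients
    oracle <- uniroot(function(x)
      conv_linear_closed_form(x, sf$sigma, co$s_l, co$r_l, co$s_r,
                              co$r_r, eps),
      sf$sigma + c(-0.05, 0.05), tol = 1e-12)$root
    m <- mollify_function(sf$fun, sf$sigma, eps)
    root <- uniroot(function(x) m(x), sf$sigma + c(-0.05, 0.05),
                    tol = 1e-10)$root
    expect_lt(abs(root - oracle), 1e-8)
    expect_lt(abs(root - sf$separatrix), 1e-3)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 10)
})

test_that("find_unstable_equilibrium demands a sign change", {
  spec <- mollifier_spec(0.02, c(0.3, 0.9), c(0.35, 0.8), x_crit = 0.5)
  # growth branch only on (0.35, 0.8) once mollified against a field
  # that is positive throughout: no root
  fake <- list(convolution = function(x) rep(0.1, length(x)),
               spec = spec)
  expect_error(find_unstable_equilibrium(fake), "sign change")
})
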