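# Shared fixtures, built once per test run.

.cache <- new.env(parent = emptyenv())

# Reference mollified field (epsilon = 0.08), reused across files.
ref_field <- function(eps = "0.08") {
  key <- paste0("field_", eps)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- build_mollified_field(mollifier_presets()[[eps]])
  .cache[[key]]
}

# Closed-form Gaussian convolution of a broken-linear field
# f(x) = s_l (x - r_l) for x < xb, s_r (x - r_r) for x > xb:
# an independent oracle for mollify_function (erf/pnorm algebra, no
# quadrature).
conv_linear_closed_form <- function(x, xb, s_l, r_l, s_r, r_r, eps) {
  Phi <- function(z) stats::pnorm(z * sqrt(2))   # (1 + erf(z)) / 2
  ub <- (xb - x) / eps
  s_l * (x - r_l) * Phi(ub) - s_l * eps * exp(-ub^2) / (2 * sqrt(pi)) +
    s_r * (x - r_r) * (1 - Phi(ub)) +
    s_r * eps * exp(-ub^2) / (2 * sqrt(pi))
}

# Closed-form mean exit time of the standard symmetric alpha-stable
# process from (-r, r) (Getoor): the solver's independent oracle.
stable_exit_time_exact <- function(x, alpha, r = 1) {
  gamma(0.5) / (2^alpha * gamma(1 + alpha / 2) * gamma((1 + alpha) / 2)) *
    (r^2 - x^2)^(alpha / 2)
}

# Fixed-step RK4 integrator: independent ODE oracle for the
# deterministic (psi = 0) limit.
rk4_trajectory <- function(f, x0, T, dt) {
  n <- ceiling(T / dt)
  x <- numeric(n + 1L)
  x[1] <- x0
  for (k in seq_len(n)) {
    k1 <- f(x[k])
    k2 <- f(x[k] + dt / 2 * k1)
    k3 <- f(x[k] + dt / 2 * k2)
    k4 <- f(x[k] + dt * k3)
    x[k + 1L] <- x[k] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# Minimal scalar_field stand-in for set-extraction unit tests.
fake_scalar_field <- function(x, values, D, kind = "escape probability") {
  structure(list(x = x, values = values, interior = seq_along(x),
                 D = D, target = NULL, kind = kind,
                 h = x[2] - x[1], alpha = NA, psi = NA,
                 closure = "absorbing"),
            class = "scalar_field")
}
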