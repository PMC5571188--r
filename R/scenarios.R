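#' Reference scenario grid
#'
#' The full 3 x 3 x 2 analysis grid: mollification radius
#' `epsilon` in {0.08, 0.05, 0.025} (with their printed supports, see
#' [mollifier_presets()]), stability index `alpha` in {0.5, 1, 1.5} and
#' noise intensity `psi` in {0.1, 1}, at the reference vegetation
#' parameters G = 0.85, D = 0.2, x_crit = 0.3.
#'
#' Each scenario carries the mollified field (built once per `epsilon`
#' and shared), its unstable equilibrium `x_A`, and the two exit
#' domains: the Definition-I ray `D = (x_A, Inf)` with savanna target
#' `(0, x_A)`, truncated at `r = 1.52 - x_A`, and the Definition-II
#' bounded domain `D = (x_A, 1.52 - x_A)`.  The mirror rule
#' `r = 1.52 - x_A` reproduces the printed pair (0.2676, 1.2524) for
#' `epsilon = 0.08` exactly (the pair is symmetric about 0.76, the
#' forest state rounded to 2 decimals) and anchors the other two
#' `epsilon` values to their own `x_A`.
#'
#' @param epsilons subset of `c(0.08, 0.05, 0.025)`.
#' @param alphas subset of `c(0.5, 1, 1.5)`.
#' @param psis subset of `c(0.1, 1)`.
#' @param params a [vegetation_params()] object.
#' @return A list of scenario objects (class `"basin_scenario"`), each a
#'   list with `epsilon`, `alpha`, `psi`, `params`, `mollifier`, `noise`,
#'   `field`, `x_A`, `domains` (`def1`, `def2`), `criteria`
#'   (`def1`: m = 0.5, M = 0.7; `def2`: AMET, M = 0.7), `label`.
#' @export
reference_grid <- function(epsilons = c(0.08, 0.05, 0.025),
                           alphas = c(0.5, 1, 1.5),
                           psis = c(0.1, 1),
                           params = vegetation_params()) {
  presets <- mollifier_presets()
  stopifnot(all(as.character(epsilons) %in% names(presets)))
  fields <- lapply(as.character(epsilons), function(key)
    build_mollified_field(presets[[key]], params))
  names(fields) <- as.character(epsilons)
  out <- list()
  for (eps in epsilons) {
    fld <- fields[[as.character(eps)]]
    xA <- fld$x_A
    r <- 1.52 - xA
    domains <- list(
      def1 = domain_spec(c(xA, Inf), target = c(0, xA),
                         closure = "absorbing", truncation = r),
      def2 = domain_spec(c(xA, r))
    )
    criteria <- list(
      def1 = basin_criteria(m = 0.5, M = 0.7),
      def2 = basin_criteria(M = 0.7, m_mode = "amet")
    )
    for (alpha in alphas) for (psi in psis) {
      sc <- structure(list(
        epsilon = eps, alpha = alpha, psi = psi,
        params = params, mollifier = fld$spec,
        noise = noise_spec(alpha, psi),
        field = fld, x_A = xA,
        domains = domains, criteria = criteria,
        label = sprintf("eps%g_a%g_psi%g", eps, alpha, psi)
      ), class = "basin_scenario")
      out[[sc$label]] <- sc
    }
  }
  out
}

#' @export
print.basin_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario %s: epsilon = %g (x_A = %.4f), alpha = %g, psi = %g\n",
    x$label, x$epsilon, x$x_A, x$alpha, x$psi))
  invisible(x)
}

#' Mollify a piecewise function around a single breakpoint
#'
#' Generic Gaussian mollification \eqn{(\eta_\varepsilon * f)(x)} for an
#' arbitrary scalar field with one discontinuity, integrating over
#' `x +- 10 epsilon` split at the breakpoint.  Used for synthetic
#' property-test fields; the vegetation model's own mollification, which
#' restricts the integral to a finite support `U`, is
#' [convolved_drift()].
#'
#' @param f vectorized function (its value exactly at the breakpoint is
#'   irrelevant).
#' @param breakpoint location of the discontinuity.
#' @param epsilon mollification radius.
#' @return A function of `x` (vectorized) evaluating the convolution.
#' @export
mollify_function <- function(f, breakpoint, epsilon) {
  stopifnot(is.function(f), epsilon > 0)
  function(x) vapply(x, function(xi) {
    lo <- xi - 10 * epsilon; hi <- xi + 10 * epsilon
    kern <- function(t) f(t) * gaussian_mollifier(xi - t, epsilon)
    if (breakpoint <= lo || breakpoint >= hi)
      return(stats::integrate(kern, lo, hi, rel.tol = 1e-10)$value)
    stats::integrate(kern, lo, breakpoint, rel.tol = 1e-10)$value +
      stats::integrate(kern, breakpoint, hi, rel.tol = 1e-10)$value
  }, numeric(1))
}

#' Random piecewise two-branch drift with known ground truth
#'
#' Generates a piecewise-linear scalar field with a single discontinuity
#' of a randomly chosen sliding-mode class, for property testing against
#' brute-force oracles.  For the `"repelling-sliding"` class the field
#' is a genuine two-well: stable equilibria on both sides of the
#' breakpoint, which is the separatrix.  For `"attracting-sliding"` the
#' boundary itself is the attractor (both one-sided flows point into
#' it); for `"transversal"` the flow crosses the boundary downward onto
#' the single stable equilibrium below.
#'
#' @param seed integer seed.
#' @return An object of class `"synthetic_field"`: list with `f_minus`,
#'   `f_plus`, `sigma` (breakpoint), `fun` (piecewise evaluation, `NA`
#'   at the breakpoint), `class_truth`, `equilibria` (stable roots of
#'   the stored pieces, possibly empty), `attractor_below`,
#'   `attractor_above` (limit of the flow started on each side),
#'   `separatrix` (`sigma` for the repelling class, else `NA`).
#' @export
random_two_well_field <- function(seed) {
  set.seed(seed)
  cls <- sample(c("repelling-sliding", "attracting-sliding",
                  "transversal"), 1)
  x_b <- stats::runif(1, 0.35, 0.65)
  s_l <- -stats::runif(1, 0.3, 1.5)
  s_r <- -stats::runif(1, 0.3, 1.5)
  gap_l <- stats::runif(1, 0.1, 0.3)
  gap_r <- stats::runif(1, 0.1, 0.3)
  if (cls == "repelling-sliding") {
    r_l <- x_b - gap_l; r_r <- x_b + gap_r
    eq <- c(r_l, r_r); attr_lo <- r_l; attr_hi <- r_r; sep <- x_b
  } else if (cls == "attracting-sliding") {
    r_l <- x_b + gap_l; r_r <- x_b - gap_r      # virtual roots
    eq <- numeric(0); attr_lo <- x_b; attr_hi <- x_b; sep <- NA_real_
  } else {
    r_l <- x_b - gap_l; r_r <- x_b - gap_r      # both flows point down
    eq <- r_l; attr_lo <- r_l; attr_hi <- r_l; sep <- NA_real_
  }
  f_minus <- function(x) s_l * (x - r_l)
  f_plus <- function(x) s_r * (x - r_r)
  structure(list(
    f_minus = f_minus, f_plus = f_plus, sigma = x_b,
    fun = function(x) ifelse(x < x_b, f_minus(x),
                             ifelse(x > x_b, f_plus(x), NA_real_)),
    class_truth = cls, equilibria = eq,
    attractor_below = attr_lo, attractor_above = attr_hi,
    separatrix = sep, seed = seed,
    coefficients = list(s_l = s_l, r_l = r_l, s_r = s_r, r_r = r_r)
  ), class = "synthetic_field")
}

#' Reference path ensembles
#'
#' The trajectory configurations used for illustration and regression:
#' the five initial conditions {0.9, 0.6, 0.35, 0.19, 0.1} under
#' (psi, alpha) in {(0.01, 1.5), (0.01, 1), (0.05, 1.5)} on the
#' epsilon = 0.08 mollified field, plus the deterministic (psi = 0)
#' companion solution for each start.
#'
#' @param field a mollified field (default: epsilon = 0.08 preset).
#' @param n_paths stochastic paths per configuration.
#' @param T horizon.
#' @param dt step.
#' @param seed root seed; configurations get distinct derived seeds.
#' @return Nested list: per configuration (`psi0.01_a1.5`, ...), a list
#'   with `noise`, `ensembles` (one [simulate_paths()] result per
#'   initial condition) and `deterministic` (matrix of drift-only
#'   trajectories, one column per initial condition).
#' @export
reference_ensembles <- function(field = NULL, n_paths = 1L, T = 50,
                                dt = 0.01, seed = 1L) {
  if (is.null(field))
    field <- build_mollified_field(mollifier_presets()[["0.08"]])
  x0s <- c(0.9, 0.6, 0.35, 0.19, 0.1)
  configs <- list(c(psi = 0.01, alpha = 1.5),
                  c(psi = 0.01, alpha = 1.0),
                  c(psi = 0.05, alpha = 1.5))
  f <- as_drift_function(field)
  n_steps <- ceiling(T / dt)
  det_traj <- function(x0) {
    x <- numeric(n_steps + 1L); x[1] <- x0
    for (k in seq_len(n_steps)) x[k + 1L] <- x[k] + f(x[k]) * dt
    x
  }
  det <- vapply(x0s, det_traj, numeric(n_steps + 1L))
  colnames(det) <- paste0("x0_", x0s)
  out <- list()
  for (ic in seq_along(configs)) {
    cf <- configs[[ic]]
    ns <- noise_spec(cf[["alpha"]], cf[["psi"]])
    ens <- lapply(seq_along(x0s), function(j)
      simulate_paths(field, ns, x0s[j], T, dt, n_paths,
                     seed = seed + 1000L * ic + j))
    names(ens) <- paste0("x0_", x0s)
    out[[sprintf("psi%g_a%g", cf[["psi"]], cf[["alpha"]])]] <-
      list(noise = ns, ensembles = ens, deterministic = det,
           times = (0:n_steps) * dt)
  }
  out
}
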