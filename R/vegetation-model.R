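#' Parameters of the conceptual Amazonian vegetation model
#'
#' The model describes the relative forest cover \eqn{x \in [0, 1]} which
#' grows logistically with saturating rate `G` above a critical cover
#' threshold `x_crit` and dies at rate `D` below it:
#' \deqn{dx/dt = G(1-x)x - Dx \quad (x > x_{crit}), \qquad
#'       dx/dt = -Dx \quad (x < x_{crit}).}
#' The field is discontinuous at the switching boundary
#' \eqn{\Sigma = \{x = x_{crit}\}}.  Two stable equilibria exist: the
#' savanna state \eqn{x_S = 0} and the forest state \eqn{x_F = 1 - D/G}
#' (the latter provided \eqn{x_F > x_{crit}}).
#'
#' @param G saturating growth rate (per unit time).
#' @param D death rate (per unit time); requires `G > D > 0`.
#' @param x_crit critical forest-cover threshold (dimensionless fraction
#'   in (0, 1)).
#' @return An object of class `"vegetation_params"`: a list with fields
#'   `G`, `D`, `x_crit`, `x_F` and a logical `forest_exists`.
#' @examples
#' p <- vegetation_params()        # G = 0.85, D = 0.2, x_crit = 0.3
#' p$x_F                           # 0.7647...
#' @export
vegetation_params <- function(G = 0.85, D = 0.2, x_crit = 0.3) {
  stopifnot(is.numeric(G), is.numeric(D), is.numeric(x_crit),
            length(G) == 1L, length(D) == 1L, length(x_crit) == 1L,
            is.finite(G), is.finite(D), is.finite(x_crit))
  if (!(G > D && D > 0))
    stop("require G > D > 0", call. = FALSE)
  if (!(x_crit > 0 && x_crit < 1))
    stop("require 0 < x_crit < 1", call. = FALSE)
  x_F <- 1 - D / G
  forest_exists <- x_crit < x_F
  if (!forest_exists)
    warning("forest state absent: x_crit >= x_F = ", signif(x_F, 6),
            call. = FALSE)
  structure(list(G = G, D = D, x_crit = x_crit, x_F = x_F,
                 forest_exists = forest_exists),
            class = "vegetation_params")
}

#' @export
print.vegetation_params <- function(x, ...) {
  cat("Vegetation model parameters\n")
  cat(sprintf("  G = %g, D = %g, x_crit = %g\n", x$G, x$D, x$x_crit))
  cat(sprintf("  forest state x_F = %g (%s), savanna state x_S = 0\n",
              x$x_F, if (x$forest_exists) "exists" else "absent"))
  invisible(x)
}

#' Piecewise representation of the discontinuous vegetation field
#'
#' Bundles the two smooth one-sided branches, the switching function
#' `h(x) = x_crit - x` and the boundary location.  `f_plus` is the growth
#' branch valid for `x > x_crit`; `f_minus` the decay branch for
#' `x < x_crit`.  Both are polynomial, hence C^1 up to the boundary,
#' where they disagree (a genuine jump).
#'
#' @param params a [vegetation_params()] object.
#' @return An object of class `"piecewise_field"` with vectorized
#'   functions `f_plus`, `f_minus`, `h`, and the boundary `sigma`.
#' @export
piecewise_field <- function(params = vegetation_params()) {
  stopifnot(inherits(params, "vegetation_params"))
  G <- params$G; D <- params$D; xc <- params$x_crit
  structure(list(
    f_plus  = function(x) G * (1 - x) * x - D * x,
    f_minus = function(x) -D * x,
    h       = function(x) xc - x,
    sigma   = xc,
    params  = params
  ), class = "piecewise_field")
}

#' Filippov convex-inclusion value at the switching boundary
#'
#' At the boundary the field value is undefined; Filippov's convexification
#' replaces it by the closed convex hull of the two one-sided limits,
#' \deqn{co[f_-, f_+](x_{crit}) = \{(1-q) f_-(x_{crit}) + q f_+(x_{crit}),
#'       \; q \in [0,1]\}
#'     = [-D\,x_{crit},\; G(1-x_{crit})x_{crit} - D\,x_{crit}].}
#'
#' @param params a [vegetation_params()] object.
#' @return An object of class `"filippov_interval"`: list with `lower`,
#'   `upper`, and `value(q)` mapping the convexification parameter
#'   `q` in \[0, 1\] to a rate.
#' @examples
#' fi <- filippov_interval(vegetation_params())
#' c(fi$lower, fi$upper)    # -0.06  0.1185
#' @export
filippov_interval <- function(params = vegetation_params()) {
  stopifnot(inherits(params, "vegetation_params"))
  fld <- piecewise_field(params)
  lo <- fld$f_minus(params$x_crit)
  hi <- fld$f_plus(params$x_crit)
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  fm <- fld$f_minus(params$x_crit); fp <- fld$f_plus(params$x_crit)
  structure(list(
    lower = lo, upper = hi,
    value = function(q) {
      stopifnot(all(q >= 0 & q <= 1))
      (1 - q) * fm + q * fp
    },
    at = params$x_crit
  ), class = "filippov_interval")
}

#' @export
print.filippov_interval <- function(x, ...) {
  cat(sprintf("Filippov interval at x = %g: [%g, %g]\n",
              x$at, x$lower, x$upper))
  invisible(x)
}

#' Evaluate the discontinuous vegetation field
#'
#' Returns the one-sided branch value away from the switching boundary.
#' Exactly at the boundary the field is set-valued: a scalar query there
#' returns the [filippov_interval()] object rather than a number, so a
#' caller can never silently evaluate at the discontinuity; a vector query
#' containing the boundary is an error.
#'
#' @param x forest cover (finite, non-negative); scalar or vector.
#' @param params a [vegetation_params()] object.
#' @return Numeric vector of rates, or a `"filippov_interval"` when the
#'   scalar `x` equals `x_crit`.
#' @export
evaluate_field <- function(x, params = vegetation_params()) {
  stopifnot(inherits(params, "vegetation_params"))
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("x must be finite numeric", call. = FALSE)
  if (any(x < 0))
    stop("x must be non-negative", call. = FALSE)
  xc <- params$x_crit
  at_sigma <- x == xc
  if (any(at_sigma)) {
    if (length(x) == 1L) return(filippov_interval(params))
    stop("vector query hits the switching boundary x = ", xc,
         "; use filippov_interval() for the set value", call. = FALSE)
  }
  fld <- piecewise_field(params)
  ifelse(x > xc, fld$f_plus(x), fld$f_minus(x))
}

#' Equilibria of the vegetation model
#'
#' The savanna state \eqn{x_S = 0} (root of the decay branch) and the
#' forest state \eqn{x_F = 1 - D/G} (root of the growth branch).  Both are
#' stable for the admissible parameter range; the forest state is flagged
#' absent when `x_crit >= x_F`.
#'
#' @param params a [vegetation_params()] object.
#' @return A data frame with columns `x`, `state`, `stability`, `exists`.
#' @export
equilibria <- function(params = vegetation_params()) {
  stopifnot(inherits(params, "vegetation_params"))
  data.frame(
    x = c(0, params$x_F),
    state = c("savanna", "forest"),
    stability = c("stable", "stable"),
    exists = c(TRUE, params$forest_exists),
    stringsAsFactors = FALSE
  )
}

# Sliding-mode classification for a scalar two-branch field.
# value_minus / value_plus are the one-sided limits at the boundary, where
# "minus" is the branch valid below the boundary and "plus" the branch
# above.  With the switching function h(x) = x_b - x the normal n = grad h
# = -1 points from the upper region into the lower one; the classification
# is stated here in the equivalent physical form: a boundary both sides
# flow away from is repelling, one both sides flow into is attracting,
# and same-signed one-sided values cross transversally.
classify_jump <- function(value_minus, value_plus) {
  if (value_minus * value_plus > 0) return("transversal")
  if (value_minus > 0 && value_plus < 0) return("attracting-sliding")
  "repelling-sliding"
}

#' Classify the switching boundary of the vegetation field
#'
#' Classifies the boundary \eqn{x = x_{crit}} by the signs of the one-sided
#' field limits (normal convention `n = grad h = -1` for
#' `h(x) = x_crit - x`): a *transversal* crossing when both projections
#' have the same sign, an *attracting sliding mode* when both point into
#' the boundary, and a *repelling sliding mode* when both point away --
#' the vegetation model's case, which destroys forward uniqueness at
#' `x_crit`.
#'
#' @param params a [vegetation_params()] object, or a list with functions
#'   `f_minus`, `f_plus` and boundary `sigma` (e.g. a
#'   [piecewise_field()] or a synthetic test field).
#' @return One of `"transversal"`, `"attracting-sliding"`,
#'   `"repelling-sliding"`.
#' @examples
#' classify_switch(vegetation_params())   # "repelling-sliding"
#' @export
classify_switch <- function(params = vegetation_params()) {
  fld <- if (inherits(params, "vegetation_params")) piecewise_field(params)
         else params
  stopifnot(is.function(fld$f_minus), is.function(fld$f_plus),
            is.numeric(fld$sigma))
  classify_jump(fld$f_minus(fld$sigma), fld$f_plus(fld$sigma))
}

#' Analytic solutions started on the switching boundary
#'
#' For the repelling sliding mode the initial-value problem with
#' \eqn{x_0 = x_{crit}} has three solution branches inside the Filippov
#' inclusion: a growth branch
#' \deqn{x(t) = -\frac{D-G}{2G}\left(\tanh\frac{(C_1 - t)(D-G)}{2} + 1\right)}
#' (free integration constant \eqn{C_1}, approaching the forest state),
#' the constant branch \eqn{x(t) = x_{crit}} (possible because
#' \eqn{0 \in co[f_-, f_+]}), and the decay branch
#' \eqn{x(t) = x_{crit} e^{-Dt}} (sliding off towards the savanna state).
#'
#' @param params a [vegetation_params()] object.
#' @return An object of class `"analytic_solution_set"`: list with
#'   functions `tanh_branch(t, C1)`, `constant_branch(t)`,
#'   `decay_branch(t)`.
#' @export
analytic_solutions <- function(params = vegetation_params()) {
  stopifnot(inherits(params, "vegetation_params"))
  G <- params$G; D <- params$D; xc <- params$x_crit
  structure(list(
    tanh_branch = function(t, C1 = 0) {
      -(D - G) / (2 * G) * (tanh((C1 - t) * (D - G) / 2) + 1)
    },
    constant_branch = function(t) rep(xc, length(t)),
    decay_branch = function(t) xc * exp(-D * t),
    params = params
  ), class = "analytic_solution_set")
}
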