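#' Criteria defining a stochastic basin of attraction
#'
#' Two retention criteria build the basin.  Under Definition I the
#' retained core is \eqn{D_I = \{x \in D : p(x) < m\}} (escape
#' probability below `m`, strict) and the returning fringe is
#' \eqn{D_{II}^c = \{x \in D_I^c : p_{ret}(x) > M\}} (return probability
#' above `M`, strict).  Under Definition II the core uses the mean exit
#' time, \eqn{D_I = \{x \in D : u(x) \ge m\}} (non-strict), with `m`
#' either a fixed time or the average mean exit time over `D` (AMET),
#' and the fringe \eqn{\{p_{ret} \ge M\}} (non-strict).  The
#' strict/non-strict forms follow the two definitions exactly; on a grid
#' they are immaterial but fixed for determinism.
#'
#' @param m retention threshold: a probability in (0, 1) for
#'   Definition I, a time for Definition II (ignored when
#'   `m_mode = "amet"`).
#' @param M return-probability threshold in (0, 1).
#' @param m_mode `"fixed"` or `"amet"` (average mean exit time,
#'   Definition II only).
#' @return An object of class `"basin_criteria"`.
#' @export
basin_criteria <- function(m = 0.5, M = 0.7,
                           m_mode = c("fixed", "amet")) {
  m_mode <- match.arg(m_mode)
  stopifnot(is.numeric(M), length(M) == 1L, M > 0, M < 1)
  if (m_mode == "fixed")
    stopifnot(is.numeric(m), length(m) == 1L, is.finite(m), m > 0)
  structure(list(m = m, M = M, m_mode = m_mode),
            class = "basin_criteria")
}

# Sub/super-level set of grid values as a union of intervals.
# Crossing locations between adjacent nodes are linearly interpolated;
# runs touching the first/last interior node are closed with the domain
# bounds.  Returns a 2-column matrix (possibly 0 rows).
threshold_intervals <- function(x, v, threshold, above, strict, bounds) {
  keep <- if (above) {
    if (strict) v > threshold else v >= threshold
  } else {
    if (strict) v < threshold else v <= threshold
  }
  n <- length(x)
  if (!any(keep)) return(matrix(numeric(0), 0, 2))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  cross <- function(i, j) {
    if (v[i] == v[j]) return((x[i] + x[j]) / 2)
    stats::approx(v[c(i, j)], x[c(i, j)], xout = threshold)$y
  }
  out <- matrix(NA_real_, nrow(runs), 2)
  for (q in seq_len(nrow(runs))) {
    a <- runs[q, 1]; b <- runs[q, 2]
    out[q, 1] <- if (a == 1L) bounds[1] else cross(a - 1L, a)
    out[q, 2] <- if (b == n) bounds[2] else cross(b, b + 1L)
  }
  out
}

interval_union_length <- function(ints, window = c(-Inf, Inf)) {
  if (nrow(ints) == 0L) return(0)
  lo <- pmax(ints[, 1], window[1])
  hi <- pmin(ints[, 2], window[2])
  sum(pmax(hi - lo, 0))
}

new_sba_result <- function(D_I, D_II_c, criteria, definition, scenario) {
  basin <- rbind(D_I, D_II_c)
  if (nrow(basin)) basin <- basin[order(basin[, 1]), , drop = FALSE]
  structure(list(D_I = D_I, D_II_c = D_II_c, basin = basin,
                 criteria = criteria, definition = definition,
                 scenario = scenario),
            class = "sba_result")
}

#' @export
print.sba_result <- function(x, ...) {
  fmt <- function(m) {
    if (nrow(m) == 0L) return("{}")
    paste(apply(m, 1, function(r)
      sprintf("(%.4f, %s)", r[1],
              if (is.finite(r[2])) sprintf("%.4f", r[2]) else "Inf")),
      collapse = " U ")
  }
  cat(sprintf("Stochastic basin of attraction (Definition %s)\n",
              x$definition))
  if (!is.null(x$scenario))
    cat(sprintf("  scenario: alpha = %g, psi = %g, epsilon = %g\n",
                x$scenario$alpha, x$scenario$psi, x$scenario$epsilon))
  cat("  D_I    =", fmt(x$D_I), "\n")
  cat("  D_II^c =", fmt(x$D_II_c), "\n")
  cat("  basin  =", fmt(x$basin), "\n")
  invisible(x)
}

#' Average mean exit time over the domain
#'
#' The unweighted arithmetic mean of the solved mean-exit-time field over
#' the interior grid nodes of `D`; used as the Definition II retention
#' threshold (`m_mode = "amet"`).  The averaging measure is a
#' configuration choice; uniform node weighting is the default.
#'
#' @param u a `"scalar_field"` from [solve_mean_exit_time()].
#' @return Scalar time.
#' @export
amet <- function(u) {
  stopifnot(inherits(u, "scalar_field"))
  if (length(u$interior) == 0L) stop("empty interior", call. = FALSE)
  mean(u$values[u$interior])
}

#' Stochastic basin under Definition I (escape-probability criteria)
#'
#' Assembles the basin from two already-solved escape problems: the
#' escape probability `p_escape` on the domain of attraction `D`, and
#' the return probability `p_return` on `D_I^c` with target `D_I`
#' (solved after `D_I` is known; see [compute_sba()] for the
#' orchestration).  `D_I` is the strict sub-level set `{p_escape < m}`
#' and `D_II^c` the strict super-level set `{p_return > M}`.  Thresholds
#' never crossed give empty sets, not errors.
#'
#' @param p_escape a `"scalar_field"` escape probability on `D`.
#' @param p_return a `"scalar_field"` return probability on `D_I^c`, or
#'   NULL (then `D_II^c` is empty).
#' @param criteria a [basin_criteria()].
#' @param scenario optional descriptor list (`alpha`, `psi`, `epsilon`).
#' @return An `"sba_result"`.
#' @export
sba_definition_I <- function(p_escape, p_return, criteria = basin_criteria(),
                             scenario = NULL) {
  stopifnot(inherits(p_escape, "scalar_field"),
            inherits(criteria, "basin_criteria"))
  stopifnot(criteria$m > 0, criteria$m < 1)
  ii <- p_escape$interior
  bounds <- c(p_escape$D[1],
              if (is.finite(p_escape$D[2])) p_escape$D[2] else Inf)
  D_I <- threshold_intervals(p_escape$x[ii], p_escape$values[ii],
                             criteria$m, above = FALSE, strict = TRUE,
                             bounds = bounds)
  D_II_c <- matrix(numeric(0), 0, 2)
  if (!is.null(p_return)) {
    stopifnot(inherits(p_return, "scalar_field"))
    jj <- p_return$interior
    D_II_c <- threshold_intervals(p_return$x[jj], p_return$values[jj],
                                  criteria$M, above = TRUE, strict = TRUE,
                                  bounds = p_return$D)
  }
  new_sba_result(D_I, D_II_c, criteria, "I", scenario)
}

#' Stochastic basin under Definition II (exit-time criterion)
#'
#' Assembles the basin from a solved mean-exit-time field on the bounded
#' domain `D` and a return-probability field on `D_I^c`.  `D_I` is the
#' non-strict super-level set `{u >= m}` with `m` either fixed or the
#' AMET of `u`; `D_II^c` is `{p_return >= M}`.
#'
#' @param u a `"scalar_field"` from [solve_mean_exit_time()].
#' @param p_return a `"scalar_field"` return probability, or NULL.
#' @param criteria a [basin_criteria()]; `m_mode = "amet"` replaces `m`
#'   by `amet(u)`.
#' @param scenario optional descriptor list.
#' @return An `"sba_result"` (its `criteria$m` holds the value actually
#'   used).
#' @export
sba_definition_II <- function(u, p_return,
                              criteria = basin_criteria(m_mode = "amet"),
                              scenario = NULL) {
  stopifnot(inherits(u, "scalar_field"),
            inherits(criteria, "basin_criteria"))
  m <- if (criteria$m_mode == "amet") amet(u) else criteria$m
  crit_used <- basin_criteria(m = m, M = criteria$M, m_mode = "fixed")
  crit_used$m_mode <- criteria$m_mode
  ii <- u$interior
  D_I <- threshold_intervals(u$x[ii], u$values[ii], m,
                             above = TRUE, strict = FALSE, bounds = u$D)
  D_II_c <- matrix(numeric(0), 0, 2)
  if (!is.null(p_return)) {
    stopifnot(inherits(p_return, "scalar_field"))
    jj <- p_return$interior
    D_II_c <- threshold_intervals(p_return$x[jj], p_return$values[jj],
                                  criteria$M, above = TRUE,
                                  strict = FALSE, bounds = p_return$D)
  }
  new_sba_result(D_I, D_II_c, crit_used, "II", scenario)
}

#' Length of a stochastic basin
#'
#' Lebesgue measure of the basin intervals clipped to a reference
#' window.  Rays are measured up to the window's right edge, so basins
#' built on right-unbounded domains remain comparable across scenarios.
#'
#' @param sba an `"sba_result"`.
#' @param window numeric length-2 clipping window (default `c(0, 1.52)`,
#'   the state range spanned by the exit domains).
#' @return Scalar length.
#' @export
basin_length <- function(sba, window = c(0, 1.52)) {
  stopifnot(inherits(sba, "sba_result"))
  interval_union_length(sba$basin, window)
}

#' Compute a stochastic basin of attraction for a scenario
#'
#' Full orchestration for one noise/mollification scenario.  Under
#' Definition I it solves the escape problem on the forest domain
#' `D = (x_A, Inf)` with the savanna target, extracts `D_I = {p < m}`,
#' then re-solves a fresh escape problem on `D_I^c = (0, l)` with target
#' `D_I = (l, Inf)` for the returning fringe.  Under Definition II it
#' solves the mean exit time on the bounded domain, thresholds at the
#' AMET (or fixed `m`), and solves the return problem on `(0, a)` with
#' the bounded `D_I` interval as target.
#'
#' @param scenario a scenario from [reference_grid()] (or any list with
#'   `field`, `noise`, `domains`, `criteria`, `alpha`, `psi`, `epsilon`).
#' @param definition `"I"` or `"II"`.
#' @param h grid spacing for the solves.
#' @return An `"sba_result"` with the solved fields attached
#'   (`p_escape`/`u`, `p_return`).
#' @export
compute_sba <- function(scenario, definition = c("I", "II"), h = 0.002) {
  definition <- match.arg(definition)
  fld <- scenario$field
  noise <- scenario$noise
  if (definition == "I") {
    dom <- scenario$domains$def1
    crit <- scenario$criteria$def1
    gen <- build_generator(fld, noise, dom, h)
    p1 <- solve_escape_probability(gen)
    res0 <- sba_definition_I(p1, NULL, crit,
                             scenario[c("alpha", "psi", "epsilon")])
    p2 <- NULL
    if (nrow(res0$D_I)) {
      l <- res0$D_I[1, 1]
      if (l > h * 4) {
        dom2 <- domain_spec(c(0, l), target = c(l, Inf))
        gen2 <- build_generator(fld, noise, dom2, h)
        p2 <- solve_escape_probability(gen2)
      }
    }
    out <- sba_definition_I(p1, p2, crit,
                            scenario[c("alpha", "psi", "epsilon")])
    out$p_escape <- p1; out$p_return <- p2
    return(out)
  }
  dom <- scenario$domains$def2
  crit <- scenario$criteria$def2
  gen <- build_generator(fld, noise, dom, h)
  u <- solve_mean_exit_time(gen)
  res0 <- sba_definition_II(u, NULL, crit,
                            scenario[c("alpha", "psi", "epsilon")])
  p2 <- NULL
  if (nrow(res0$D_I)) {
    a <- res0$D_I[1, 1]; b <- res0$D_I[1, 2]
    if (a > h * 4) {
      dom2 <- domain_spec(c(0, a), target = c(a, b))
      gen2 <- build_generator(fld, noise, dom2, h)
      p2 <- solve_escape_probability(gen2)
    }
  }
  out <- sba_definition_II(u, p2, crit,
                           scenario[c("alpha", "psi", "epsilon")])
  out$u <- u; out$p_return <- p2
  out
}
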