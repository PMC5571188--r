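# Accept either a mollified_field, a piecewise-smooth function, or NULL
# (zero drift) wherever a drift is needed.
as_drift_function <- function(field) {
  if (is.null(field)) return(function(x) numeric(length(x)) )
  if (inherits(field, "mollified_field")) return(field$fun)
  if (is.function(field)) return(field)
  stop("field must be a mollified_field, a function, or NULL",
       call. = FALSE)
}

# Deterministic child seed for path j under root seed s (kept < 2^31).
child_seed <- function(s, j) {
  (as.double(s) * 48271 + j * 65537) %% 2147483629 + 1
}

#' Simulate paths of the stochastic vegetation model
#'
#' Euler-Maruyama integration of
#' \eqn{dX_t = f^\varepsilon(X_t)\,dt + \psi\, dL^\alpha_t}
#' on a uniform time grid.  States may go negative: the decay branch
#' `-Dx` extends below zero and pushes back towards 0, the ecological
#' reading being dormancy ("hibernation") until conditions allow
#' regrowth; no absorption is imposed.
#'
#' Each path uses its own RNG substream derived deterministically from
#' the root seed, so ensembles are bit-reproducible and enlarging
#' `n_paths` does not reshuffle earlier paths.
#'
#' @param field drift: a [build_mollified_field()] result, a function,
#'   or NULL for zero drift.
#' @param noise a [noise_spec()].
#' @param x0 initial cover (scalar).
#' @param T time horizon.
#' @param dt time step.
#' @param n_paths number of paths.
#' @param seed integer root seed.
#' @return An object of class `"path_ensemble"`: list with `times`
#'   (length `m`), `states` (`m x n_paths` matrix), `divergent` (logical
#'   per path, `|X| > 1e6` reached), and the configuration.
#' @export
simulate_paths <- function(field, noise, x0, T, dt, n_paths = 1L,
                           seed = 1L) {
  stopifnot(inherits(noise, "noise_spec"), T > 0, dt > 0, n_paths >= 1)
  f <- as_drift_function(field)
  n_steps <- ceiling(T / dt)
  times <- (0:n_steps) * dt
  states <- matrix(NA_real_, n_steps + 1L, n_paths)
  divergent <- logical(n_paths)
  sc <- noise$psi * dt^(1 / noise$alpha)
  for (j in seq_len(n_paths)) {
    set.seed(child_seed(seed, j))
    dL <- rstable_standard(n_steps, noise$alpha)
    x <- numeric(n_steps + 1L)
    x[1] <- x0
    for (k in seq_len(n_steps)) {
      x[k + 1L] <- x[k] + f(x[k]) * dt + sc * dL[k]
      if (abs(x[k + 1L]) > 1e6) {
        divergent[j] <- TRUE
        x[(k + 1L):(n_steps + 1L)] <- x[k + 1L]
        break
      }
    }
    states[, j] <- x
  }
  structure(list(times = times, states = states, divergent = divergent,
                 x0 = x0, dt = dt, seed = seed, noise = noise),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf(
    "Path ensemble: %d paths, %d steps of dt = %g from x0 = %g (seed %d)\n",
    ncol(x$states), length(x$times) - 1L, x$dt, x$x0, x$seed))
  invisible(x)
}

# Vectorized-over-paths first-exit simulation used by the MC estimators.
# Single RNG stream (chunked in time), deterministic under the seed.
# Returns exit times (NA when censored at T) and landing states.
mc_first_exit <- function(f, noise, D, x0, n_paths, dt, T, seed) {
  set.seed(seed)
  sc <- noise$psi * dt^(1 / noise$alpha)
  x <- rep(x0, n_paths)
  tau <- rep(NA_real_, n_paths)
  landing <- rep(NA_real_, n_paths)
  idx <- seq_len(n_paths)
  n_steps <- ceiling(T / dt)
  k <- 0L
  while (length(idx) && k < n_steps) {
    k <- k + 1L
    xi <- x[idx]
    xi <- xi + f(xi) * dt + sc * rstable_standard(length(idx), noise$alpha)
    x[idx] <- xi
    out <- xi <= D[1] | xi >= D[2]
    if (any(out)) {
      tau[idx[out]] <- k * dt
      landing[idx[out]] <- xi[out]
      idx <- idx[!out]
    }
  }
  list(tau = tau, landing = landing, censored = length(idx))
}

#' Monte Carlo mean first exit time
#'
#' Estimates \eqn{u(x_0) = E\,\tau} for the first exit from the open
#' interval `D`, by direct path simulation.  Exit detection is
#' discrete-time (the state after a full Euler step), consistent with
#' cadlag paths that cross by jumping.  Paths still inside `D` at the
#' horizon are censored: their contribution is counted at `T` (biasing
#' the estimate low) and reported; if more than half the paths are
#' censored the horizon is extended once (x 4) and, if censoring
#' persists, the estimate is flagged.
#'
#' @param field drift (see [simulate_paths()]).
#' @param noise a [noise_spec()].
#' @param D numeric length-2 open interval (the domain).
#' @param x0 initial cover inside `D` (a boundary value returns 0).
#' @param n_paths number of paths.
#' @param dt time step.
#' @param T horizon; `NULL` picks `50` and relies on the extension rule.
#' @param seed integer seed.
#' @return List with `estimate`, `stderr`, `n_censored`, `censor_warning`,
#'   `n_paths`, `T`.
#' @export
mc_mean_exit_time <- function(field, noise, D, x0, n_paths = 1000L,
                              dt = 1e-3, T = NULL, seed = 1L) {
  stopifnot(inherits(noise, "noise_spec"), length(D) == 2L, D[1] < D[2])
  if (x0 < D[1] || x0 > D[2])
    stop("x0 must lie in the closed domain", call. = FALSE)
  if (x0 == D[1] || x0 == D[2])
    return(list(estimate = 0, stderr = 0, n_censored = 0L,
                censor_warning = FALSE, n_paths = n_paths, T = 0))
  if (is.null(T)) T <- 50
  f <- as_drift_function(field)
  res <- mc_first_exit(f, noise, D, x0, n_paths, dt, T, seed)
  if (res$censored > n_paths / 2) {
    T <- 4 * T
    res <- mc_first_exit(f, noise, D, x0, n_paths, dt, T, seed)
  }
  tau <- res$tau
  cens <- is.na(tau)
  tau[cens] <- T
  list(estimate = mean(tau),
       stderr = stats::sd(tau) / sqrt(n_paths),
       n_censored = sum(cens),
       censor_warning = sum(cens) > n_paths / 2,
       n_paths = n_paths, T = T)
}

#' Monte Carlo escape probability
#'
#' Estimates \eqn{p(x_0) = P\{X_\tau \in U\}}: the probability that the
#' first exit from `D` lands in the exterior target set `U`.  Censored
#' paths (no exit by `T`) are excluded from the fraction and reported.
#'
#' @param field drift (see [simulate_paths()]).
#' @param noise a [noise_spec()].
#' @param D numeric length-2 open interval (the domain).
#' @param U numeric length-2 target interval in the complement of `D`
#'   (landing counts when `U[1] < X_tau < U[2]`).
#' @param x0 initial cover inside `D`.
#' @param n_paths,dt,T,seed as in [mc_mean_exit_time()].
#' @return List with `estimate`, `stderr`, `n_censored`, `n_exited`,
#'   `n_paths`, `T`.
#' @export
mc_escape_probability <- function(field, noise, D, U, x0,
                                  n_paths = 1000L, dt = 1e-3, T = NULL,
                                  seed = 1L) {
  stopifnot(inherits(noise, "noise_spec"), length(D) == 2L, D[1] < D[2],
            length(U) == 2L)
  if (x0 <= D[1] || x0 >= D[2])
    stop("x0 must lie in the open domain", call. = FALSE)
  if (is.null(T)) T <- 50
  f <- as_drift_function(field)
  res <- mc_first_exit(f, noise, D, x0, n_paths, dt, T, seed)
  if (res$censored > n_paths / 2) {
    T <- 4 * T
    res <- mc_first_exit(f, noise, D, x0, n_paths, dt, T, seed)
  }
  hit <- !is.na(res$tau)
  n_ex <- sum(hit)
  in_target <- res$landing[hit] > U[1] & res$landing[hit] < U[2]
  p <- if (n_ex) mean(in_target) else NA_real_
  se <- if (n_ex) sqrt(max(p * (1 - p), 1 / n_ex)) / sqrt(n_ex) else NA_real_
  list(estimate = p, stderr = se,
       n_censored = n_paths - n_ex, n_exited = n_ex,
       n_paths = n_paths, T = T)
}
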