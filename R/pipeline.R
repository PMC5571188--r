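#' Read a pipeline configuration
#'
#' Configurations are plain JSON files.  Recognized keys (all optional
#' unless a command requires them): `epsilon` (one of the preset radii),
#' `alpha`, `psi`, `h` (grid spacing), `domain` (length-2, `null` upper
#' for unbounded), `target` (length-2), `closure`, `truncation`,
#' `definition` (`"I"`/`"II"`), `m`, `M`, `m_mode`, `seed`, `grid_from`,
#' `grid_to`, `grid_step`, `mc_check` (logical), `mc_paths`, `mc_dt`.
#'
#' @param path JSON file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

require_keys <- function(config, keys) {
  miss <- setdiff(keys, names(config))
  if (length(miss))
    stop("missing config key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

write_table_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  path
}

manifest_entry <- function(outputs, config, t0) {
  list(package = "levybasin",
       version = as.character(utils::packageVersion("levybasin")),
       config = config,
       outputs = outputs,
       elapsed_s = as.numeric(Sys.time()) - t0)
}

config_field <- function(config, params = vegetation_params()) {
  require_keys(config, "epsilon")
  presets <- mollifier_presets()
  key <- as.character(config$epsilon)
  spec <- if (key %in% names(presets)) presets[[key]]
          else {
            require_keys(config, c("U", "U_eps"))
            mollifier_spec(config$epsilon, config$U, config$U_eps)
          }
  build_mollified_field(spec, params)
}

#' Run the mollification stage
#'
#' Builds the mollified field for the configured `epsilon`, writes the
#' sampled drift as a two-column table (`field.tsv`) and a JSON report
#' (`mollify.json`) with `x_A` and the junction-gap diagnostics.
#'
#' @param config list (see [read_run_config()]); requires `epsilon`.
#' @param out_dir output directory (created if needed).
#' @return The manifest list, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_mollify <- function(config, out_dir) {
  t0 <- as.numeric(Sys.time())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fld <- config_field(config)
  step <- config$grid_step %||% 0.005
  tab <- sample_field(fld,
                      from = config$grid_from %||% 0,
                      to = config$grid_to %||% 1,
                      by = step)
  o1 <- write_table_file(tab, file.path(out_dir, "field.tsv"))
  rep <- list(epsilon = fld$spec$epsilon, U = fld$spec$U,
              U_eps = fld$spec$U_eps, x_A = fld$x_A,
              junction_gap = as.list(fld$junction_gap))
  o2 <- write_json_file(rep, file.path(out_dir, "mollify.json"))
  man <- manifest_entry(c(o1, o2), config, t0)
  write_json_file(man, file.path(out_dir, "manifest.json"))
  invisible(man)
}

#' Run the exit-problem solvers
#'
#' Builds the discrete generator for the configured scenario and solves
#' the mean exit time (`u.tsv`) and, when a `target` is configured, the
#' escape probability (`p.tsv`).  With `mc_check = TRUE`, Monte Carlo
#' estimates at three interior probe points and their 3-standard-error
#' verdicts are appended to the JSON report.
#'
#' @param config list; requires `epsilon`, `alpha`, `psi`, `domain`.
#' @param out_dir output directory.
#' @return The manifest, invisibly.
#' @export
run_solve <- function(config, out_dir) {
  t0 <- as.numeric(Sys.time())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  require_keys(config, c("epsilon", "alpha", "psi", "domain"))
  fld <- config_field(config)
  noise <- noise_spec(config$alpha, config$psi)
  D <- unlist(config$domain)
  if (length(D) == 1L || is.na(D[2])) D <- c(D[1], Inf)
  dom <- domain_spec(D, target = config$target,
                     closure = config$closure %||% "absorbing",
                     truncation = config$truncation %||% 3)
  h <- config$h %||% 0.002
  gen <- build_generator(fld, noise, dom, h)
  outputs <- character(0)
  rep <- list(alpha = noise$alpha, psi = noise$psi,
              epsilon = fld$spec$epsilon, x_A = fld$x_A,
              D = dom$D, target = dom$target, h = h,
              closure = dom$closure, truncation = dom$truncation,
              n_nodes = length(gen$x), n_interior = length(gen$interior))
  u <- solve_mean_exit_time(gen)
  outputs <- c(outputs, write_table_file(
    data.frame(x = u$x, u = u$values), file.path(out_dir, "u.tsv")))
  p <- NULL
  if (!is.null(dom$target)) {
    p <- solve_escape_probability(gen)
    outputs <- c(outputs, write_table_file(
      data.frame(x = p$x, p = p$values), file.path(out_dir, "p.tsv")))
  }
  if (isTRUE(config$mc_check)) {
    dr <- if (dom$unbounded) dom$truncation else dom$D[2]
    probes <- dom$D[1] + c(0.25, 0.5, 0.75) * (dr - dom$D[1])
    mc_D <- c(dom$D[1], dr)
    checks <- lapply(probes, function(x0) {
      mu <- mc_mean_exit_time(fld, noise, mc_D, x0,
                              n_paths = config$mc_paths %||% 2000L,
                              dt = config$mc_dt %||% 1e-3,
                              seed = config$seed %||% 1L)
      entry <- list(x0 = x0, u_solver = field_at(u, x0),
                    u_mc = mu$estimate, u_stderr = mu$stderr,
                    u_ok = abs(field_at(u, x0) - mu$estimate) <=
                      3 * mu$stderr)
      if (!is.null(p)) {
        mp <- mc_escape_probability(fld, noise, mc_D, dom$target, x0,
                                    n_paths = config$mc_paths %||% 2000L,
                                    dt = config$mc_dt %||% 1e-3,
                                    seed = (config$seed %||% 1L) + 1L)
        entry <- c(entry, list(p_solver = field_at(p, x0),
                               p_mc = mp$estimate, p_stderr = mp$stderr,
                               p_ok = abs(field_at(p, x0) - mp$estimate)
                                 <= 3 * mp$stderr))
      }
      entry
    })
    rep$mc_check <- checks
  }
  outputs <- c(outputs, write_json_file(rep,
                                        file.path(out_dir, "solve.json")))
  man <- manifest_entry(outputs, config, t0)
  write_json_file(man, file.path(out_dir, "manifest.json"))
  invisible(man)
}

sba_record <- function(sba) {
  ival <- function(m) if (nrow(m) == 0L) list() else
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  list(definition = sba$definition,
       alpha = sba$scenario$alpha, psi = sba$scenario$psi,
       epsilon = sba$scenario$epsilon,
       m = sba$criteria$m, M = sba$criteria$M,
       m_mode = sba$criteria$m_mode,
       D_I = ival(sba$D_I), D_II_c = ival(sba$D_II_c),
       basin = ival(sba$basin),
       basin_length = basin_length(sba))
}

#' Run the stochastic-basin stage over a scenario grid
#'
#' Computes the stochastic basin of attraction for every scenario in the
#' configured sub-grid, under one or both definitions, and writes a JSON
#' record per scenario plus a combined summary table
#' (`sba_summary.tsv`).
#'
#' @param config list; optional keys `epsilon`, `alpha`, `psi` (scalars
#'   or vectors selecting the sub-grid; defaults: full grid),
#'   `definition` (`"I"`, `"II"` or `c("I","II")`), `h`.
#' @param out_dir output directory.
#' @return The manifest, invisibly.
#' @export
run_sba <- function(config, out_dir) {
  t0 <- as.numeric(Sys.time())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenarios <- reference_grid(
    epsilons = config$epsilon %||% c(0.08, 0.05, 0.025),
    alphas = config$alpha %||% c(0.5, 1, 1.5),
    psis = config$psi %||% c(0.1, 1))
  defs <- config$definition %||% c("I", "II")
  h <- config$h %||% 0.002
  records <- list()
  rows <- list()
  for (sc in scenarios) for (d in defs) {
    sba <- compute_sba(sc, d, h = h)
    rec <- sba_record(sba)
    records[[paste0(sc$label, "_def", d)]] <- rec
    rows[[paste0(sc$label, "_def", d)]] <- data.frame(
      definition = d, epsilon = sc$epsilon, alpha = sc$alpha,
      psi = sc$psi,
      D_I_left = if (nrow(sba$D_I)) sba$D_I[1, 1] else NA_real_,
      D_I_right = if (nrow(sba$D_I)) sba$D_I[nrow(sba$D_I), 2]
                  else NA_real_,
      basin_left = if (nrow(sba$basin)) sba$basin[1, 1] else NA_real_,
      basin_length = basin_length(sba))
  }
  o1 <- write_json_file(records, file.path(out_dir, "sba.json"))
  o2 <- write_table_file(do.call(rbind, rows),
                         file.path(out_dir, "sba_summary.tsv"))
  man <- manifest_entry(c(o1, o2), config, t0)
  write_json_file(man, file.path(out_dir, "manifest.json"))
  invisible(man)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
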