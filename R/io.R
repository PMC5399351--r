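#' Run configuration files
#'
#' Runs are described by a YAML file with blocks
#' `model` (potential name + parameters, `gamma`, `D`, `tau`,
#' `length_scale`), `sim` (fields of [sim_config()]), `solver` (fields of
#' [kramers_grid()]) and `analysis` (`nbins`, `min_count`), plus top-level
#' `seed` and `out_dir`.  The mapping is round-trippable:
#' `read_run_config(write_run_config(cfg, f))` reproduces `cfg`.
#'
#' @param path file path.
#' @return `read_run_config`: a list of class `run_config` with
#'   materialized `potential`, `params`, `sim` (when present) and
#'   `solver_grid` objects alongside the raw fields.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

as_run_config <- function(raw) {
  m <- raw$model %||% stop("config: missing [model] block")
  for (f in c("gamma", "D", "tau")) {
    val <- m[[f]] %||% stop("config: model$", f, " missing")
    if (!is.numeric(val) || val <= 0)
      stop("config: model$", f, " must be a positive number (got ", val, ")")
  }
  pot <- potential_by_name(m$potential %||% "double_well",
                           m$potential_args %||% list())
  params <- gcn_params(gamma = m$gamma, D = m$D, tau = m$tau,
                       length_scale = m$length_scale %||% 1)
  cfg <- list(raw = raw, potential = pot, params = params,
              seed = raw$seed %||% 1L, out_dir = raw$out_dir %||% ".")
  if (!is.null(raw$sim)) {
    s <- raw$sim
    cfg$sim <- sim_config(n_traj = s$n_traj, n_steps = s$n_steps,
                          dt = s$dt %||% (1e-3 * m$tau),
                          burn_in = s$burn_in %||% 0,
                          seed = raw$seed %||% 1L,
                          record_stride = s$record_stride,
                          exact_ou = s$exact_ou %||% FALSE)
  }
  if (!is.null(raw$solver)) {
    g <- raw$solver
    cfg$solver_grid <- kramers_grid(nx = g$nx %||% 161, nv = g$nv %||% 80,
                                    L = g$L, alpha = g$alpha %||% 1.3,
                                    g_floor = g$g_floor %||% 0.05)
  }
  cfg$analysis <- list(nbins = raw$analysis$nbins %||% 101,
                       min_count = raw$analysis$min_count %||% 20)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @param cfg a `run_config` (or the raw list it was built from).
#' @export
write_run_config <- function(cfg, path) {
  raw <- if (inherits(cfg, "run_config")) cfg$raw else cfg
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Serialize a field profile to CSV
#'
#' One row per bin; a commented header records the model parameters, seed
#' and units (velocity-squared for the temperature columns; all columns
#' dimensional unless the profile came from the dimensionless solver).
#'
#' @param fp a `field_profile`.
#' @param path output file.
#' @export
write_profile_csv <- function(fp, path) {
  p <- attr(fp, "params")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# gcntherm field profile | potential=%s seed=%s",
            attr(fp, "potential"), attr(fp, "seed")),
    sprintf("# gamma=%g D=%g tau=%g length_scale=%g", p$gamma, p$D, p$tau,
            p$length_scale),
    "# units: x [length]; n [1/length]; u [velocity]; msv,T,theta [velocity^2];",
    "#        j_q [velocity^3/length]; qdot [velocity^2/time/length]; sigma_m [1/time/length]"),
    con)
  utils::write.csv(as.data.frame(fp), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Serialize a thermo budget to JSON
#'
#' @param budget a `thermo_budget` (or any named list of scalars).
#' @param path output file.
#' @export
write_budget_json <- function(budget, path) {
  jsonlite::write_json(unclass(budget), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' End-to-end simulation run from a config
#'
#' Runs `simulate_xv` -> `estimate_fields` -> `thermo_budget` and writes
#' `profile.csv`, `budget.json` and the resolved `config.yaml` (plus a
#' `log.txt` with per-stage wall times and the stationarity verdict) into
#' the output directory.
#'
#' @param cfg a `run_config` (see [read_run_config()]) or a path to one.
#' @param out_dir output directory (default from the config).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `ensemble`, `profile`, `budget`,
#'   `stationarity` and the output paths.
#' @export
run_simulation <- function(cfg, out_dir = NULL, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(cfg$sim)) stop("config has no [sim] block")
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  logl <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    dt <- proc.time()[["elapsed"]] - t0
    logl <<- c(logl, sprintf("%-12s %8.2f s", name, dt))
    say("%s done in %.2f s", name, dt)
    val
  }
  ens <- stage("simulate", simulate_xv(cfg$potential, cfg$params, cfg$sim))
  st <- stationarity_check(ens)
  logl <- c(logl, sprintf("stationarity TV=%.4f pass=%s", st$tv, st$pass))
  fp <- stage("fields", {
    f <- estimate_fields(ens, cfg$potential, cfg$params,
                         nbins = cfg$analysis$nbins,
                         min_count = cfg$analysis$min_count)
    entropy_flux_density(f)
  })
  bud <- stage("budget", thermo_budget(fp))
  paths <- list(profile = file.path(out_dir, "profile.csv"),
                budget = file.path(out_dir, "budget.json"),
                config = file.path(out_dir, "config.yaml"),
                log = file.path(out_dir, "log.txt"))
  write_profile_csv(fp, paths$profile)
  write_budget_json(bud, paths$budget)
  write_run_config(cfg, paths$config)
  writeLines(logl, paths$log)
  invisible(list(ensemble = ens, profile = fp, budget = bud,
                 stationarity = st, paths = paths))
}

#' Human-readable summary of a completed run
#'
#' Reads the artifacts written by [run_simulation()] and prints a compact
#' report: density and temperature profiles at a few positions, the heat
#' and entropy budgets with their z-scores, and verdicts ("Clausius:
#' total entropy flux negative", "local equilibrium (qdot = 0)") mirroring
#' the standard diagnostic panels for this model.
#'
#' @param run_dir directory containing `profile.csv` and `budget.json`.
#' @return Invisibly, the report lines (also printed).
#' @export
run_report <- function(run_dir) {
  pf <- file.path(run_dir, "profile.csv")
  bf <- file.path(run_dir, "budget.json")
  if (!file.exists(pf) || !file.exists(bf))
    stop("missing run artifacts in ", run_dir)
  fp <- read_profile_csv(pf)
  bud <- jsonlite::read_json(bf, simplifyVector = TRUE)
  ok <- !fp$masked
  lines <- c(
    sprintf("run: %s", normalizePath(run_dir)),
    sprintf("bins: %d (%d unmasked)", nrow(fp), sum(ok)),
    sprintf("max |theta - <v^2>_x|: %.4f", max(abs(fp$theta - fp$msv)[ok])),
    sprintf("total heat flux:    %+.4e (z = %+.2f)", bud$total_qdot, bud$z_qdot),
    sprintf("total entropy flux: %+.4e (z = %+.2f)",
            bud$total_entropy_flux, bud$z_entropy_flux))
  if (is.finite(bud$z_entropy_flux) && bud$z_entropy_flux < -3)
    lines <- c(lines, "Clausius: total entropy flux negative (beyond 3 SE)")
  if (all(abs(fp$qdot[ok]) < 1e-10))
    lines <- c(lines, "local equilibrium (qdot = 0)")
  cat(lines, sep = "\n")
  invisible(lines)
}
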