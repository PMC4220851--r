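#' Scenario objects
#'
#' A scenario bundles a base parameter set, field overrides, a quota
#' closure, a task and task options into a reproducible, serializable unit.
#' Built-in scenarios encode the reference figure settings: the L-sweeps at
#' the two total-potassium levels ("fig1A"-"fig1H"), the b-sweeps showing
#' the continuous/discrete divergence ("fig2A", "fig2B"), and equilibrium
#' listings ("table1-equilibria", "khe-equilibria").
#'
#' @param name scenario label.
#' @param base base parameter set name ("table1") or a
#'   \code{stoich_params} object.
#' @param overrides named list of parameter overrides.
#' @param closure "qss" or "lke".
#' @param task one of simulate, iterate, equilibria, stability, invariance,
#'   sweep, phase.
#' @param options task options (e.g. sweep parameter, values, protocol).
#' @return A \code{stoich_scenario}.
#' @export
scenario <- function(name, base = "table1", overrides = list(),
                     closure = c("qss", "lke"),
                     task = c("simulate", "iterate", "equilibria",
                              "stability", "invariance", "sweep",
                              "phase"),
                     options = list()) {
  closure <- match.arg(closure)
  task <- match.arg(task)
  bad <- setdiff(names(overrides), param_fields())
  if (length(bad))
    stop("overrides reference unknown parameter field(s): ",
         paste(bad, collapse = ", "))
  params <- if (inherits(base, "stoich_params")) base
  else if (identical(base, "table1")) reference_parameters(
    L = if (!is.null(overrides$L)) overrides$L else 1.0)
  else stop("unknown base parameter set: ", base)
  pl <- unclass(params)
  pl[names(overrides)] <- overrides
  params <- do.call(stoich_params, pl)
  diag <- validate_params(params)
  if (any(vapply(diag, function(d) d$severity == "error", logical(1))))
    stop("resolved scenario fails validation")
  structure(list(name = name, base = if (is.character(base)) base else
    "custom", overrides = overrides, closure = closure, task = task,
    options = options, params = params),
    class = "stoich_scenario")
}

#' @export
print.stoich_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': task %s, closure %s, base %s\n", x$name,
              x$task, x$closure, x$base))
  if (length(x$overrides))
    cat("overrides:", paste(names(x$overrides), unlist(x$overrides),
                            sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

fig1_overrides <- function(K_t) list(K_t = K_t, l = 0.2, u = 0.05, L = 1.0)

#' @rdname scenario
#' @export
builtin_scenarios <- function() {
  mk_fig1 <- function(name, K_t, model, variable)
    scenario(name, overrides = fig1_overrides(K_t), task = "sweep",
             options = list(model = model, param = "L",
                            from = 0.25, to = 2.0, n = 200,
                            variable = variable))
  mk_fig2 <- function(name, model)
    scenario(name, overrides = list(l = 0.009, u = 0.02, L = 1.6),
             task = "sweep",
             options = list(model = model, param = "b",
                            from = 0.8, to = 3.5, n = 200,
                            variable = "x"))
  list(
    fig1A = mk_fig1("fig1A", 0.045, "continuous", "x"),
    fig1B = mk_fig1("fig1B", 0.045, "discrete", "x"),
    fig1C = mk_fig1("fig1C", 0.045, "continuous", "y"),
    fig1D = mk_fig1("fig1D", 0.045, "discrete", "y"),
    fig1E = mk_fig1("fig1E", 0.060, "continuous", "x"),
    fig1F = mk_fig1("fig1F", 0.060, "discrete", "x"),
    fig1G = mk_fig1("fig1G", 0.060, "continuous", "y"),
    fig1H = mk_fig1("fig1H", 0.060, "discrete", "y"),
    fig2A = mk_fig2("fig2A", "continuous"),
    fig2B = mk_fig2("fig2B", "discrete"),
    `table1-equilibria` = scenario(
      "table1-equilibria", overrides = list(l = 0.2, u = 0.05, L = 1.0),
      task = "equilibria"),
    `khe-equilibria` = scenario(
      "khe-equilibria", overrides = list(l = 0, u = 0, L = 1.0),
      task = "equilibria")
  )
}

#' Load or save a scenario
#'
#' Scenarios serialize as JSON with keys name, base, overrides, closure,
#' task, options. \code{load_scenario} also accepts a built-in scenario
#' name.
#'
#' @param path a JSON file path, or a built-in name.
#' @return A \code{stoich_scenario}.
#' @export
load_scenario <- function(path) {
  builtins <- builtin_scenarios()
  if (path %in% names(builtins)) return(builtins[[path]])
  if (!file.exists(path)) stop("no such scenario file or built-in: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("name", "base", "overrides", "closure", "task", "options")
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown scenario keys: ",
                        paste(bad, collapse = ", "))
  scenario(name = x$name, base = if (is.null(x$base)) "table1" else x$base,
           overrides = as.list(x$overrides),
           closure = if (is.null(x$closure)) "qss" else x$closure,
           task = x$task, options = as.list(x$options))
}

#' @rdname load_scenario
#' @param sc a \code{stoich_scenario}.
#' @export
save_scenario <- function(sc, path) {
  jsonlite::write_json(
    list(name = sc$name, base = sc$base, overrides = sc$overrides,
         closure = sc$closure, task = sc$task, options = sc$options),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run a scenario
#'
#' Executes the scenario's task and writes its outputs (CSV for
#' trajectories, orbits and sweeps; JSON for equilibrium, stability,
#' invariance and phase reports) into \code{out_dir}. Deterministic tasks
#' rerun bitwise-identically from the same scenario.
#'
#' @param sc a \code{stoich_scenario} or built-in name.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress the one-line summary.
#' @return Invisibly, a list with the task result and output paths.
#' @export
run_scenario <- function(sc, out_dir = tempdir(), quiet = FALSE) {
  if (is.character(sc)) sc <- load_scenario(sc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  o <- sc$options
  pick <- function(key, default) if (!is.null(o[[key]])) o[[key]] else default
  params <- sc$params
  paths <- character(0)
  res <- switch(sc$task,
    simulate = {
      tr <- simulate_model(
        state0 = unlist(pick("state0", c(0.3, 0.3))),
        t_end = pick("t_end", 1000), params = params,
        closure = sc$closure)
      paths <- file.path(out_dir, paste0(sc$name, "-trajectory.csv"))
      write_trajectory(tr, paths)
      tr
    },
    iterate = {
      ob <- map_orbit(unlist(pick("state0", c(0.3, 0.3))),
                      N = pick("N", 2300), burn_in = pick("burn_in", 2000),
                      params = params, closure = sc$closure)
      paths <- file.path(out_dir, paste0(sc$name, "-orbit.csv"))
      write_orbit(ob, paths)
      ob
    },
    equilibria = {
      eqs <- find_equilibria(params, sc$closure,
                             grid_density = pick("grid_density", 50))
      paths <- file.path(out_dir, paste0(sc$name, "-equilibria.json"))
      jsonlite::write_json(lapply(eqs, function(e)
        list(x = e$x, y = e$y, kind = e$kind, feasible = e$feasible,
             residual_continuous = e$residual_continuous,
             residual_discrete = e$residual_discrete)),
        paths, auto_unbox = TRUE, digits = NA)
      eqs
    },
    stability = {
      eqs <- find_equilibria(params, sc$closure,
                             grid_density = pick("grid_density", 50))
      reps <- lapply(eqs, function(e) {
        if (!e$feasible) return(NULL)
        lapply(c("continuous", "discrete"), function(m)
          classify_equilibrium(m, e, params, sc$closure))
      })
      paths <- file.path(out_dir, paste0(sc$name, "-stability.json"))
      jsonlite::write_json(list(
        schema = "stability-report/1",
        reports = lapply(Filter(Negate(is.null), reps), function(pair)
          lapply(pair, function(r) list(
            model = r$model, x = r$x, y = r$y, kind = r$kind,
            verdict = r$verdict, region = r$region,
            eigenvalues = list(re = Re(r$eigenvalues),
                               im = Im(r$eigenvalues)),
            nullcline_slope_F = r$nullcline_slope_F,
            nullcline_slope_G = r$nullcline_slope_G,
            theorem_flags = r$theorem_flags)))),
        paths, auto_unbox = TRUE, digits = NA)
      reps
    },
    invariance = {
      rep <- invariance_check(params, sc$closure)
      paths <- file.path(out_dir, paste0(sc$name, "-invariance.json"))
      jsonlite::write_json(list(
        schema = "invariance-report/1",
        k = rep$geometry$k, p = rep$geometry$p, s = rep$geometry$s,
        triangle = rep$geometry$triangle,
        min_margin = rep$min_margin, pool_ok = rep$pool_ok,
        verdict = rep$verdict), paths, auto_unbox = TRUE, digits = NA)
      rep
    },
    sweep = {
      vals <- pick("values",
                   seq(pick("from", 0.25), pick("to", 2.0),
                       length.out = pick("n", 200)))
      bd <- bifurcation_sweep(
        model = pick("model", "continuous"), param_name = pick("param", "L"),
        values = vals, params = params, closure = sc$closure,
        transient = pick("transient", 500), record = pick("record", 200),
        burn_in = pick("burn_in", 2000), n_sample = pick("n_sample", 300))
      paths <- file.path(out_dir, paste0(sc$name, "-sweep.csv"))
      write_bifurcation(bd, paths)
      bd
    },
    phase = {
      rep <- classify_phase(params, sc$closure,
                            t_end = pick("t_end", 2000))
      paths <- file.path(out_dir, paste0(sc$name, "-phase.json"))
      jsonlite::write_json(list(
        schema = "phase-report/1", phase = rep$phase,
        subcase = rep$subcase, E1_verdict = rep$E1$verdict),
        paths, auto_unbox = TRUE, digits = NA)
      rep
    })
  if (!quiet) {
    msg <- switch(sc$task,
      equilibria = paste0(length(res), " equilibria"),
      invariance = paste0("verdict ", res$verdict),
      phase = paste0("phase ", res$phase),
      sweep = paste0(length(res$values), " values"),
      "done")
    message("scenario '", sc$name, "' (", sc$task, "): ", msg,
            " -> ", paste(paths, collapse = ", "))
  }
  invisible(list(result = res, paths = paths, scenario = sc))
}
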