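#' Classify the immunoediting phase
#'
#' Combines equilibrium analysis with trajectory simulation to label the
#' parameter configuration with one of the three immunoediting phases:
#' \describe{
#'   \item{elimination}{the tumour-free equilibrium E1 = (0, u/d) is locally
#'     stable and all test trajectories drive the tumour below the
#'     extinction threshold, sustained over the last tenth of the horizon.}
#'   \item{equilibrium}{trajectories settle on a stable internal
#'     equilibrium: tumour and immune cells coexist at fixed levels.}
#'   \item{escape}{neither of the above. Subcases reported: convergence to
#'     the immune-free boundary state (k, 0) (possible only in the
#'     l = u = 0 reduction); convergence to an immune-collapse state with
#'     the immune population at its treatment-sustained floor u/d (within
#'     5\%) and the tumour near its resource ceiling (x above 0.75 k) —
#'     the continuation of the (k, 0) attractor to l, u > 0; or sustained
#'     bounded oscillation of both populations.}
#' }
#'
#' @param params a \code{stoich_params} object.
#' @param closure quota closure.
#' @param starts optional matrix/list of initial states inside the
#'   trapezoid; defaults to a deterministic spread.
#' @param t_end simulation horizon (days).
#' @param extinction_threshold tumour biomass below which the tumour counts
#'   as eliminated (default 1e-6), required over the last 10\% of the
#'   horizon.
#' @param conv_tol amplitude below which the tail of a trajectory counts as
#'   converged to a point.
#' @return A \code{phase_report}: list with \code{phase}, \code{subcase},
#'   the E1 stability report, internal equilibria with verdicts, and
#'   per-start outcomes.
#' @export
classify_phase <- function(params, closure = c("qss", "lke"),
                           starts = NULL, t_end = 2000,
                           extinction_threshold = 1e-6,
                           conv_tol = 1e-4) {
  closure <- match.arg(closure)
  g <- trapezoid_spec(params)
  if (is.null(starts)) {
    fr <- c(0.15, 0.4, 0.7)
    starts <- do.call(rbind, lapply(fr, function(tx)
      cbind(tx * g$k, fr * (g$p - g$s * tx * g$k) * 0.9)))
    starts <- starts[c(1, 5, 9, 3, 7), , drop = FALSE]
  }
  if (is.list(starts)) starts <- do.call(rbind, starts)
  E1 <- boundary_equilibrium(params)
  E1_rep <- classify_equilibrium("continuous", E1, params, closure)
  eqs <- find_equilibria(params, closure, grid_density = 25,
                         include_boundary = FALSE)
  eq_reps <- lapply(eqs, function(e)
    classify_equilibrium("continuous", e, params, closure))
  n_tail <- 0.1
  outcomes <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    tr <- tryCatch(
      simulate_model(starts[i, ], t_end, params, closure,
                     times = seq(0, t_end, length.out = 2001L)),
      error = function(e) NULL)
    if (is.null(tr)) {
      outcomes[[i]] <- list(kind = "failed")
      next
    }
    tail_idx <- tr$t >= (1 - n_tail) * t_end
    xt <- tr$x[tail_idx]; yt <- tr$y[tail_idx]
    amp <- max(max(xt) - min(xt), max(yt) - min(yt))
    extinct <- all(xt < extinction_threshold)
    converged <- amp < conv_tol
    final <- c(x = tr$x[nrow(tr)], y = tr$y[nrow(tr)])
    floor_y <- params$u / params$d
    kind <- if (extinct) "tumour-extinct"
    else if (converged && final[["y"]] < extinction_threshold)
      "immune-free point"
    else if (converged &&
             final[["y"]] <= floor_y * 1.05 + extinction_threshold &&
             final[["x"]] >= 0.75 * g$k)
      "immune-floor point"
    else if (converged) "internal point"
    else "oscillation"
    outcomes[[i]] <- list(kind = kind, final = final, amplitude = amp)
  }
  kinds <- vapply(outcomes, `[[`, character(1), "kind")
  stable_internal <- any(vapply(eq_reps, function(r)
    r$kind == "internal" && r$stable, logical(1)))
  if (any(kinds == "failed")) {
    phase <- "inconclusive"; subcase <- "simulation failure"
  } else if (E1_rep$stable && all(kinds == "tumour-extinct")) {
    phase <- "elimination"; subcase <- "E1 absorbing"
  } else if (all(kinds == "internal point") &&
             (stable_internal || length(eq_reps) == 0)) {
    phase <- "equilibrium"; subcase <- "stable internal coexistence"
  } else if (all(kinds == "immune-free point") &&
             params$l == 0 && params$u == 0) {
    phase <- "escape"; subcase <- "boundary attractor (k, 0)"
  } else if (all(kinds == "immune-floor point")) {
    phase <- "escape"
    subcase <- "immune collapse (treatment-sustained floor, tumour near capacity)"
  } else if (any(kinds == "oscillation") &&
             all(kinds %in% c("oscillation", "internal point"))) {
    phase <- "escape"; subcase <- "oscillatory coexistence"
  } else if (all(kinds == "internal point")) {
    phase <- "equilibrium"; subcase <- "point coexistence"
  } else {
    phase <- "inconclusive"; subcase <- paste(unique(kinds),
                                              collapse = "+")
  }
  structure(list(phase = phase, subcase = subcase, E1 = E1_rep,
                 internal = eq_reps, outcomes = outcomes,
                 starts = starts, t_end = t_end,
                 extinction_threshold = extinction_threshold),
            class = "phase_report")
}

#' @export
print.phase_report <- function(x, ...) {
  cat("Immunoediting phase:", x$phase, "(", x$subcase, ")\n")
  cat("E1 = (0, u/d):", x$E1$verdict, "\n")
  if (length(x$internal))
    for (r in x$internal)
      cat(sprintf("internal E2 at (%.5g, %.5g): %s\n", r$x, r$y,
                  r$verdict))
  else cat("no internal equilibrium located\n")
  invisible(x)
}

#' Scan the (u, K_t) plane for immunoediting phases
#'
#' Classifies the phase on a grid of treatment influx and total potassium
#' values; used to show all three phases are realized and to recover the
#' stability thresholds of the tumour-free state empirically.
#'
#' @param params base parameter set (its u and K_t are overridden).
#' @param u_values,K_t_values grid values.
#' @param closure quota closure.
#' @param ... passed to [classify_phase()].
#' @return A data frame with columns u, K_t, phase, subcase,
#'   E1_eigenvalue (the nontrivial eigenvalue of the tumour-free state).
#' @export
phase_scan <- function(params, u_values, K_t_values,
                       closure = c("qss", "lke"), ...) {
  closure <- match.arg(closure)
  out <- list()
  for (u in u_values) for (K_t in K_t_values) {
    q <- params; q$u <- u; q$K_t <- K_t
    if (q$theta * u / q$d >= K_t) {
      out[[length(out) + 1L]] <- data.frame(
        u = u, K_t = K_t, phase = "infeasible", subcase = "theta*u/d >= K_t",
        E1_eigenvalue = NA_real_)
      next
    }
    rep <- tryCatch(classify_phase(q, closure, ...),
                    error = function(e) NULL)
    lam <- tumour_growth_factor(0, u / q$d, q, closure) -
      q$c / q$a * u / q$d
    out[[length(out) + 1L]] <- data.frame(
      u = u, K_t = K_t,
      phase = if (is.null(rep)) "error" else rep$phase,
      subcase = if (is.null(rep)) "" else rep$subcase,
      E1_eigenvalue = as.numeric(lam))
  }
  do.call(rbind, out)
}
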