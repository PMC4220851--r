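#' Tumour potassium quota
#'
#' The tumour cell's potassium:carbon quota Q implied by the closed potassium
#' budget K_t = Q x + theta y + K_f. Two closures are provided:
#' \describe{
#'   \item{qss}{quasi-steady-state of the quota kinetics
#'     dQ/dt = alpha K_f - mu_m (1 - q/Q) Q, giving
#'     Q = (q mu_m/alpha + K_t - theta y) / (mu_m/alpha + x). Defined for
#'     x >= 0.}
#'   \item{lke}{the limiting form alpha -> Inf, in which all non-immune
#'     potassium sits in the tumour pool: Q = (K_t - theta y)/x. At x = 0 it
#'     returns +Inf so that quota-limited factors saturate continuously.}
#' }
#'
#' @param x tumour biomass (>= 0).
#' @param y immune biomass (>= 0); feasibility requires theta*y < K_t.
#' @param params a \code{stoich_params} object.
#' @param closure "qss" (default) or "lke".
#' @return The quota Q (vectorized over x, y).
#' @export
quota <- function(x, y, params, closure = c("qss", "lke")) {
  closure <- match.arg(closure)
  x <- unname(x); y <- unname(y)
  check_feasible(x, y, params)
  if (closure == "qss") {
    m <- params$mu_m / params$alpha
    (params$q * m + params$K_t - params$theta * y) / (m + x)
  } else {
    ifelse(x > 0, (params$K_t - params$theta * y) / x, Inf)
  }
}

check_feasible <- function(x, y, params, tol = 0) {
  if (any(x < 0) || any(y < 0))
    stop("infeasible state: negative biomass")
  if (any(params$theta * y - params$K_t > tol))
    stop("infeasible state: theta*y >= K_t (immune potassium demand ",
         "exceeds the total pool)")
  invisible(TRUE)
}

# q/Q and Q/theta with their partials, written so the lke x -> 0 limit needs
# no Inf arithmetic. Returns list(w, w_x, w_y, v, v_x, v_y).
quota_terms <- function(x, y, params, closure) {
  th <- params$theta
  if (closure == "qss") {
    m <- params$mu_m / params$alpha
    den <- params$q * m + params$K_t - th * y     # > 0 when feasible
    w <- params$q * (m + x) / den                 # q/Q
    w_x <- params$q / den
    w_y <- params$q * (m + x) * th / den^2
    v <- den / (th * (m + x))                     # Q/theta
    v_x <- -v / (m + x)
    v_y <- -1 / (m + x)
  } else {
    den <- params$K_t - th * y
    w <- params$q * x / den
    w_x <- params$q / den
    w_y <- params$q * x * th / den^2
    if (x > 0) {
      v <- den / (th * x)
      v_x <- -v / x
      v_y <- -1 / x
    } else {                                      # continuous extension
      v <- Inf; v_x <- 0; v_y <- 0
    }
  }
  list(w = w, w_x = w_x, w_y = w_y, v = v, v_x = v_x, v_y = v_y)
}

#' Per-capita tumour growth factor
#'
#' Liebig's minimum over the carbon-limited (logistic) and potassium-limited
#' (Droop) per-capita rates: b * min(1 - x/L, 1 - q/Q(x,y)). The potassium
#' branch vanishes exactly where q x = K_t - theta y.
#'
#' @inheritParams quota
#' @return Per-capita growth rate (per day), with attribute
#'   \code{"branch"} in \{"carbon", "potassium"\}.
#' @export
tumour_growth_factor <- function(x, y, params, closure = c("qss", "lke")) {
  closure <- match.arg(closure)
  check_feasible(x, y, params)
  qt <- quota_terms(x, y, params, closure)
  carbon <- 1 - x / params$L
  potassium <- 1 - qt$w
  branch <- if (carbon <= potassium) "carbon" else "potassium"
  structure(params$b * min(carbon, potassium), branch = branch)
}

#' Immune recruitment efficiency
#'
#' e * min(1, Q/theta): recruitment proceeds at the full efficiency e while
#' the tumour is potassium-rich (Q >= theta) and is reduced proportionally
#' to Q/theta when the tumour is potassium-poor.
#'
#' @inheritParams quota
#' @return Dimensionless multiplier in (0, e], with attribute
#'   \code{"branch"} in \{"rich", "poor"\}.
#' @export
recruitment_efficiency <- function(x, y, params, closure = c("qss", "lke")) {
  closure <- match.arg(closure)
  check_feasible(x, y, params)
  qt <- quota_terms(x, y, params, closure)
  branch <- if (qt$v >= 1) "rich" else "poor"
  structure(params$e * min(1, qt$v), branch = branch)
}

#' Continuous model right-hand side
#'
#' The vector field of the stoichiometric tumour-immune system:
#' \deqn{dx/dt = b x min(1 - x/L, 1 - q/Q) - f(x) y}
#' \deqn{dy/dt = e min(1, Q/theta) f(x) y - l x y - d y + u}
#' with f the Monod functional response encoded in \code{params}.
#'
#' @inheritParams quota
#' @param detail if TRUE, attach Q, free potassium K_f and the active
#'   branches as attributes.
#' @return Named numeric \code{c(dx, dy)}.
#' @export
model_rhs <- function(x, y, params, closure = c("qss", "lke"),
                      detail = FALSE) {
  closure <- match.arg(closure)
  check_feasible(x, y, params)
  rhs_core(x, y, params, closure, detail)
}

rhs_core <- function(x, y, params, closure, detail = FALSE) {
  x <- unname(x); y <- unname(y)
  qt <- quota_terms(x, y, params, closure)
  fx <- params$c * x / (params$a + x)
  carbon <- 1 - x / params$L
  potassium <- 1 - qt$w
  phi <- params$b * min(carbon, potassium)
  eff <- params$e * min(1, qt$v)
  dx <- phi * x - fx * y
  dy <- eff * fx * y - params$l * x * y - params$d * y + params$u
  out <- c(dx = dx, dy = dy)
  if (detail) {
    Q <- if (closure == "qss") {
      m <- params$mu_m / params$alpha
      (params$q * m + params$K_t - params$theta * y) / (m + x)
    } else if (x > 0) (params$K_t - params$theta * y) / x else Inf
    K_f <- if (is.finite(Q)) params$K_t - Q * x - params$theta * y else 0
    attr(out, "Q") <- Q
    attr(out, "K_f") <- K_f
    attr(out, "limiting_branch") <-
      if (carbon <= potassium) "carbon" else "potassium"
    attr(out, "efficiency_branch") <- if (qt$v >= 1) "rich" else "poor"
  }
  out
}

#' Right-hand side in the scaled (theta-free) gauge
#'
#' Evaluates the same vector field from \code{scaled_params}, using only
#' p = K_t/theta and s = q/theta: q/Q = s (m + x)/(s m + p - y) under qss
#' and s x/(p - y) under lke, and Q/theta likewise. Used to verify that the
#' theta-gauge is unobservable.
#'
#' @param x,y state.
#' @param scaled a \code{scaled_params} object.
#' @param closure "qss" or "lke".
#' @return Named numeric \code{c(dx, dy)}.
#' @export
model_rhs_scaled <- function(x, y, scaled, closure = c("qss", "lke")) {
  closure <- match.arg(closure)
  if (y >= scaled$p) stop("infeasible state: y >= p")
  if (closure == "qss") {
    m <- scaled$mu_m / scaled$alpha
    w <- scaled$s * (m + x) / (scaled$s * m + scaled$p - y)
    v <- (scaled$s * m + scaled$p - y) / (m + x)   # Q/theta
  } else {
    w <- if (x > 0) scaled$s * x / (scaled$p - y) else 0
    v <- if (x > 0) (scaled$p - y) / x else Inf
  }
  fx <- scaled$c * x / (scaled$a + x)
  phi <- scaled$b * min(1 - x / scaled$L, 1 - w)
  eff <- scaled$e * min(1, v)
  c(dx = phi * x - fx * y,
    dy = eff * fx * y - scaled$l * x * y - scaled$d * y + scaled$u)
}

#' Simulate the continuous model
#'
#' Adaptive-step integration (deSolve, lsoda) of the model vector field. The
#' right-hand side is continuous with kinks at the two switch surfaces
#' (carbon vs potassium limitation; Q = theta); crossings are detected post
#' hoc by monitoring the active branch at the output points. Components more
#' negative than -atol stop the run; negative components within tolerance
#' are clipped to zero and counted.
#'
#' @param state0 numeric \code{c(x, y)}, feasible (theta*y < K_t).
#' @param t_end final time (days).
#' @param params a \code{stoich_params} object.
#' @param closure quota closure, "qss" (default) or "lke".
#' @param times output time grid; default 1001 points over [0, t_end].
#' @param rtol,atol solver tolerances.
#' @return A \code{stoich_trajectory}: data frame with columns t, x, y, Q,
#'   K_f, limiting_branch, efficiency_branch, plus solver metadata
#'   attributes (\code{switch_crossings}, \code{clipped}).
#' @examples
#' p <- reference_parameters(L = 1.0, l = 0.2, u = 0.05, K_t = 0.045)
#' tr <- simulate_model(c(0.3, 0.3), 100, p)
#' tail(as.data.frame(tr))
#' @export
simulate_model <- function(state0, t_end, params,
                           closure = c("qss", "lke"), times = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  closure <- match.arg(closure)
  if (t_end <= 0) stop("t_end must be positive")
  check_feasible(state0[1], state0[2], params)
  if (is.null(times)) times <- seq(0, t_end, length.out = 1001L)
  slack <- 1e-8 * params$K_t + 1e-12
  func <- function(t, state, parms) {
    x <- max(state[1], 0); y <- state[2]
    if (params$theta * y - params$K_t > slack)
      stop("trajectory left the feasible region (theta*y >= K_t) at t = ",
           signif(t, 6))
    y <- min(max(y, 0), (params$K_t - slack) / params$theta)
    list(rhs_core(x, y, params, closure))
  }
  sol <- deSolve::ode(y = c(x = state0[1], y = state0[2]), times = times,
                      func = func, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol, maxsteps = 100000L)
  sol <- as.data.frame(sol)
  if (nrow(sol) < length(times))
    stop("solver stopped early at t = ", signif(max(sol[[1]]), 6),
         "; last accepted state (", signif(sol[nrow(sol), 2], 6), ", ",
         signif(sol[nrow(sol), 3], 6), ")")
  names(sol) <- c("t", "x", "y")
  neg <- (sol$x < 0 & sol$x > -1e3 * atol) |
         (sol$y < 0 & sol$y > -1e3 * atol)
  clipped <- sum(neg)
  sol$x <- pmax(sol$x, 0)
  sol$y <- pmax(sol$y, 0)
  det <- lapply(seq_len(nrow(sol)), function(i)
    rhs_core(sol$x[i], sol$y[i], params, closure, detail = TRUE))
  sol$Q <- vapply(det, attr, numeric(1), "Q")
  sol$K_f <- vapply(det, attr, numeric(1), "K_f")
  sol$limiting_branch <- vapply(det, attr, character(1), "limiting_branch")
  sol$efficiency_branch <- vapply(det, attr, character(1),
                                  "efficiency_branch")
  crossings <- sum(sol$limiting_branch[-1] != sol$limiting_branch[-nrow(sol)]) +
    sum(sol$efficiency_branch[-1] != sol$efficiency_branch[-nrow(sol)])
  structure(sol, class = c("stoich_trajectory", "data.frame"),
            params = params, closure = closure,
            rtol = rtol, atol = atol,
            switch_crossings = crossings, clipped = clipped)
}

#' @export
print.stoich_trajectory <- function(x, ...) {
  cat(sprintf(
    "Continuous trajectory: %d points, t in [%g, %g], closure = %s\n",
    nrow(x), min(x$t), max(x$t), attr(x, "closure")))
  cat(sprintf("final state: x = %.6g, y = %.6g\n",
              x$x[nrow(x)], x$y[nrow(x)]))
  cat(sprintf("switch crossings observed: %d; clipped points: %d\n",
              attr(x, "switch_crossings"), attr(x, "clipped")))
  invisible(x)
}

#' @export
plot.stoich_trajectory <- function(x, which = c("time", "phase"), ...) {
  which <- match.arg(which)
  if (which == "time") {
    graphics::matplot(x$t, cbind(x$x, x$y), type = "l", lty = 1,
                      col = c("firebrick", "steelblue"),
                      xlab = "time (days)", ylab = "biomass (C units)", ...)
    graphics::legend("topright", c("tumour x", "immune y"), lty = 1,
                     col = c("firebrick", "steelblue"), bty = "n")
  } else {
    graphics::plot(x$x, x$y, type = "l", xlab = "tumour x",
                   ylab = "immune y", ...)
  }
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Columns: t, x, y, Q, K_f, limiting_branch, efficiency_branch.
#' @param traj a \code{stoich_trajectory}.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
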