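# Per-capita rates of the continuous model, frozen at (x, y). These are the
# exponents of the discrete analogue: the map advances one day with the
# rates held constant, so x' = x e^gx, y' = y e^gy.
percapita_rates <- function(x, y, params, closure) {
  x <- unname(x); y <- unname(y)
  qt <- quota_terms(x, y, params, closure)
  P <- params$c / (params$a + x)                  # f(x)/x, P(0) = f'(0)
  fx <- params$c * x / (params$a + x)
  phi <- params$b * min(1 - x / params$L, 1 - qt$w)
  eff <- params$e * min(1, qt$v)
  gx <- phi - P * y
  gy <- eff * fx - params$l * x - params$d + if (y > 0) params$u / y else 0
  c(gx = gx, gy = gy)
}

#' One step of the discrete analogue
#'
#' The discrete-time analogue of the continuous model assumes the per-capita
#' growth rates change only at integer times; integrating over one unit
#' interval gives the exponential map
#' \deqn{x' = x exp(g_x),  y' = y exp(g_y)}
#' with g_x = b min(1 - x/L, 1 - q/Q) - P(x) y and
#' g_y = e min(1, Q/theta) f(x) - l x - d + u/y, where P(x) = f(x)/x
#' (continuously extended by P(0) = f'(0)). Fixed points coincide exactly
#' with the equilibria of the continuous model.
#'
#' With \code{influx = "exact"} the constant influx u is instead integrated
#' exactly against the frozen linear part g = g_y - u/y, giving
#' y' = y e^g + u (e^g - 1)/g; this variant shares the same fixed points.
#'
#' @param x,y current state; y must be positive when u > 0 (the frozen
#'   per-capita influx u/y is otherwise undefined).
#' @param params a \code{stoich_params} object.
#' @param closure quota closure, "qss" (default) or "lke".
#' @param influx "frozen" (default) or "exact".
#' @param cap exponent magnitude cap; |g| above it is clamped with a
#'   diagnostic attribute \code{"capped"} (chaotic sweeps can transiently
#'   produce huge rates).
#' @return Named numeric \code{c(x, y)} for the next iterate.
#' @export
map_step <- function(x, y, params, closure = c("qss", "lke"),
                     influx = c("frozen", "exact"), cap = 50) {
  closure <- match.arg(closure)
  influx <- match.arg(influx)
  check_feasible(x, y, params)
  if (y == 0 && params$u > 0 && influx == "frozen")
    stop("y = 0 with u > 0: frozen per-capita influx u/y is undefined")
  capped <- FALSE
  clamp <- function(g) {
    if (abs(g) > cap) { capped <<- TRUE; sign(g) * cap } else g
  }
  if (influx == "frozen") {
    g <- percapita_rates(x, y, params, closure)
    out <- c(x = x * exp(clamp(g[["gx"]])), y = y * exp(clamp(g[["gy"]])))
  } else {
    g <- percapita_rates(x, y, params, closure)
    glin <- g[["gy"]] - if (y > 0) params$u / y else 0
    glin <- clamp(glin)
    ynew <- if (abs(glin) > 1e-12)
      y * exp(glin) + params$u * (exp(glin) - 1) / glin
    else y * exp(glin) + params$u
    out <- c(x = x * exp(clamp(g[["gx"]])), y = ynew)
  }
  if (capped) attr(out, "capped") <- TRUE
  out
}

#' Iterate the discrete map
#'
#' @param state0 numeric \code{c(x, y)} start.
#' @param N number of iterates to produce (orbit has N + 1 rows incl. the
#'   start).
#' @param burn_in first \code{burn_in} iterates flagged as transient.
#' @inheritParams map_step
#' @return A \code{stoich_orbit}: data frame with columns n, x, y,
#'   transient; attributes carry the parameter snapshot and a count of
#'   capped exponents.
#' @examples
#' p <- reference_parameters(L = 1.6, l = 0.009, u = 0.02)
#' ob <- map_orbit(c(0.3, 0.3), 200, burn_in = 100, params = p)
#' @export
map_orbit <- function(state0, N, burn_in = 0, params,
                      closure = c("qss", "lke"),
                      influx = c("frozen", "exact"), cap = 50) {
  closure <- match.arg(closure)
  influx <- match.arg(influx)
  if (!(N > burn_in) || burn_in < 0) stop("need N > burn_in >= 0")
  xs <- numeric(N + 1); ys <- numeric(N + 1)
  xs[1] <- state0[1]; ys[1] <- state0[2]
  ncapped <- 0L
  for (n in seq_len(N)) {
    st <- tryCatch(
      map_step(xs[n], ys[n], params, closure, influx, cap),
      error = function(e)
        stop("map_step failed at iterate ", n, ": ", conditionMessage(e),
             call. = FALSE))
    if (isTRUE(attr(st, "capped"))) ncapped <- ncapped + 1L
    xs[n + 1] <- st[["x"]]; ys[n + 1] <- st[["y"]]
  }
  structure(
    data.frame(n = 0:N, x = xs, y = ys,
               transient = c(TRUE, seq_len(N) <= burn_in)),
    class = c("stoich_orbit", "data.frame"),
    params = params, closure = closure, influx = influx,
    burn_in = burn_in, capped = ncapped)
}

#' @export
print.stoich_orbit <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Discrete orbit: %d iterates (%d transient), closure = %s\n",
              n - 1, attr(x, "burn_in"), attr(x, "closure")))
  cat(sprintf("final iterate: x = %.6g, y = %.6g\n", x$x[n], x$y[n]))
  if (attr(x, "capped") > 0)
    cat("capped exponents:", attr(x, "capped"), "\n")
  invisible(x)
}

#' @export
plot.stoich_orbit <- function(x, ...) {
  post <- x[!x$transient, ]
  graphics::plot(post$x, post$y, pch = 20, cex = 0.4, xlab = "tumour x",
                 ylab = "immune y", ...)
  invisible(x)
}

#' Export an orbit as CSV
#' @param orbit a \code{stoich_orbit}.
#' @param path output path.
#' @export
write_orbit <- function(orbit, path) {
  utils::write.csv(as.data.frame(orbit), path, row.names = FALSE)
  invisible(path)
}

#' Composed refined map
#'
#' Re-derives the exponential map with rates frozen over steps of length
#' 1/m and composes m of them; as m grows this converges to the time-1 flow
#' of the continuous model. Used to verify one-step consistency.
#'
#' @param x,y state.
#' @param m number of substeps.
#' @inheritParams map_step
#' @return \code{c(x, y)} after time 1.
#' @export
map_step_refined <- function(x, y, m, params, closure = c("qss", "lke")) {
  closure <- match.arg(closure)
  for (i in seq_len(m)) {
    g <- percapita_rates(x, y, params, closure)
    x <- x * exp(g[["gx"]] / m)
    y <- y * exp(g[["gy"]] / m)
  }
  c(x = x, y = y)
}
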