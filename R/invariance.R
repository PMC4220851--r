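#' Invariant-region geometry
#'
#' The candidate forward-invariant set is the open trapezoid
#' Delta = \{0 < x < k, 0 < y, s x + y < p\} with k = min(L, p/s) (a
#' triangle when L >= p/s), where p = K_t/theta and s = q/theta. Its slant
#' edge s x + y = p is exactly the zero set of the free-potassium pool:
#' inside Delta the potassium mass balance K_c + K_i + K_f = K_t holds with
#' K_f >= 0.
#'
#' @param params a \code{stoich_params} object.
#' @return list(p, s, k, triangle).
#' @export
trapezoid_spec <- function(params) {
  p <- params$K_t / params$theta
  s <- params$q / params$theta
  k <- min(params$L, p / s)
  list(p = p, s = s, k = k, triangle = params$L >= p / s)
}

#' Boundary-flux audit of the invariant trapezoid
#'
#' Samples the boundary of Delta and evaluates the inward normal component
#' of the vector field at each sample: dy/dt on the bottom edge y = 0,
#' -dx/dt on the right edge x = k, and -(s dx/dt + dy/dt)/sqrt(s^2+1) on
#' the slant edge s x + y = p. The x = 0 axis is itself invariant
#' (dx/dt = 0 there) and is noted, not sampled. Interior samples audit the
#' sign of the free potassium pool K_f. The verdict is "invariant" only if
#' every boundary sample has nonnegative inward flux (up to tol) and every
#' interior sample has K_f >= 0.
#'
#' @param params a \code{stoich_params} object.
#' @param closure quota closure.
#' @param n_boundary samples per edge.
#' @param n_interior interior mass-balance samples.
#' @param tol margin tolerance.
#' @return An \code{invariance_report}.
#' @export
invariance_check <- function(params, closure = c("qss", "lke"),
                             n_boundary = 100, n_interior = 200,
                             tol = 1e-9) {
  closure <- match.arg(closure)
  g <- trapezoid_spec(params)
  if (g$s >= 1)
    warning("s >= 1: the trapezoid geometry is degenerate", call. = FALSE)
  eps <- 1e-9
  samp <- seq(eps, 1 - eps, length.out = n_boundary)
  rows <- list()
  flux_at <- function(x, y, edge, nx, ny) {
    d <- rhs_core(x, y, params, closure)
    data.frame(edge = edge, x = x, y = y,
               flux = nx * d[["dx"]] + ny * d[["dy"]])
  }
  # bottom edge y = 0, inward normal (0, 1)
  for (t in samp) rows[[length(rows) + 1L]] <-
    flux_at(t * g$k, 0, "bottom", 0, 1)
  # right edge x = k (absent in the triangle case), inward normal (-1, 0)
  if (!g$triangle) {
    ytop <- g$p - g$s * g$k
    for (t in samp) rows[[length(rows) + 1L]] <-
      flux_at(g$k, t * ytop, "right", -1, 0)
  }
  # slant edge s x + y = p, inward normal -(s, 1)/|.|
  nrm <- sqrt(g$s^2 + 1)
  for (t in samp) {
    x <- t * g$k
    y <- g$p - g$s * x
    if (y <= 0) next
    rows[[length(rows) + 1L]] <-
      flux_at(x, y, "slant", -g$s / nrm, -1 / nrm)
  }
  flux <- do.call(rbind, rows)
  # interior mass-balance audit
  ti <- seq(eps, 1 - eps, length.out = ceiling(sqrt(n_interior)))
  interior <- expand.grid(tx = ti, ty = ti)
  interior$x <- interior$tx * g$k
  interior$y <- interior$ty * (g$p - g$s * interior$x)
  interior$K_f <- vapply(seq_len(nrow(interior)), function(i) {
    d <- rhs_core(interior$x[i], interior$y[i], params, closure,
                  detail = TRUE)
    attr(d, "K_f")
  }, numeric(1))
  min_margin <- min(flux$flux)
  pool_ok <- all(interior$K_f >= -tol)
  structure(list(
    geometry = g, flux = flux, interior = interior[, c("x", "y", "K_f")],
    min_margin = min_margin, pool_ok = pool_ok,
    verdict = if (min_margin >= -tol && pool_ok) "invariant"
              else "violated",
    worst = flux[which.min(flux$flux), ],
    closure = closure
  ), class = "invariance_report")
}

#' @export
print.invariance_report <- function(x, ...) {
  g <- x$geometry
  cat(sprintf(
    "Invariance audit of Delta: k = %.6g, p = %.6g, s = %.6g (%s)\n",
    g$k, g$p, g$s, if (g$triangle) "triangle" else "trapezoid"))
  cat(sprintf("minimum inward flux: %.6g on edge '%s' at (%.4g, %.4g)\n",
              x$min_margin, x$worst$edge, x$worst$x, x$worst$y))
  cat("free-potassium pool nonnegative on interior samples:",
      x$pool_ok, "\n")
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}

#' Largest invariance-preserving influx
#'
#' Bisection on the treatment influx u for the largest value at which the
#' boundary-flux audit still reports the trapezoid invariant (all other
#' parameters fixed). This is the numerical counterpart of the analytic
#' bound on u under which solutions remain in Delta.
#'
#' @param params a \code{stoich_params} object (its u is ignored).
#' @param closure quota closure.
#' @param u_max upper bracket.
#' @param tol bisection tolerance on u.
#' @param n_boundary samples per edge for each audit.
#' @return The empirical threshold influx.
#' @export
max_invariant_influx <- function(params, closure = c("qss", "lke"),
                                 u_max = 10, tol = 1e-4,
                                 n_boundary = 60) {
  closure <- match.arg(closure)
  ok <- function(u) {
    q <- params; q$u <- u
    rep <- suppressWarnings(
      invariance_check(q, closure, n_boundary = n_boundary,
                       n_interior = 16))
    rep$verdict == "invariant"
  }
  if (!ok(0)) return(NA_real_)
  if (ok(u_max)) return(u_max)
  lo <- 0; hi <- u_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) lo <- mid else hi <- mid
  }
  lo
}
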