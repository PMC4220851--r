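# Analytic partial derivatives of the continuous vector field (F, G) at an
# off-switch state. branch overrides allow one-sided derivatives on the two
# switch surfaces (Liebig min; Q = theta).
cont_partials <- function(x, y, params, closure,
                          g_branch = NULL, e_branch = NULL) {
  qt <- quota_terms(x, y, params, closure)
  a <- params$a; cc <- params$c
  fx <- cc * x / (a + x)
  dfx <- cc * a / (a + x)^2
  carbon <- 1 - x / params$L
  potassium <- 1 - qt$w
  if (is.null(g_branch))
    g_branch <- if (carbon <= potassium) "carbon" else "potassium"
  if (is.null(e_branch))
    e_branch <- if (qt$v >= 1) "rich" else "poor"
  if (g_branch == "carbon") {
    phi <- params$b * carbon; phi_x <- -params$b / params$L; phi_y <- 0
  } else {
    phi <- params$b * potassium
    phi_x <- -params$b * qt$w_x
    phi_y <- -params$b * qt$w_y
  }
  if (e_branch == "rich") {
    eff <- params$e; eff_x <- 0; eff_y <- 0
  } else {
    eff <- params$e * qt$v
    eff_x <- params$e * qt$v_x
    eff_y <- params$e * qt$v_y
  }
  list(
    F_x = phi + x * phi_x - dfx * y,
    F_y = x * phi_y - fx,
    G_x = eff_x * fx * y + eff * dfx * y - params$l * y,
    G_y = eff_y * fx * y + eff * fx - params$l * x - params$d,
    phi = phi, phi_x = phi_x, phi_y = phi_y,
    eff = eff, eff_x = eff_x, eff_y = eff_y,
    fx = fx, dfx = dfx,
    g_branch = g_branch, e_branch = e_branch,
    on_switch = abs(carbon - potassium) < 1e-12 ||
      (is.finite(qt$v) && abs(qt$v - 1) < 1e-12))
}

#' Model Jacobian
#'
#' Analytic Jacobian of the continuous vector field (F, G) or of the
#' discrete map (R, S) at a state. On a switch surface (Liebig branch tie
#' or Q = theta) the matrix is one-sided; the attribute \code{"on_switch"}
#' flags this and \code{"one_sided"} carries the matrices for the four
#' branch combinations.
#'
#' @param model "continuous" or "discrete".
#' @param x,y evaluation state (feasible).
#' @param params a \code{stoich_params} object.
#' @param closure quota closure.
#' @return A 2x2 matrix with dimnames over \code{c("x","y")}.
#' @export
model_jacobian <- function(model = c("continuous", "discrete"), x, y,
                           params, closure = c("qss", "lke")) {
  model <- match.arg(model)
  closure <- match.arg(closure)
  check_feasible(x, y, params)
  build <- function(gb, eb) {
    pp <- cont_partials(x, y, params, closure, gb, eb)
    if (model == "continuous") {
      J <- matrix(c(pp$F_x, pp$F_y, pp$G_x, pp$G_y), 2, 2, byrow = TRUE)
    } else {
      P <- params$c / (params$a + x)
      dP <- -params$c / (params$a + x)^2
      gx <- pp$phi - P * y
      gy <- pp$eff * pp$fx - params$l * x - params$d +
        if (y > 0) params$u / y else 0
      gx_x <- pp$phi_x - dP * y
      gx_y <- pp$phi_y - P
      gy_x <- pp$eff_x * pp$fx + pp$eff * pp$dfx - params$l
      gy_y <- pp$eff_y * pp$fx - if (y > 0) params$u / y^2 else 0
      J <- matrix(c(exp(gx) * (1 + x * gx_x), exp(gx) * x * gx_y,
                    exp(gy) * y * gy_x, exp(gy) * (1 + y * gy_y)),
                  2, 2, byrow = TRUE)
    }
    dimnames(J) <- list(c("x", "y"), c("x", "y"))
    J
  }
  pp0 <- cont_partials(x, y, params, closure)
  J <- build(pp0$g_branch, pp0$e_branch)
  if (pp0$on_switch) {
    sides <- list()
    for (gb in c("carbon", "potassium")) for (eb in c("rich", "poor"))
      sides[[paste(gb, eb, sep = "/")]] <- build(gb, eb)
    attr(J, "one_sided") <- sides
    attr(J, "on_switch") <- TRUE
  } else attr(J, "on_switch") <- FALSE
  J
}

#' Central-difference Jacobian (numerical cross-check)
#'
#' @inheritParams model_jacobian
#' @param h relative step.
#' @return 2x2 matrix.
#' @export
numeric_jacobian <- function(model = c("continuous", "discrete"), x, y,
                             params, closure = c("qss", "lke"),
                             h = 1e-6) {
  model <- match.arg(model)
  closure <- match.arg(closure)
  fn <- if (model == "continuous")
    function(s) unname(model_rhs(s[1], s[2], params, closure))
  else
    function(s) unname(map_step(s[1], s[2], params, closure))
  s0 <- c(x, y)
  J <- matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  for (j in 1:2) {
    hj <- h * max(1, abs(s0[j]))
    sp <- s0; sp[j] <- sp[j] + hj
    sm <- s0; sm[j] <- sm[j] - hj
    if (sm[j] < 0) { sm[j] <- 0; hj2 <- sp[j] - sm[j] } else hj2 <- 2 * hj
    J[, j] <- (fn(sp) - fn(sm)) / hj2
  }
  J
}

#' Jury stability test for a 2x2 matrix
#'
#' Both characteristic roots of M have magnitude less than 1 iff
#' |tr M| < 1 + det M < 2.
#'
#' @param M a 2x2 numeric matrix.
#' @return Logical with attributes \code{tr} and \code{det}.
#' @export
jury_stable <- function(M) {
  tr <- M[1, 1] + M[2, 2]
  de <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  structure(abs(tr) < 1 + de && 1 + de < 2, tr = tr, det = de)
}

#' Boundary equilibrium
#'
#' The model has the unique boundary equilibrium E1 = (0, u/d): with no
#' tumour, the immune pool balances the treatment influx against apoptosis.
#' When u = 0 this coincides with the extinction state (0, 0).
#'
#' @param params a \code{stoich_params} object.
#' @return A \code{stoich_equilibrium} at (0, u/d); \code{$feasible} is
#'   FALSE if theta*u/d >= K_t (the immune pool would exhaust the total
#'   potassium).
#' @export
boundary_equilibrium <- function(params) {
  y <- params$u / params$d
  feas <- params$theta * y < params$K_t
  new_equilibrium(0, y, params, kind = "boundary", feasible = feas)
}

new_equilibrium <- function(x, y, params, kind, closure = "qss",
                            feasible = TRUE) {
  res_c <- if (feasible) model_rhs(x, y, params, closure) else c(NA, NA)
  res_d <- if (feasible && (y > 0 || params$u == 0)) {
    st <- map_step(x, y, params, closure)
    c(st[["x"]] - x, st[["y"]] - y)
  } else c(NA, NA)
  structure(list(x = x, y = y, kind = kind, closure = closure,
                 feasible = feasible,
                 residual_continuous = sqrt(sum(res_c^2)),
                 residual_discrete = sqrt(sum(res_d^2))),
            class = "stoich_equilibrium")
}

#' @export
print.stoich_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium at (x, y) = (%.8g, %.8g)%s\n", x$kind,
              x$x, x$y, if (x$feasible) "" else " [infeasible]"))
  cat(sprintf("residuals: continuous %.3g, discrete %.3g\n",
              x$residual_continuous, x$residual_discrete))
  invisible(x)
}

# Damped Newton for a 2D root of fun with analytic jacobian jac.
newton2 <- function(start, fun, jac, tol = 1e-12, maxit = 60) {
  s <- start
  r <- fun(s)
  if (any(!is.finite(r))) return(NULL)
  for (it in seq_len(maxit)) {
    if (sqrt(sum(r^2)) < tol) return(list(root = s, res = sqrt(sum(r^2))))
    J <- jac(s)
    if (any(!is.finite(J)) || abs(det(J)) < 1e-300) return(NULL)
    step <- tryCatch(solve(J, r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      s_new <- s - lam * step
      r_new <- tryCatch(fun(s_new), error = function(e) NULL)
      if (!is.null(r_new) && all(is.finite(r_new)) &&
          sqrt(sum(r_new^2)) < sqrt(sum(r^2))) break
      lam <- lam / 2
      if (lam < 1e-10) return(NULL)
    }
    s <- s_new; r <- r_new
  }
  if (sqrt(sum(r^2)) < tol) list(root = s, res = sqrt(sum(r^2))) else NULL
}

#' Locate internal equilibria
#'
#' Seeds a damped Newton root solve of the chosen system — the continuous
#' vector field (F, G) or the discrete fixed-point residual (R - x, S - y)
#' — from a dense grid over the invariant trapezoid, deduplicates the roots
#' and reports both models' residuals for each. Both systems share their
#' equilibria; solving either gives the same set.
#'
#' @param params a \code{stoich_params} object.
#' @param closure quota closure.
#' @param model which residual to solve, "continuous" (default) or
#'   "discrete".
#' @param grid_density seeds per axis over the trapezoid (default 50).
#' @param tol accepted residual norm (default 1e-10).
#' @param dedupe_radius roots closer than this are merged (default 1e-6).
#' @param include_boundary also return the boundary equilibria ((0, u/d);
#'   and (0, 0), (k, 0) in the l = u = 0 reduction).
#' @return A list of \code{stoich_equilibrium} objects (possibly only
#'   boundary ones; an empty internal set is a valid outcome).
#' @export
find_equilibria <- function(params, closure = c("qss", "lke"),
                            model = c("continuous", "discrete"),
                            grid_density = 50, tol = 1e-10,
                            dedupe_radius = 1e-6,
                            include_boundary = TRUE) {
  closure <- match.arg(closure)
  model <- match.arg(model)
  p <- params$K_t / params$theta
  s <- params$q / params$theta
  k <- min(params$L, if (s > 0) p / s else Inf)
  feas_y <- function(x) min(p - s * x, params$K_t / params$theta) *
    0.999999
  if (model == "continuous") {
    fun <- function(st) {
      if (st[1] <= 0 || st[2] <= 0 || params$theta * st[2] >= params$K_t)
        stop("outside domain")
      unname(model_rhs(st[1], st[2], params, closure))
    }
    jac <- function(st) unname(model_jacobian("continuous", st[1], st[2],
                                              params, closure))
  } else {
    fun <- function(st) {
      if (st[1] <= 0 || st[2] <= 0 || params$theta * st[2] >= params$K_t)
        stop("outside domain")
      nx <- map_step(st[1], st[2], params, closure)
      c(nx[["x"]] - st[1], nx[["y"]] - st[2])
    }
    jac <- function(st) {
      J <- model_jacobian("discrete", st[1], st[2], params, closure)
      unname(J) - diag(2)
    }
  }
  roots <- list()
  gx <- k * seq_len(grid_density) / (grid_density + 1)
  for (x0 in gx) {
    ytop <- feas_y(x0)
    if (ytop <= 0) next
    gy <- ytop * seq_len(grid_density) / (grid_density + 1)
    for (y0 in gy) {
      sol <- tryCatch(newton2(c(x0, y0), fun, jac, tol = tol),
                      error = function(e) NULL)
      if (is.null(sol)) next
      r <- sol$root
      if (r[1] <= dedupe_radius || r[2] <= dedupe_radius) next
      if (params$theta * r[2] >= params$K_t) next
      dup <- any(vapply(roots, function(z)
        sqrt((z[1] - r[1])^2 + (z[2] - r[2])^2) < dedupe_radius,
        logical(1)))
      if (!dup) roots[[length(roots) + 1L]] <- r
    }
  }
  out <- lapply(roots, function(r)
    new_equilibrium(r[1], r[2], params, kind = "internal",
                    closure = closure))
  # keep only roots whose residuals meet tol in both systems
  out <- Filter(function(eq) eq$residual_continuous < 1e2 * tol &&
                  eq$residual_discrete < 1e-6, out)
  if (include_boundary) {
    bnd <- list(boundary_equilibrium(params))
    if (params$l == 0 && params$u == 0) {
      bnd <- list(new_equilibrium(0, 0, params, "boundary", closure),
                  new_equilibrium(k, 0, params, "boundary", closure))
    }
    out <- c(bnd, out)
  }
  out
}

#' Region of the phase plane relative to the quota threshold
#'
#' Omega1 is the potassium-rich region (Q >= theta), Omega2 the
#' potassium-poor one (Q < theta). Under the lke closure and in scaled
#' coordinates the separating set is the line x + y = p.
#'
#' @param x,y positive-cone state.
#' @param params a \code{stoich_params} object.
#' @param closure quota closure.
#' @param tol half-width of the reported "boundary" band on Q/theta.
#' @return "Omega1", "Omega2" or "boundary".
#' @export
region_of <- function(x, y, params, closure = c("qss", "lke"),
                      tol = 1e-12) {
  closure <- match.arg(closure)
  qt <- quota_terms(x, y, params, closure)
  if (is.finite(qt$v) && abs(qt$v - 1) <= tol) return("boundary")
  if (qt$v >= 1) "Omega1" else "Omega2"
}

#' Classify the stability of an equilibrium
#'
#' Builds a stability report for the continuous model (eigenvalue real
#' parts; saddle iff det < 0) or the discrete map (Jury criterion
#' |tr| < 1 + det < 2, cross-checked against |eigenvalue|). The report
#' carries the nullcline slopes -F_x/F_y and -G_x/G_y, the quota region
#' (Omega1/Omega2) and flags for the nullcline-slope theorem clauses that
#' apply to internal equilibria: slope(G) < slope(F) forces a saddle
#' (continuous) or instability (discrete); slope(G) > slope(F) together
#' with the spectral condition gives local asymptotic stability.
#'
#' @param model "continuous" or "discrete".
#' @param eq a \code{stoich_equilibrium}, or numeric \code{c(x, y)}.
#' @param params a \code{stoich_params} object.
#' @param closure quota closure.
#' @param tol residual tolerance for accepting eq as an equilibrium.
#' @return A \code{stability_report}.
#' @export
classify_equilibrium <- function(model = c("continuous", "discrete"), eq,
                                 params, closure = c("qss", "lke"),
                                 tol = 1e-7) {
  model <- match.arg(model)
  closure <- match.arg(closure)
  if (inherits(eq, "stoich_equilibrium")) {
    x <- eq$x; y <- eq$y; kind <- eq$kind
  } else { x <- eq[1]; y <- eq[2]; kind <- if (x == 0) "boundary" else "internal" }
  res <- model_rhs(x, y, params, closure)
  if (sqrt(sum(res^2)) > tol)
    warning("point is not an equilibrium to tolerance (|rhs| = ",
            signif(sqrt(sum(res^2)), 3), ")", call. = FALSE)
  J <- model_jacobian(model, x, y, params, closure)
  ev <- eigen(unclass(J)[1:2, 1:2], only.values = TRUE)$values
  pp <- cont_partials(x, y, params, closure)
  slope_F <- if (abs(pp$F_y) > 0) -pp$F_x / pp$F_y else NA_real_
  slope_G <- if (abs(pp$G_y) > 0) -pp$G_x / pp$G_y else NA_real_
  hyst <- 1e-9
  if (model == "continuous") {
    re <- Re(ev)
    de <- Re(ev[1] * ev[2])
    verdict <- if (any(abs(re) < hyst)) "non-hyperbolic"
    else if (de < 0) "saddle"
    else if (all(re < 0)) {
      if (is.complex(ev) && any(abs(Im(ev)) > hyst)) "stable focus"
      else "stable node"
    } else {
      if (is.complex(ev) && any(abs(Im(ev)) > hyst)) "unstable focus"
      else "unstable node"
    }
    stable <- startsWith(verdict, "stable")
    jury <- NULL
  } else {
    mods <- Mod(ev)
    jury <- jury_stable(unclass(J)[1:2, 1:2])
    verdict <- if (any(abs(mods - 1) < hyst)) "non-hyperbolic"
    else if (all(mods < 1)) {
      if (is.complex(ev) && any(abs(Im(ev)) > hyst)) "stable focus"
      else "stable node"
    } else if (all(mods > 1)) {
      if (is.complex(ev) && any(abs(Im(ev)) > hyst)) "unstable focus"
      else "unstable node"
    } else "saddle"
    stable <- all(mods < 1)
    if (verdict != "non-hyperbolic" && isTRUE(jury) != stable)
      warning("Jury verdict disagrees with eigenvalue moduli",
              call. = FALSE)
  }
  flags <- character(0)
  if (kind == "internal" && is.finite(slope_F) && is.finite(slope_G)) {
    if (slope_G < slope_F)
      flags <- c(flags, if (model == "continuous")
        "slope(G)<slope(F): saddle clause" else
          "slope(G)<slope(F): unstable clause")
    else if (slope_G > slope_F && stable)
      flags <- c(flags, "slope(G)>slope(F): LAS clause")
  }
  structure(list(
    model = model, x = x, y = y, kind = kind,
    jacobian = J, eigenvalues = ev, verdict = verdict, stable = stable,
    jury = jury,
    nullcline_slope_F = slope_F, nullcline_slope_G = slope_G,
    region = region_of(x, y, params, closure),
    theorem_flags = flags,
    on_switch = isTRUE(attr(J, "on_switch")),
    partials = pp[c("F_x", "F_y", "G_x", "G_y")]
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("%s-model stability at (%.6g, %.6g) [%s, %s]\n", x$model,
              x$x, x$y, x$kind, x$region))
  cat("eigenvalues:", paste(format(x$eigenvalues, digits = 6),
                            collapse = ", "), "\n")
  cat("verdict:", x$verdict, "\n")
  if (!is.null(x$jury))
    cat(sprintf("Jury: |tr| = %.4g, 1 + det = %.4g -> %s\n",
                abs(attr(x$jury, "tr")), 1 + attr(x$jury, "det"),
                if (isTRUE(x$jury)) "stable" else "not stable"))
  cat(sprintf("nullcline slopes: tumour %.5g, immune %.5g\n",
              x$nullcline_slope_F, x$nullcline_slope_G))
  if (length(x$theorem_flags))
    cat("clauses:", paste(x$theorem_flags, collapse = "; "), "\n")
  if (x$on_switch) cat("note: equilibrium lies on a switch surface;",
                       "derivatives are one-sided\n")
  invisible(x)
}
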