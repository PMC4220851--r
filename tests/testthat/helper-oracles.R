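# Independent oracles, coded directly from the model definitions and kept
# separate from the package internals they are used to check.

# Stoichiometric predator-prey (KHE) right-hand side: the l = u = 0 core,
# written out in plain arithmetic.
oracle_khe_rhs <- function(x, y, pars, closure = "qss") {
  Q <- if (closure == "qss") {
    (pars$q * pars$mu_m / pars$alpha + pars$K_t - pars$theta * y) /
      (pars$mu_m / pars$alpha + x)
  } else (pars$K_t - pars$theta * y) / x
  f <- pars$c * x / (pars$a + x)
  dx <- pars$b * x * min(1 - x / pars$L, 1 - pars$q / Q) - f * y
  dy <- pars$e * min(1, Q / pars$theta) * f * y - pars$d * y
  unname(c(dx, dy))
}

# Frozen-per-capita-rate exponential map, brute-force arithmetic.
oracle_map_step <- function(x, y, pars, closure = "qss") {
  Q <- if (closure == "qss") {
    (pars$q * pars$mu_m / pars$alpha + pars$K_t - pars$theta * y) /
      (pars$mu_m / pars$alpha + x)
  } else if (x > 0) (pars$K_t - pars$theta * y) / x else Inf
  gx <- pars$b * min(1 - x / pars$L, 1 - pars$q / Q) -
    (pars$c / (pars$a + x)) * y
  gy <- pars$e * min(1, Q / pars$theta) * pars$c * x / (pars$a + x) -
    pars$l * x - pars$d + if (y > 0) pars$u / y else 0
  unname(c(x * exp(gx), y * exp(gy)))
}

# Random parameter sets around the reference values (multiplicative jitter,
# kept in the regime q < theta, e <= 1).
rand_params <- function(seed) {
  set.seed(seed)
  jit <- function(v, w = 0.2) v * exp(stats::runif(1, -w, w))
  suppressWarnings(stoich_params(
    b = jit(1.2), L = stats::runif(1, 0.25, 2.0), K_t = jit(0.025),
    theta = jit(0.03), q = jit(0.0038), mu_m = jit(1.2),
    alpha = jit(10), e = min(1, jit(0.8)), d = jit(0.25),
    l = stats::runif(1, 0, 0.05), u = stats::runif(1, 0, 0.05),
    c = jit(0.81), a = jit(0.25)))
}

# Random feasible state strictly inside the trapezoid of pars.
rand_state <- function(pars, margin = 0.05) {
  p <- pars$K_t / pars$theta
  s <- pars$q / pars$theta
  k <- min(pars$L, p / s)
  x <- stats::runif(1, margin * k, (1 - margin) * k)
  ymax <- (p - s * x) * (1 - margin)
  y <- stats::runif(1, margin * ymax, ymax)
  c(x = x, y = y)
}

# Quadratic (logistic) test map and its derivative, for period/Lyapunov
# harness checks.
logistic_step <- function(r) function(x) r * x * (1 - x)
logistic_jac <- function(r) function(x) matrix(r * (1 - 2 * x), 1, 1)

table1 <- function(L = 1.0, ...) reference_parameters(L = L, ...)
fig1_params <- function(K_t = 0.045, L = 1.0)
  reference_parameters(L = L, l = 0.2, u = 0.05, K_t = K_t)
fig2_params <- function(b = 1.2)
  reference_parameters(L = 1.6, l = 0.009, u = 0.02, b = b)

# TRUE when the Liebig and efficiency branches are constant across the
# central-difference stencil at (x, y): finite differences are only a valid
# derivative check away from the switch-surface kinks.
stencil_off_switch <- function(pars, x, y, h = 1e-6) {
  br <- function(xx, yy) {
    d <- model_rhs(xx, yy, pars, detail = TRUE)
    paste(attr(d, "limiting_branch"), attr(d, "efficiency_branch"))
  }
  hx <- h * max(1, abs(x)); hy <- h * max(1, abs(y))
  b0 <- br(x, y)
  all(vapply(list(c(x + hx, y), c(max(x - hx, 0), y),
                  c(x, y + hy), c(x, max(y - hy, 0))),
             function(s) identical(br(s[1], s[2]), b0), logical(1)))
}
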