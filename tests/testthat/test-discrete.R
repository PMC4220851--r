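test_that("one step equals the brute-force frozen-rate oracle", {
  p <- fig1_params(K_t = 0.045, L = 1.0)
  got <- map_step(0.5, 0.2, p)
  want <- oracle_map_step(0.5, 0.2, p)
  expect_equal(unname(got), want, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:200) {
    st <- rand_state(p)
    for (cl in c("qss", "lke"))
      expect_equal(unname(map_step(st[1], st[2], p, cl)),
                   oracle_map_step(st[1], st[2], p, cl),
                   tolerance = 1e-12)
  }
})

test_that("with l = u = 0 the map coincides with the discrete KHE map", {
  set.seed(5)
  for (i in 1:5) {
    pars <- rand_params(i)
    pars$l <- 0; pars$u <- 0
    for (j in 1:200) {
      st <- rand_state(pars)
      expect_equal(unname(map_step(st[1], st[2], pars)),
                   oracle_map_step(st[1], st[2], pars),
                   tolerance = 1e-12)
    }
  }
})

test_that("continuous equilibria are exact fixed points of the map", {
  p <- fig1_params(K_t = 0.045, L = 1.0)
  eqs <- find_equilibria(p, grid_density = 20)
  expect_gt(length(eqs), 0)
  for (e in eqs) {
    if (!e$feasible) next
    st <- map_step(e$x, e$y, p)
    expect_lt(abs(st[["x"]] - e$x) + abs(st[["y"]] - e$y), 1e-8)
  }
  # x = 0 maps to x' = 0
  st0 <- map_step(0, 0.3, p)
  expect_identical(st0[["x"]], 0)
})

test_that("positive starts stay positive and errors are informative", {
  p <- fig2_params(b = 3.4)
  ob <- map_orbit(c(0.3, 0.3), 500, 100, p)
  expect_true(all(ob$x >= 0))
  expect_true(all(ob$y > 0))
  expect_error(map_step(0.5, 0, fig1_params()), "u > 0")
  expect_error(map_orbit(c(0.3, 0.3), 10, 20, p), "N > burn_in")
})

test_that("orbit collapses to a point for small b and spreads for large b", {
  ob1 <- map_orbit(c(0.3, 0.3), 1200, 1000, fig2_params(b = 0.9))
  post <- ob1[!ob1$transient, ]
  expect_lt(max(post$x) - min(post$x), 1e-6)
  ob2 <- map_orbit(c(0.3, 0.3), 1500, 1000, fig2_params(b = 3.2))
  post2 <- ob2[!ob2$transient, ]
  # at least two well-separated clusters of iterates
  expect_gt(max(post2$x) - min(post2$x), 0.5)
})

test_that("refined frozen-rate maps converge to the time-1 flow", {
  p <- fig1_params(K_t = 0.045, L = 1.0)
  set.seed(3)
  for (i in 1:10) {
    st <- rand_state(p, margin = 0.2)
    flow <- simulate_model(st, 1, p, times = c(0, 1),
                           rtol = 1e-10, atol = 1e-12)
    target <- c(flow$x[2], flow$y[2])
    errs <- vapply(c(1, 2, 4, 8), function(m) {
      z <- map_step_refined(st[1], st[2], m, p)
      sqrt(sum((z - target)^2))
    }, numeric(1))
    expect_true(all(diff(errs) < 1e-12))   # monotone decrease
    expect_lt(errs[4], errs[1] / 2)
  }
})

test_that("the exact-influx variant shares fixed points with the ODE", {
  p <- fig1_params(K_t = 0.045, L = 1.0)
  e1 <- boundary_equilibrium(p)
  st <- map_step(e1$x, e1$y, p, influx = "exact")
  expect_equal(unname(st), c(e1$x, e1$y), tolerance = 1e-12)
  eqs <- find_equilibria(p, grid_density = 15, include_boundary = FALSE)
  for (e in eqs) {
    st <- map_step(e$x, e$y, p, influx = "exact")
    expect_lt(abs(st[["x"]] - e$x) + abs(st[["y"]] - e$y), 1e-7)
  }
})

test_that("exponent capping triggers a diagnostic instead of overflow", {
  p <- table1(u = 1000, l = 0)
  st <- map_step(0.5, 1e-4, p)
  expect_true(isTRUE(attr(st, "capped")))
  expect_true(all(is.finite(st)))
})
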