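test_that("quota closures give the closed-form values and the lke limit", {
  p <- table1()
  # qss at (1, 0): (q*mu_m/alpha + K_t)/(mu_m/alpha + 1)
  expect_equal(quota(1, 0, p), (0.0038 * 0.12 + 0.025) / 1.12,
               tolerance = 1e-12)
  expect_equal(quota(1, 0, p), 0.0227286, tolerance = 1e-5)
  expect_equal(quota(1, 0, p, "lke"), 0.025, tolerance = 1e-12)
  # alpha -> Inf: qss converges pointwise to lke for x > 0
  p_big <- table1(alpha = 1e9)
  for (st in list(c(1, 0), c(0.3, 0.4), c(1.5, 0.1))) {
    expect_equal(quota(st[1], st[2], p_big),
                 quota(st[1], st[2], p, "lke"), tolerance = 1e-6)
  }
  expect_identical(quota(0, 0.1, p, "lke"), Inf)
  expect_error(quota(0.5, 1, p), "infeasible")
})

test_that("growth factor follows Liebig's minimum with exact zero sets", {
  p <- table1()
  # potassium-limited near the origin
  g0 <- tumour_growth_factor(1e-12, 0, p)
  expect_equal(as.numeric(g0), 1.2 * (1 - 0.0038 / 0.212133),
               tolerance = 1e-5)
  expect_equal(as.numeric(g0), 1.17851, tolerance = 1e-5)
  # carbon branch zero at carrying capacity
  p2 <- table1(K_t = 0.5)  # potassium abundant so carbon branch binds
  gL <- tumour_growth_factor(p2$L, 0, p2)
  expect_equal(as.numeric(gL), 0, tolerance = 1e-12)
  expect_identical(attr(gL, "branch"), "carbon")
  # potassium branch zero exactly at q x = K_t - theta y (both closures)
  pbig <- suppressWarnings(reference_parameters(L = 10))
  xstar <- pbig$K_t / pbig$q
  expect_equal(xstar, 6.5789, tolerance = 1e-4)
  for (cl in c("qss", "lke"))
    expect_equal(as.numeric(tumour_growth_factor(xstar, 0, pbig, cl)), 0,
                 tolerance = 1e-12)
})

test_that("recruitment efficiency saturates at e and reduces as Q/theta", {
  p <- table1()
  r1 <- recruitment_efficiency(0.1, 0.1, p, "lke")   # Q = 0.022/0.1 >> theta
  expect_equal(as.numeric(r1), 0.8)
  expect_identical(attr(r1, "branch"), "rich")
  r2 <- recruitment_efficiency(0.5, 0.7, p, "lke")   # Q = 0.008 < theta
  expect_equal(as.numeric(r2), 0.8 * 0.008 / 0.03, tolerance = 1e-12)
  expect_equal(as.numeric(r2), 0.21333, tolerance = 1e-4)
  # continuity at the switch Q = theta: y such that (K_t - theta*y)/x = theta
  x <- 0.5
  ysw <- (p$K_t - p$theta * x) / p$theta
  lo <- recruitment_efficiency(x, ysw - 1e-9, p, "lke")
  hi <- recruitment_efficiency(x, ysw + 1e-9, p, "lke")
  expect_equal(as.numeric(lo), as.numeric(hi), tolerance = 1e-6)
  expect_equal(as.numeric(lo), p$e, tolerance = 1e-6)
})

test_that("rhs vanishes at the boundary equilibrium and on the y-axis", {
  p <- fig1_params()
  expect_equal(unname(model_rhs(0, p$u / p$d, p)), c(0, 0),
               tolerance = 1e-15)
  for (y in c(0.1, 0.5, 1.2)) {
    r <- model_rhs(0, y, p)
    expect_identical(r[["dx"]], 0)
    expect_equal(r[["dy"]], p$u - p$d * y, tolerance = 1e-15)
  }
  # KHE reduction: immune-free boundary equilibrium at x = min(L, K_t/q)
  p0 <- table1()
  k <- min(p0$L, p0$K_t / p0$q)
  expect_equal(unname(model_rhs(k, 0, p0)), c(0, 0), tolerance = 1e-12)
})

test_that("the scaled (theta-free) form defines the same vector field", {
  for (seed in 1:20) {
    pars <- rand_params(seed)
    sp <- scale_params(pars)
    set.seed(seed + 1000)
    st <- rand_state(pars)
    for (cl in c("qss", "lke")) {
      got <- unname(model_rhs_scaled(st[1], st[2], sp, cl))
      want <- unname(model_rhs(st[1], st[2], pars, cl))
      expect_lt(max(abs(got - want) / pmax(abs(want), 1)), 1e-12)
    }
  }
})

test_that("potassium pools close the mass balance and K_f tracks the trapezoid", {
  pars <- fig1_params()
  set.seed(7)
  for (i in 1:50) {
    st <- rand_state(pars)
    d <- model_rhs(st[1], st[2], pars, detail = TRUE)
    Q <- attr(d, "Q"); K_f <- attr(d, "K_f")
    K_c <- Q * st[[1]]; K_i <- pars$theta * st[[2]]
    expect_equal(unname(K_c + K_i + K_f), pars$K_t, tolerance = 1e-14)
    # under qss, sign(K_f) = sign(K_t - theta*y - q*x)
    expect_equal(sign(K_f), unname(sign(pars$K_t - pars$theta * st[[2]] -
                                        pars$q * st[[1]])))
  }
})

test_that("with l = u = 0 the rhs equals the independently coded KHE core", {
  set.seed(42)
  for (i in 1:8) {
    pars <- rand_params(i)
    pars$l <- 0; pars$u <- 0
    for (j in 1:250) {
      st <- rand_state(pars)
      for (cl in c("qss", "lke")) {
        got <- unname(model_rhs(st[1], st[2], pars, cl))
        want <- oracle_khe_rhs(st[1], st[2], pars, cl)
        expect_lt(max(abs(got - want) / pmax(abs(want), 1)), 1e-12)
      }
    }
  }
})

test_that("simulation holds an equilibrium and respects the trapezoid", {
  p <- fig1_params()
  tr <- simulate_model(c(0, 0.2), 200, p)       # E1 = (0, u/d) = (0, 0.2)
  expect_lt(max(abs(tr$x)), 1e-8)
  expect_lt(max(abs(tr$y - 0.2)), 1e-7)

  p2 <- fig1_params(K_t = 0.045, L = 1.0)
  g <- trapezoid_spec(p2)
  tr2 <- simulate_model(c(0.3, 0.3), 500, p2)
  expect_true(all(tr2$x > 0 & tr2$x < g$k + 1e-8))
  expect_true(all(g$s * tr2$x + tr2$y < g$p + 1e-8))
  expect_true(all(tr2$K_f > -1e-10))
  # quota floor Q >= q along the trajectory
  expect_true(all(tr2$Q >= p2$q - 1e-12))
})

test_that("trajectories export branch labels and CSV round-trips", {
  p <- fig1_params(K_t = 0.045)
  tr <- simulate_model(c(0.3, 0.3), 50, p)
  expect_true(all(tr$limiting_branch %in% c("carbon", "potassium")))
  expect_true(all(tr$efficiency_branch %in% c("rich", "poor")))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(tr))
  expect_equal(back$x, tr$x, tolerance = 1e-12)
})
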