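test_that("boundary equilibrium is (0, u/d) with zero residuals", {
  p <- fig1_params()                      # u = 0.05, d = 0.25
  e1 <- boundary_equilibrium(p)
  expect_equal(c(e1$x, e1$y), c(0, 0.2))
  expect_lt(e1$residual_continuous, 1e-14)
  expect_lt(e1$residual_discrete, 1e-14)
  e0 <- boundary_equilibrium(table1())    # u = 0: coincides with (0, 0)
  expect_equal(c(e0$x, e0$y), c(0, 0))
  # infeasible when theta*u/d >= K_t
  pbad <- table1(u = 0.5)
  expect_false(boundary_equilibrium(pbad)$feasible)
})

test_that("E1 linearization is triangular with eigenvalue -d", {
  p <- fig1_params()
  J <- model_jacobian("continuous", 0, p$u / p$d, p)
  expect_identical(J["x", "y"], 0)            # F_y = -f(0) = 0
  expect_equal(J["y", "y"], -0.25)            # -d
  lam <- as.numeric(tumour_growth_factor(0, p$u / p$d, p)) -
    (p$c / p$a) * p$u / p$d
  expect_equal(J["x", "x"], lam, tolerance = 1e-12)
  Jd <- model_jacobian("discrete", 0, p$u / p$d, p)
  expect_equal(Jd["y", "y"], 0.75)            # 1 - d
  expect_identical(Jd["x", "y"], 0)
})

test_that("analytic Jacobians agree with central differences off-switch", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:10) {
    pars <- rand_params(i + 100)
    for (j in 1:40) {
      st <- rand_state(pars, margin = 0.1)
      if (!stencil_off_switch(pars, st[[1]], st[[2]])) next
      J <- model_jacobian("continuous", st[1], st[2], pars)
      if (isTRUE(attr(J, "on_switch"))) next
      Jn <- numeric_jacobian("continuous", st[1], st[2], pars)
      expect_equal(unclass(J)[1:2, 1:2], Jn, tolerance = 1e-5)
      Jd <- model_jacobian("discrete", st[1], st[2], pars)
      Jdn <- numeric_jacobian("discrete", st[1], st[2], pars)
      expect_equal(unclass(Jd)[1:2, 1:2], Jdn, tolerance = 1e-5)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 300)
})

test_that("Jury verdict matches the eigenvalue moduli", {
  M1 <- matrix(c(0.5, 0.1, 0.2, 0.3), 2, 2, byrow = TRUE)
  expect_true(jury_stable(M1))
  ev <- eigen(M1, only.values = TRUE)$values
  expect_equal(sort(Re(ev)), c(0.227, 0.573), tolerance = 1e-3)
  M2 <- diag(c(2, 0.5))
  expect_false(jury_stable(M2))             # |tr| = 2.5 >= 1 + det = 2
  set.seed(123)
  for (i in 1:1000) {
    M <- matrix(stats::rnorm(4, sd = 1.2), 2, 2)
    mods <- Mod(eigen(M, only.values = TRUE)$values)
    if (any(abs(mods - 1) < 1e-9)) next     # unit-circle band excluded
    expect_identical(isTRUE(jury_stable(M)), all(mods < 1))
  }
})

test_that("continuous and discrete fixed-point sets coincide", {
  for (seed in 1:6) {
    pars <- rand_params(seed + 300)
    ec <- find_equilibria(pars, grid_density = 15,
                          include_boundary = FALSE)
    ed <- find_equilibria(pars, model = "discrete", grid_density = 15,
                          include_boundary = FALSE)
    for (e in c(ec, ed)) {
      expect_lt(e$residual_continuous, 1e-9)
      expect_lt(e$residual_discrete, 1e-7)
    }
    # Hausdorff distance between the two root sets
    if (length(ec) && length(ed)) {
      dmat <- outer(seq_along(ec), seq_along(ed), Vectorize(function(i, j)
        sqrt((ec[[i]]$x - ed[[j]]$x)^2 + (ec[[i]]$y - ed[[j]]$y)^2)))
      haus <- max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
      expect_lt(haus, 1e-6)
    } else {
      expect_identical(length(ec), length(ed))
    }
  }
})

test_that("the l = u = 0 equilibria match the independent KHE core", {
  pars <- table1(L = 0.25)
  eqs <- find_equilibria(pars, grid_density = 20,
                         include_boundary = FALSE)
  for (e in eqs) {
    r <- oracle_khe_rhs(e$x, e$y, pars)
    expect_lt(sqrt(sum(r^2)), 1e-8)
  }
})

test_that("region labels split the plane at Q = theta", {
  p <- table1()
  expect_identical(region_of(0.1, 0.1, p, "lke"), "Omega1")  # Q = 0.22
  expect_identical(region_of(0.5, 0.7, p, "lke"), "Omega2")  # Q = 0.008
  # in scaled coordinates (theta = 1) the lke separatrix is x + y = p
  sp <- scale_params(p)
  p1 <- suppressWarnings(unscale_params(sp, theta = 1))
  for (x in c(0.1, 0.3, 0.6)) {
    y_line <- sp$p - x
    expect_identical(region_of(x, y_line - 1e-9, p1, "lke"), "Omega1")
    expect_identical(region_of(x, y_line + 1e-9, p1, "lke"), "Omega2")
  }
})

test_that("classification reports saddles, slopes and theorem clauses", {
  p <- fig1_params(K_t = 0.045, L = 2.0)
  eqs <- find_equilibria(p, grid_density = 25, include_boundary = FALSE)
  expect_gte(length(eqs), 2)
  saw_saddle <- FALSE
  for (e in eqs) {
    rep_c <- classify_equilibrium("continuous", e, p)
    det_J <- det(unclass(rep_c$jacobian)[1:2, 1:2])
    if (det_J < 0) {
      saw_saddle <- TRUE
      expect_identical(rep_c$verdict, "saddle")
      # Theorem clause: immune nullcline flatter than tumour's at a saddle
      if (rep_c$nullcline_slope_G < rep_c$nullcline_slope_F)
        expect_true(any(grepl("saddle clause", rep_c$theorem_flags)))
    }
    rep_d <- classify_equilibrium("discrete", e, p)
    expect_identical(isTRUE(rep_d$jury), rep_d$stable)
    # discrete instability clause mirrors the slope comparison
    if (!is.na(rep_d$nullcline_slope_G) &&
        rep_d$nullcline_slope_G < rep_d$nullcline_slope_F)
      expect_false(rep_d$stable)
  }
  expect_true(saw_saddle)
})

test_that("raising u stabilizes E1 and raising K_t destabilizes it", {
  eig_at <- function(u, K_t) {
    p <- reference_parameters(L = 1.0, l = 0.2, u = u, K_t = K_t)
    as.numeric(tumour_growth_factor(0, u / p$d, p)) - p$c / p$a * u / p$d
  }
  us <- seq(0.01, 0.12, length.out = 8)
  lams <- vapply(us, eig_at, numeric(1), K_t = 0.045)
  expect_true(all(diff(lams) < 0))
  kts <- seq(0.03, 0.08, length.out = 8)
  lams_k <- vapply(kts, function(k) eig_at(0.05, k), numeric(1))
  expect_true(all(diff(lams_k) > 0))
  # classification agrees with the eigenvalue sign
  p_stab <- reference_parameters(L = 1.0, l = 0.2, u = 0.12)
  rep1 <- classify_equilibrium("continuous", boundary_equilibrium(p_stab),
                               p_stab)
  expect_true(rep1$stable)
})
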