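test_that("detect_period identifies constant, alternating and cyclic samples", {
  expect_identical(detect_period(rep(0.4, 50)), 1L)
  expect_identical(detect_period(rep(c(0.2, 0.7), 25)), 2L)
  # quadratic map in its 2-cycle regime
  r <- 3.2; x <- 0.3
  for (i in 1:500) x <- r * x * (1 - x)
  xs <- numeric(64)
  for (i in 1:64) { x <- r * x * (1 - x); xs[i] <- x }
  expect_identical(detect_period(xs), 2L)
  # fully chaotic quadratic map: aperiodic
  r <- 4; x <- 0.345
  for (i in 1:500) x <- r * x * (1 - x)
  xs <- numeric(256)
  for (i in 1:256) { x <- r * x * (1 - x); xs[i] <- x }
  expect_identical(detect_period(xs), 0L)
  expect_error(detect_period(c(1, 2)), "at least 4")
})

test_that("lyapunov_max recovers ln 2 for the chaotic quadratic map", {
  lam <- lyapunov_max(logistic_step(4), logistic_jac(4), 0.345,
                      N = 20000, burn_in = 500)
  expect_equal(lam, log(2), tolerance = 0.01)
})

test_that("the exponent at a stable fixed point is the log multiplier", {
  p <- fig2_params(b = 0.9)
  ob <- map_orbit(c(0.3, 0.3), 2000, 1900, p)
  fp <- as.numeric(ob[nrow(ob), c("x", "y")])
  J <- unclass(model_jacobian("discrete", fp[1], fp[2], p))[1:2, 1:2]
  target <- log(max(Mod(eigen(J, only.values = TRUE)$values)))
  expect_lt(target, 0)
  lam <- model_lyapunov(p, state0 = fp, N = 3000, burn_in = 100)
  expect_equal(lam, target, tolerance = 0.02)
})

test_that("a single-value sweep reproduces the plain orbit protocol", {
  p <- fig2_params(b = 1.4)
  bd <- bifurcation_sweep("discrete", "b", 1.4, p, start = c(0.3, 0.3),
                          burn_in = 300, n_sample = 50, lyapunov = FALSE)
  ob <- map_orbit(c(0.3, 0.3), 350, 300, p)
  post <- ob[!ob$transient, ]
  expect_equal(bd$samples$x, post$x, tolerance = 1e-14)
  expect_equal(bd$samples$y, post$y, tolerance = 1e-14)
  expect_identical(bd$summary$period, 1L)
})

test_that("warm and cold starts agree in the unique-attractor regime", {
  p <- fig2_params()
  vals <- seq(0.9, 1.5, by = 0.2)
  w <- bifurcation_sweep("discrete", "b", vals, p, burn_in = 800,
                         n_sample = 60, lyapunov = FALSE)
  c0 <- bifurcation_sweep("discrete", "b", vals, p, burn_in = 800,
                          n_sample = 60, warm_start = FALSE,
                          lyapunov = FALSE)
  both1 <- w$summary$period == 1L & c0$summary$period == 1L
  expect_true(any(both1))
  expect_equal(w$summary$x_max[both1], c0$summary$x_max[both1],
               tolerance = 1e-6)
})

test_that("period-doubling order holds along the discrete b-sweep", {
  p <- fig2_params()
  vals <- seq(1.6, 3.1, length.out = 16)
  bd <- bifurcation_sweep("discrete", "b", vals, p, burn_in = 1500,
                          n_sample = 128, lyapunov = FALSE)
  per <- bd$summary$period
  first_aper <- match(0L, per)
  pre <- if (is.na(first_aper)) per else per[seq_len(first_aper - 1)]
  pre <- pre[!is.na(pre)]
  expect_true(all(pre %in% 2^(0:6)))
  expect_true(all(diff(pre) >= 0))
  expect_true(any(pre == 1L) && any(pre == 2L))
})

test_that("failed sweep values are recorded without aborting the sweep", {
  p <- fig1_params(K_t = 0.045, L = 1.0)
  # u sweep into the infeasible regime: early values fine, late ones fail
  vals <- c(0.05, 0.1, 50)
  bd <- bifurcation_sweep("continuous", "u", vals, p, transient = 50,
                          record = 20, n_sample = 30)
  expect_identical(sum(bd$summary$failed), 1L)
  expect_false(bd$summary$failed[1])
})

test_that("bifurcation CSV export is tidy and complete", {
  p <- fig2_params()
  bd <- bifurcation_sweep("discrete", "b", c(1.0, 1.2), p, burn_in = 100,
                          n_sample = 20, lyapunov = FALSE)
  path <- tempfile(fileext = ".csv")
  write_bifurcation(bd, path)
  back <- utils::read.csv(path)
  expect_setequal(names(back),
                  c("value", "variable", "sample", "state", "period",
                    "lyapunov"))
  expect_identical(nrow(back), 2L * 2L * 20L)
})
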