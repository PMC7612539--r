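test_that("degenerate inflows give the analytic steady states", {
  dt <- 1e-3
  zeroq <- uniform_wave(rep(0, 870), dt, kind = "flow")
  par <- wk_params(0.5, 1.5, 0, 32)
  p <- solve_2wk(zeroq, par, wk_settings("transient", P_0 = 32))
  expect_true(all(abs(p$values - 32) < 1e-12))

  # constant inflow: steady state up to the trapezoid discretization error,
  # which is O((dt/tau)^2) of the pressure drop, well below 1e-4 mmHg here
  constq <- uniform_wave(rep(90, 870), dt, kind = "flow")
  p2 <- solve_2wk(constq, par, wk_settings("periodic"))
  expect_true(all(abs(p2$values - (32 + 0.5 * 90)) < 1e-4))
  par3 <- wk_params(0.5, 1.5, 0.025, 32)
  p3 <- solve_3wk(constq, par3, wk_settings("periodic"))
  expect_true(all(abs(p3$values - (32 + 0.5 * 90)) < 1e-4))
})

test_that("three-element solution reduces to two-element when Z_0 = 0", {
  q <- half_sine_flow(300, 0.25, 0.87)
  p2 <- solve_2wk(q, wk_params(0.5, 1.5, 0, 32))
  p3 <- solve_3wk(q, wk_params(0.5, 1.5, 0, 32))
  expect_lt(max(abs(p2$values - p3$values)), 1e-9)
})

test_that("closed-form periodic solutions agree with the RK4 reference", {
  period <- 0.87
  lvet <- 0.25
  Qmax <- 88 * pi / (2 * lvet)
  q <- half_sine_flow(Qmax, lvet, period)
  fns <- half_sine_fun(Qmax, lvet, period)
  k <- round(1e-3 / 1e-5)

  par2 <- wk_params(0.5, 1.5, 0, 32)
  p2 <- solve_2wk(q, par2)
  r2 <- solve_wk_rk4(fns$q, par2, period, dt = 1e-5)
  idx <- seq(1, by = k, length.out = length(p2$values))
  expect_lt(max(abs(p2$values - r2$values[idx])), 0.05)

  par3 <- wk_params(0.5, 1.5, 0.05 * 0.5, 32)
  p3 <- solve_3wk(q, par3)
  r3 <- solve_wk_rk4(fns$q, par3, period, dt = 1e-5, dqfun = fns$dq)
  expect_lt(max(abs(p3$values - r3$values[idx])), 0.05)
})

test_that("periodic solutions satisfy the Windkessel mean identity and floor", {
  q <- half_sine_flow(300, 0.25, 0.87)
  for (z0 in c(0, 0.03)) {
    par <- wk_params(0.6, 1.2, z0, 30)
    p <- solve_3wk(q, par)
    qbar <- wave_stats(q)$Q_mean
    expect_lt(abs(wave_stats(p)$MBP - (30 + 0.6 * qbar)), 0.1)
    expect_true(all(p$values >= 30 - 1e-9))  # nonnegative inflow, P >= P_out
  }
})

test_that("transient iteration approaches the periodic cycle geometrically", {
  period <- 0.87; lvet <- 0.25; Qmax <- 300
  q <- half_sine_flow(Qmax, lvet, period)
  fns <- half_sine_fun(Qmax, lvet, period)
  par <- wk_params(0.5, 1.5, 0, 32)
  tau <- diastolic_decay_constant(par)
  p_per <- solve_2wk(q, par)

  # chain three single-cycle RK4 integrations from a perturbed start: the
  # start-of-cycle deviation must contract by exp(-T/tau) each cycle
  p0 <- p_per$values[1] + 20
  devs <- numeric(4)
  devs[1] <- abs(p0 - p_per$values[1])
  for (cyc in 1:3) {
    r <- solve_wk_rk4(fns$q, par, period, dt = 1e-4, periodic = FALSE,
                      P_0 = p0)
    p0 <- attr(r, "P_end")
    devs[cyc + 1] <- abs(p0 - p_per$values[1])
  }
  ratios <- devs[2:4] / devs[1:3]
  expect_true(all(abs(ratios - exp(-period / tau)) < 0.02))

  # the solver's own transient mode converges to the periodic solution
  p_tr <- solve_2wk(q, par, wk_settings("transient", P_0 = p_per$values[1] + 20,
                                        tol = 1e-10, max_cycles = 500))
  expect_lt(max(abs(p_tr$values - p_per$values)), 1e-6)
})

test_that("diastolic decay constant matches the simulated diastolic slope", {
  expect_equal(diastolic_decay_constant(wk_params(0.5, 1.5, 0, 32)), 0.75)
  expect_equal(diastolic_decay_constant(wk_params(0.5, 1.5, 0.05 * 0.5, 32)),
               0.7125)
  s <- make_subject()
  tau <- diastolic_decay_constant(s$params)
  t <- wave_times(s$p)
  idx <- which(t > s$lvet + 0.05)
  slope <- stats::coef(stats::lm(log(s$p$values[idx] - 32.3) ~ t[idx]))[2]
  expect_equal(unname(slope), -1 / tau, tolerance = 0.005)
})

test_that("optimized three-element fit recovers generating parameters", {
  s <- make_subject()
  fit <- fit_3wk_optimized(s$p, s$q, R_T = 0.51, P_out = 32.3)
  expect_lt(abs(fit$Z_0 / 0.0255 - 1), 1e-3)
  expect_lt(abs(fit$C_T / 1.3 - 1), 1e-3)
  expect_lt(fit$rmse, 0.05)
  expect_equal(unname(coef(fit)), c(fit$Z_0, fit$C_T))
  expect_lt(max(abs(residuals(fit))), 0.05)
})

test_that("optimizer matches an exhaustive log-grid search", {
  s <- make_subject(HR = 60.8, SV = 79.75, R_T = 0.45, C_T = 1.1,
                    Z_0 = 0.03, P_out = 28.3)
  fit <- fit_3wk_optimized(s$p, s$q, R_T = 0.45, P_out = 28.3)
  zg <- exp(seq(log(1e-4 * 0.45), log(0.5 * 0.45), length.out = 40))
  cg <- exp(seq(log(0.05), log(10), length.out = 40))
  rmse_of <- function(z0, ct) {
    pr <- solve_3wk(s$q, wk_params(0.45, ct, z0, 28.3))
    sqrt(mean((pr$values - s$p$values)^2))
  }
  grid <- outer(zg, cg, Vectorize(rmse_of))
  best <- which(grid == min(grid), arr.ind = TRUE)
  # optimizer must land within one grid cell of the brute-force minimum
  expect_lt(abs(log(fit$Z_0) - log(zg[best[1]])),
            diff(log(zg[1:2])) + 1e-9)
  expect_lt(abs(log(fit$C_T) - log(cg[best[2]])),
            diff(log(cg[1:2])) + 1e-9)
  expect_lte(fit$rmse, min(grid) + 1e-9)
})

test_that("parameter validation rejects nonphysical Windkessel sets", {
  expect_error(wk_params(-1, 1, 0, 30), class = "cbpkit_error_invalid_params")
  expect_error(wk_params(0.5, -1, 0, 30), class = "cbpkit_error_invalid_params")
  expect_error(wk_params(0.5, 1, 0.6, 30), class = "cbpkit_error_invalid_params")
  expect_error(wk_params(0.5, 1, 0, -3), class = "cbpkit_error_invalid_params")
})
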