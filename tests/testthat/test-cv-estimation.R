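test_that("LVET estimators behave per method definition", {
  s <- make_subject()
  inp <- estimator_input(p_wave = s$p, q_wave = s$q)

  # LV3 is the literal fraction of the cycle
  lv3 <- estimate_lvet(estimator_input(q_wave = uniform_wave(
    half_sine_flow(100, 0.3, 1.0)$values, 1e-3, kind = "flow"),
    DBP = 60, SBP = 110), "LV3")
  expect_equal(lv3$value, 0.37)
  lv3s <- estimate_lvet(estimator_input(q_wave = half_sine_flow(100, 0.3, 4.0),
                                        DBP = 60, SBP = 110), "LV3",
                        weissler_sqrt = TRUE)
  expect_equal(lv3s$value, 0.37 * 2)

  # LV4 recovers the generator's ejection time from the flow wave
  lv4 <- estimate_lvet(inp, "LV4")
  expect_lt(abs(lv4$value - s$lvet), 2 * s$q$dt)

  # LV2 underestimates on a lumped-model pressure (dP/dt minimum is early)
  lv2 <- estimate_lvet(inp, "LV2")
  expect_lt(lv2$value, s$lvet)

  # LV1 is inapplicable: lumped-model waves have no dicrotic notch
  expect_error(estimate_lvet(inp, "LV1"),
               class = "cbpkit_error_inapplicable_method")
})

test_that("outflow pressure estimators: fixed fractions and diastolic fits", {
  expect_equal(estimate_pout(estimator_input(DBP = 64.6, SBP = 117.6),
                             "OP3")$value, 32.3)
  expect_equal(estimate_pout(estimator_input(DBP = 64.6, SBP = 117.6),
                             "OP4")$value, 0.7 * 64.6)

  s <- make_subject(P_out = 33.2)
  inp <- estimator_input(p_wave = s$p, q_wave = s$q)
  for (m in c("OP1", "OP2")) {
    est <- estimate_pout(inp, m, lvet = s$lvet)
    expect_lt(abs(est$value / 33.2 - 1), 1e-3)
  }
  expect_error(estimate_pout(inp, "OP1"),
               class = "cbpkit_error_inapplicable_method")  # missing LVET
})

test_that("resistance estimators implement their defining formulas", {
  constp <- uniform_wave(rep(100, 870), 1e-3, kind = "pressure")
  constq <- uniform_wave(rep(100, 870), 1e-3, kind = "flow")
  ar1 <- estimate_rt(estimator_input(p_wave = constp, q_wave = constq),
                     "AR1", P_out = 30)
  expect_equal(ar1$value, 0.70)

  q90 <- uniform_wave(rep(90, 870), 1e-3, kind = "flow")
  ar2 <- estimate_rt(estimator_input(DBP = 80, SBP = 120, q_wave = q90),
                     "AR2", P_out = 33)
  expect_equal(ar2$value, (96 - 33) / 90)

  expect_error(estimate_rt(estimator_input(DBP = 80, SBP = 120, q_wave = q90),
                           "AR2", P_out = 200),
               class = "cbpkit_error_nonphysical")
})

test_that("compliance estimators recover truth on self-generated data", {
  # Z_0 = 0: tau = R_T * C_T exactly, decay methods are exact
  s0 <- make_subject(Z_0 = 0)
  inp0 <- estimator_input(p_wave = s0$p, q_wave = s0$q)
  ac2 <- estimate_ct(inp0, "AC2", R_T = 0.51, P_out = 32.3, lvet = s0$lvet)
  expect_lt(abs(ac2$value / 1.3 - 1), 1e-3)

  # with Z_0 > 0 the decay methods recover tau/(R_T - Z_0) when Z_0 is known
  s <- make_subject()
  inp <- estimator_input(p_wave = s$p, q_wave = s$q)
  for (m in c("AC1", "AC2", "AC3", "AC4")) {
    est <- estimate_ct(inp, m, R_T = 0.51, P_out = 32.3, Z_0 = 0.0255,
                       lvet = s$lvet)
    expect_lt(abs(est$value / 1.3 - 1), 0.02)
  }

  # AC8 is the SV/PP ratio
  ac8 <- estimate_ct(estimator_input(q_wave = s0$q, DBP = 64.6,
                                     SBP = 64.6 + 52.9), "AC8")
  expect_equal(ac8$value, 88.4 / 52.9, tolerance = 1e-3)

  # AC6/AC7 root-finding on two-element data recovers the compliance
  q <- s0$q
  p2 <- solve_2wk(q, wk_params(0.51, 1.3, 0, 32.3))
  st <- wave_stats(p2)
  inp2 <- estimator_input(DBP = st$DBP, SBP = st$SBP, q_wave = q)
  for (m in c("AC6", "AC7")) {
    est <- estimate_ct(inp2, m, R_T = 0.51, P_out = 32.3)
    expect_lt(abs(est$value / 1.3 - 1), 1e-4)
  }

  # AC5 solves the two-area linear system close to truth on 2-Wk data
  inp5 <- estimator_input(p_wave = p2, q_wave = q)
  ac5 <- estimate_ct(inp5, "AC5", R_T = 0.51, P_out = 32.3, lvet = s0$lvet)
  expect_lt(abs(ac5$value / 1.3 - 1), 0.05)

  # AC9 equals the optimized fit compliance
  ac9 <- estimate_ct(inp, "AC9", R_T = 0.51, P_out = 32.3)
  expect_lt(abs(ac9$value / 1.3 - 1), 1e-3)
})

test_that("pulse wave velocity estimators recover constructed transit times", {
  period <- 1.0; dt <- 1e-3
  fw <- generate_flow_wave(60, 88.4)
  q <- fw$q_in
  shift_wave <- function(w, s) {
    k <- round(s / w$dt); n <- length(w$values)
    uniform_wave(c(w$values[(n - k + 1):n], w$values[1:(n - k)]), w$dt,
                 kind = w$kind)
  }
  # foot-to-foot over a known path length
  qd <- shift_wave(q, 0.04)
  pv1 <- estimate_pwv(estimator_input(q_wave = q, q_distal = qd, dx = 0.2,
                                      DBP = 60, SBP = 110), "PV1")
  expect_equal(pv1$value, 5.0, tolerance = 0.02)

  # least-squares shift recovery at sub-sample accuracy
  qd2 <- shift_wave(q, 0.03)
  pv3 <- estimate_pwv(estimator_input(q_wave = q, q_distal = qd2, dx = 0.15,
                                      DBP = 60, SBP = 110), "PV3")
  expect_equal(pv3$value, 5.0, tolerance = 0.01)

  # pressure-pair variants
  s <- make_subject()
  pd <- shift_wave(s$p, 0.04)
  pv2 <- estimate_pwv(estimator_input(p_pair = list(s$p, pd), dx = 0.2,
                                      q_wave = s$q), "PV2")
  expect_equal(pv2$value, 5.0, tolerance = 0.02)

  # water-hammer construction: P = P_0 + rho * c * U gives PWV = c
  A <- 5e-4; rho <- 1060; cset <- 6
  U <- q$values * 1e-6 / A
  p_wh <- uniform_wave(80 + rho * cset * U / 133.322, q$dt, kind = "pressure")
  pv5 <- estimate_pwv(estimator_input(p_wave = p_wh, q_wave = q, A = A,
                                      rho = rho), "PV5")
  expect_equal(pv5$value, 6.0, tolerance = 0.01)
})

test_that("characteristic impedance estimators: formulas, units and windows", {
  expect_equal(estimate_z0(estimator_input(DBP = 60, SBP = 110), "Z3",
                           R_T = 0.70)$value, 0.035)

  # Z4 with an explicit MBP
  q450 <- uniform_wave(c(rep(450, 300), rep(0, 570)), 1e-3, kind = "flow")
  z4 <- estimate_z0(estimator_input(DBP = 75, SBP = 120, q_wave = q450),
                    "Z4", MBP = 93)
  expect_equal(z4$value, (93 - 75) / 450)

  # Z5 unit conversion: 1060 * 5 / 5e-4 Pa.s/m3 in mmHg.s/mL
  z5 <- estimate_z0(estimator_input(DBP = 60, SBP = 110, A = 5e-4, rho = 1060),
                    "Z5", PWV = 5)
  expect_equal(z5$value, 1060 * 5 / 5e-4 * 7.5006e-9, tolerance = 1e-9)
  expect_equal(z5$value, 0.0795, tolerance = 1e-3)

  # Z2 recovers an exact early-systolic linear P-Q relation
  s <- make_subject()
  p_lin <- uniform_wave(30 + 0.08 * s$q$values, s$q$dt, kind = "pressure")
  z2 <- estimate_z0(estimator_input(p_wave = p_lin, q_wave = s$q), "Z2")
  expect_equal(z2$value, 0.08, tolerance = 1e-6)

  # Z1 averages |P_k/Q_k| exactly: a pressure proportional to the flow gives
  # the proportionality constant back
  s_prop <- uniform_wave(0.07 * s$q$values + 50, s$q$dt, kind = "pressure")
  z1x <- estimate_z0(estimator_input(p_wave = s_prop, q_wave = s$q), "Z1")
  expect_equal(z1x$value, 0.07, tolerance = 1e-9)

  # on a lumped-model subject Z1 overestimates Z_0: the input impedance at
  # harmonics 4-10 still carries part of the compliant-reservoir response
  inp <- estimator_input(p_wave = s$p, q_wave = s$q)
  z1 <- estimate_z0(inp, "Z1")
  expect_gt(z1$value, 0.0255)
  expect_lt(abs(z1$value / 0.0255 - 1), 0.5)
  z6 <- estimate_z0(inp, "Z6", R_T = 0.51, P_out = 32.3)
  expect_lt(abs(z6$value / 0.0255 - 1), 1e-3)
})

test_that("input impedance modulus decreases toward Z_0 with harmonic number", {
  s <- make_subject()
  hp <- wave_harmonics(s$p, 15)
  hq <- wave_harmonics(s$q, 15)
  z <- Mod(hp[3:16] / hq[3:16])  # harmonics 2..15
  expect_true(all(diff(z) < 1e-12))          # monotone decrease
  expect_lt(abs(z[length(z)] / 0.0255 - 1), 0.05)  # approaches Z_0
})

test_that("estimates scale correctly under pressure rescaling", {
  s <- make_subject()
  double_p <- uniform_wave(2 * s$p$values, s$p$dt, kind = "pressure")
  inp1 <- estimator_input(p_wave = s$p, q_wave = s$q)
  inp2 <- estimator_input(p_wave = double_p, q_wave = s$q)

  r1 <- estimate_rt(inp1, "AR1", P_out = 32.3)$value
  r2 <- estimate_rt(inp2, "AR1", P_out = 64.6)$value
  expect_equal(r2, 2 * r1, tolerance = 1e-9)

  z1 <- estimate_z0(inp1, "Z1")$value
  z2 <- estimate_z0(inp2, "Z1")$value
  expect_equal(z2, 2 * z1, tolerance = 1e-9)

  c1 <- estimate_ct(inp1, "AC2", R_T = 0.51, P_out = 32.3, lvet = s$lvet)$value
  c2 <- estimate_ct(inp2, "AC2", R_T = 2 * 0.51, P_out = 64.6,
                    lvet = s$lvet)$value
  expect_equal(c2, c1 / 2, tolerance = 1e-6)  # doubled pressures halve C_T
})
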