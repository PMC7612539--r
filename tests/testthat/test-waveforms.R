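test_that("wave_stats reports exact extrema and quadrature-closed means", {
  const <- uniform_wave(rep(80, 100), 1e-2, kind = "pressure")
  st <- wave_stats(const)
  expect_equal(st$DBP, 80)
  expect_equal(st$SBP, 80)
  expect_equal(st$MBP, 80)
  expect_equal(st$PP, 0)

  # half-sine ejection: integral = 2 * Qmax * lvet / pi
  q <- half_sine_flow(100, 0.3, 1.0)
  expect_equal(wave_stats(q)$SV, 2 * 100 * 0.3 / pi, tolerance = 1e-4)

  # generator scales Q_max so the stroke volume round-trips exactly
  fw <- generate_flow_wave(68.8, 88.4)
  expect_equal(wave_stats(fw$q_in)$SV, 88.4, tolerance = 1e-3)
})

test_that("wave constructor rejects degenerate input", {
  expect_error(uniform_wave(c(1, NA, rep(1, 40)), 1e-3, kind = "flow"),
               class = "cbpkit_error_invalid_wave")
  expect_error(uniform_wave(rep(1, 10), 1e-3, kind = "flow"),
               class = "cbpkit_error_invalid_wave")
  expect_error(uniform_wave(rep(1, 40), -1e-3, kind = "flow"),
               class = "cbpkit_error_invalid_wave")
})

test_that("intersecting-tangent foot detection finds onsets and is equivariant", {
  dt <- 1e-3
  t <- seq(0, 0.999, dt)
  # zero until 0.10 s then a linear rise: tangent meets the baseline at onset
  v <- pmax(0, t - 0.10) * 500
  v[t > 0.5] <- 0
  w <- uniform_wave(v, dt, kind = "flow")
  expect_lt(abs(detect_foot(w) - 0.10), 2 * dt)

  # shifting the wave content shifts the foot by the same amount
  v2 <- pmax(0, t - 0.14) * 500; v2[t > 0.54] <- 0
  w2 <- uniform_wave(v2, dt, kind = "flow")
  expect_equal(detect_foot(w2) - detect_foot(w), 0.04, tolerance = 1e-3)

  # positive scaling leaves the foot unchanged
  w3 <- uniform_wave(3.7 * v, dt, kind = "flow")
  expect_equal(detect_foot(w3), detect_foot(w), tolerance = 1e-9)

  expect_error(detect_foot(uniform_wave(rep(5, 100), dt, kind = "flow")),
               class = "cbpkit_error_landmark_not_found")
})

test_that("foot detection tolerates 1% additive noise", {
  dt <- 1e-3
  s <- make_subject()
  clean_foot <- detect_foot(s$q)
  set.seed(42)
  noisy <- s$q
  noisy$values <- noisy$values + rnorm(length(noisy$values),
                                       sd = 0.01 * max(noisy$values))
  expect_lt(abs(detect_foot(noisy) - clean_foot), 2 * dt + 1e-12)
})

test_that("dicrotic notch detection distinguishes notched from monotone decay", {
  s <- make_subject()
  expect_true(is.na(detect_dicrotic_notch(s$p)))  # lumped-model wave: no notch

  # exponential decay plus a late Gaussian bump creates a notch before the bump
  dt <- 1e-3
  t <- seq(0, 0.999, dt)
  v <- 40 * sin(pi * t / 0.25)^2 * (t < 0.25) + 60 * exp(-t / 0.6) +
    8 * exp(-((t - 0.35) / 0.03)^2)
  p <- uniform_wave(v, dt, kind = "pressure")
  notch <- detect_dicrotic_notch(p)
  expect_false(is.na(notch))
  t_peak <- (which.max(v) - 1) * dt
  expect_gt(notch, t_peak)
  expect_lt(notch, 0.35)
  # brute-force extrema scan agrees
  i <- which(diff(sign(diff(v))) == 2) + 1
  i <- i[i > which.max(v)]
  expect_equal(notch, (i[1] - 1) * dt)

  expect_true(is.na(detect_dicrotic_notch(
    uniform_wave(rep(80, 64), dt, kind = "pressure"))))
})

test_that("central-difference derivative matches analytic derivatives", {
  dt <- 1e-3
  w <- uniform_wave(rep(5, 64), dt, kind = "pressure")
  expect_true(all(wave_derivative(w)$values == 0))

  t <- seq(0, 0.999, dt)
  s <- uniform_wave(sin(2 * pi * t), dt, kind = "pressure")
  d <- wave_derivative(s)$values
  expect_lt(max(abs(d - 2 * pi * cos(2 * pi * t))) / (2 * pi), 1e-3)

  ramp <- uniform_wave(3 * t, dt, kind = "pressure")
  dr <- wave_derivative(ramp)$values
  expect_equal(dr[2:999], rep(3, 998), tolerance = 1e-9)  # interior samples
})

test_that("harmonics use the stated amplitude convention and invert exactly", {
  dt <- 1e-3
  t <- seq(0, 0.999, dt)
  const <- uniform_wave(rep(80, 1000), dt, kind = "pressure")
  h <- wave_harmonics(const, 5)
  expect_equal(Re(h[["0"]]), 80)
  expect_lt(max(Mod(h[-1])), 1e-10)

  cosw <- uniform_wave(cos(2 * pi * 3 * t), dt, kind = "pressure")
  h3 <- wave_harmonics(cosw, 6)
  expect_equal(Mod(h3[["3"]]), 1, tolerance = 1e-9)
  expect_lt(max(Mod(h3[-4])), 1e-9)

  set.seed(7)
  n <- 101  # odd so harmonics 1..(n-1)/2 carry the whole signal
  rw <- uniform_wave(rnorm(n), 1e-2, kind = "pressure")
  h <- wave_harmonics(rw, (n - 1) / 2)
  expect_lt(max(abs(harmonics_synthesize(h, n) - rw$values)), 1e-10)

  expect_error(wave_harmonics(rw, 51), class = "cbpkit_error_aliasing")
})

test_that("periodic resampling preserves identity, constants and means", {
  s <- make_subject()
  expect_identical(resample_wave(s$p, s$p$dt), s$p)

  const <- uniform_wave(rep(80, 100), 1e-2, kind = "pressure")
  rc <- resample_wave(const, 3e-3)
  expect_true(all(abs(rc$values - 80) < 1e-12))

  # band-limited wave: downsample then upsample stays within 1% of range
  down <- resample_wave(s$p, 8e-3)
  up <- resample_wave(down, 1e-3)
  rng <- diff(range(s$p$values))
  n <- min(length(up$values), length(s$p$values))
  expect_lt(max(abs(up$values[1:n] - s$p$values[1:n])), 0.01 * rng)
  expect_lt(abs(mean(down$values) - mean(s$p$values)) / abs(mean(s$p$values)),
            1e-3)

  expect_error(resample_wave(s$p, 0), class = "cbpkit_error_invalid_wave")
})
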