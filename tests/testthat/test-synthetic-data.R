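test_that("burst drive degenerates to a pure zero-mean sine at ratio one", {
  d <- make_burst_alpha(2, duration_s = 30, burst_amplitude_ratio = 1)
  env <- attr(d, "envelope")
  expect_true(all(env == 1))
  expect_lt(abs(mean(d$values[1, ])), 1e-10)
  # both regions carry the same signal
  expect_identical(d$values[1, ], d$values[2, ])
})

test_that("the analytic-signal envelope recovers the programmed burst", {
  d <- make_burst_alpha(1, duration_s = 60, burst_amplitude_ratio = 4,
                        burst_duration_s = 10)
  env <- attr(d, "envelope")
  rec <- Mod(oracle_analytic(d$values[1, ]))
  interior <- 5000:55000
  expect_lt(max(abs(rec[interior] - env[interior]) / env[interior]), 0.02)
  expect_error(make_burst_alpha(1, duration_s = 5, burst_duration_s = 10),
               "longer")
  expect_error(make_burst_alpha(1, duration_s = 30, carrier_freq = 5),
               "alpha band")
})

test_that("AM drive has equal component depths and a recoverable envelope", {
  d <- make_am_alpha(1, duration_s = 120, am_frequencies = 0.02)
  env <- attr(d, "envelope")
  # single 0.02 Hz component: envelope repeats with period 50 s
  expect_equal(env[1:10000], env[50001:60000], tolerance = 1e-9)
  expect_true(all(env > 0))

  d3 <- make_am_alpha(1, duration_s = 300)
  env3 <- attr(d3, "envelope")
  t <- (seq_along(env3) - 1) / 1000
  # least-squares projection: all three components have equal amplitude
  depths <- vapply(c(0.01, 0.02, 0.03), function(f) {
    2 * mean((env3 - mean(env3)) * sin(2 * pi * f * t))
  }, numeric(1))
  expect_equal(depths, rep(depths[1], 3), tolerance = 1e-2)

  # demodulated envelope matches the programmed one
  rec <- Mod(oracle_analytic(d3$values[1, ]))
  interior <- 10000:290000
  expect_gt(cor(rec[interior], env3[interior]), 0.99)
  expect_error(make_am_alpha(1, 60, am_frequencies = numeric(0)), "non-empty")
})

test_that("surrogate source activity is z-scored, alpha-dominant, reproducible", {
  d1 <- make_surrogate_source_activity(3, 120, seed = 9)
  d2 <- make_surrogate_source_activity(3, 120, seed = 9)
  d3 <- make_surrogate_source_activity(3, 120, seed = 10)
  expect_identical(d1$values, d2$values)
  expect_false(identical(d1$values, d3$values))
  expect_equal(ncol(d1$values), 120000)
  for (i in 1:3) {
    expect_lt(abs(mean(d1$values[i, ])), 0.02)
    expect_lt(abs(sd(d1$values[i, ]) - 1), 0.05)
  }
  # alpha band beats the 20-30 Hz band in power (independent periodogram)
  sp <- spec.pgram(ts(d1$values[1, ], frequency = 1000), plot = FALSE,
                   spans = 31)
  p_alpha <- mean(sp$spec[sp$freq >= 8 & sp$freq <= 12])
  p_beta <- mean(sp$spec[sp$freq >= 20 & sp$freq <= 30])
  expect_gt(p_alpha, p_beta)
  expect_error(make_surrogate_source_activity(2, 30, seed = 1), "60")
})

test_that("time permutation preserves values but destroys structure", {
  d <- make_am_alpha(3, duration_s = 60)
  pd <- permute_drive(d, seed = 4)
  for (i in 1:3)
    expect_equal(sort(pd$values[i, ]), sort(d$values[i, ]))
  # lag-1 autocorrelation collapses
  r1 <- cor(pd$values[1, -1], pd$values[1, -ncol(pd$values)])
  expect_lt(abs(r1), 0.05)
  # regions are permuted independently
  expect_false(identical(pd$values[1, ], pd$values[2, ]))
  # determinism
  expect_identical(permute_drive(d, seed = 4)$values, pd$values)
})

test_that("synthetic connectomes are symmetric, normalized, heavy-tailed", {
  C <- make_synthetic_connectome(10, density = 0.5, seed = 2)
  w <- C$weights
  expect_equal(max(w), 1)
  expect_true(all(diag(w) == 0))
  expect_equal(w, t(w))
  expect_equal(mean(w[upper.tri(w)] > 0), 0.5, tolerance = 0.05)
  expect_identical(make_synthetic_connectome(10, 0.5, seed = 2)$weights, w)
  expect_error(make_synthetic_connectome(1), "at least 2")
  expect_error(make_synthetic_connectome(4, density = 0), "density")
})

test_that("spectral noise reproduces its programmed power-law slope", {
  set.seed(31)
  x <- spectral_noise(2^14, rate = 1, slope = -0.8)
  expect_equal(sd(x), 1, tolerance = 1e-9)
  fit <- welch_powerlaw(x, fs = 1, band = c(0.005, 0.25))
  expect_equal(fit$beta, -0.8, tolerance = 0.05)
})

test_that("drive and connectome text round-trips preserve values", {
  d <- make_am_alpha(2, duration_s = 1)
  pd <- file.path(tempdir(), "drive.csv")
  write_drive(d, pd)
  d2 <- read_drive(pd)
  expect_equal(d2$values, d$values, tolerance = 1e-12)

  C <- make_synthetic_connectome(4, seed = 8)
  pc <- file.path(tempdir(), "conn.csv")
  write_connectome(C, pc)
  C2 <- read_connectome(pc)
  expect_equal(unname(C2$weights), unname(C$weights), tolerance = 1e-12)
  unlink(c(pd, pc))
})
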