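test_that("the zero-phase band-pass keeps in-band and rejects out-of-band tones", {
  fs <- 1000
  t <- (0:(60 * fs - 1)) / fs
  mid <- 20000:40000
  in_band <- bandpass(sin(2 * pi * 10 * t), 8, 12, fs)
  expect_lt(abs(max(in_band[mid]) - 1), 0.02)
  out_band <- bandpass(sin(2 * pi * 1 * t), 8, 12, fs)
  expect_lt(max(abs(out_band[mid])), 0.01)
  # no phase shift: in-band tone stays aligned with the original
  expect_gt(cor(in_band[mid], sin(2 * pi * 10 * t)[mid]), 0.9999)
  expect_error(bandpass(t, 8, 600, fs), "Nyquist")
})

test_that("the alpha power envelope is flat for constant tones and tracks AM", {
  fs <- 1000
  t <- (0:(200 * fs - 1)) / fs
  env <- alpha_power_envelope(sin(2 * pi * 9 * t), fs)
  expect_lt(sd(env) / mean(env), 0.01)
  # trim removes exactly the configured span from each end
  expect_equal(length(env), 200 * fs - 2 * 50 * fs)
  expect_equal(attr(env, "trimmed"), 50000L)

  slow <- 1 + 0.5 * sin(2 * pi * 0.02 * t)
  env2 <- alpha_power_envelope(slow * sin(2 * pi * 9 * t), fs)
  keep <- 50001:(length(t) - 50000)
  expect_gt(cor(env2, slow[keep]), 0.99)
  expect_error(alpha_power_envelope(sin(2 * pi * 9 * (0:50000) / fs), fs),
               "too short")
})

test_that("the alpha regressor searches seven shifts and matches direct convolution", {
  # short synthetic scene: envelope modulating anti-correlated fMRI
  fs <- 100
  dur <- 400
  t <- (0:(dur * fs - 1)) / fs
  env <- 1 + 0.5 * sin(2 * pi * 0.02 * t)
  hrf <- canonical_hrf(seq(0, 32, by = 1 / fs))
  conv_oracle <- convolve(env, rev(hrf), type = "open")[seq_along(env)] / fs
  scan_idx <- round(((11 + 1:190) * 1.94) * fs) + 1
  target <- bold_series(matrix(-conv_oracle[scan_idx], 1), TR = 1.94)
  reg <- alpha_regressor(env, target, env_rate = fs)
  expect_equal(nrow(reg$by_shift), 7)
  expect_equal(reg$by_shift$shift, -3:3)
  expect_equal(reg$best_shift, 0)
  expect_lt(reg$correlation, -0.999)
  # regressor equals the independent convolution on the scan grid
  expect_equal(as.numeric(reg$regressor), conv_oracle[scan_idx],
               tolerance = 1e-6)
  expect_error(alpha_regressor(rep(1, 1000), target, env_rate = fs),
               "degenerate")
})

test_that("cycle-locked averaging accepts the right cycles and reproduces a sine", {
  fs <- 1000
  t <- (0:(30 * fs - 1)) / fs
  ref <- sin(2 * pi * 10 * t)
  ga <- cycle_locked_average(list(ref = ref), ref, fs)
  # every interior 100 ms cycle accepted
  expect_equal(ga$n_cycles, oracle_cycle_census(ref, fs, 95, 105))
  expect_gt(ga$n_cycles, 290)
  # the averaged waveform is one sine cycle
  ideal <- sin(2 * pi * ga$phase)
  expect_gt(cor(ga$waveforms$ref, ideal), 0.999)

  # jittered cycle lengths: census must match the brute-force oracle
  set.seed(5)
  inst_freq <- 10 + cumsum(rnorm(length(t), sd = 0.02))
  inst_freq <- pmin(pmax(inst_freq, 7), 13)
  jit <- sin(2 * pi * cumsum(inst_freq) / fs)
  ga2 <- cycle_locked_average(list(x = jit), jit, fs)
  expect_equal(ga2$n_cycles, oracle_cycle_census(jit, fs, 95, 105))

  expect_error(cycle_locked_average(list(x = t), sin(2 * pi * 3 * t), fs),
               "no alpha cycles")
})

test_that("phase-binned histograms normalize correctly and match closed forms", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  ref <- sin(2 * pi * 10 * t)
  # constant rate: all six bins equal one
  h <- phase_bin_firing(rep(5, length(t)), ref, fs)
  expect_equal(as.numeric(h), rep(1, 6), tolerance = 1e-12)
  # rate = inverted reference plus offset: compare with segment integrals
  rate <- 2 - ref
  h2 <- phase_bin_firing(rate, ref, fs)
  seg_means <- vapply(0:5, function(k) {
    f <- function(ph) 2 - sin(2 * pi * ph)
    mean(f(seq(k / 6, (k + 1) / 6, length.out = 500))) / 2
  }, numeric(1))
  expect_equal(as.numeric(h2), seg_means, tolerance = 0.01)
  expect_equal(which.max(h2), 5)  # inverted rate peaks in the trough segment
  expect_equal(which.min(h2), 2)
})

test_that("functional connectivity and its similarity behave as Pearson machinery", {
  set.seed(12)
  x <- matrix(rnorm(5 * 600), 5)
  fc <- functional_connectivity(x)
  expect_equal(diag(fc), rep(1, 5))
  expect_lt(mean(abs(fc[lower.tri(fc)])), 0.1)
  expect_equal(fc_similarity(fc, fc), 1)
  # identical series pair correlates at exactly 1
  y <- rbind(x[1, ], x[1, ], x[3, ])
  fc2 <- suppressWarnings(functional_connectivity(y))
  expect_equal(fc2[2, 1], 1)
  # constant region flagged and excluded
  z <- rbind(x[1:2, ], rep(1, 600))
  expect_warning(fc3 <- functional_connectivity(z), "constant")
  expect_true(all(is.na(fc3[3, ])))
  expect_error(functional_connectivity(x[, 1:2]), "3 scans")
})

test_that("sliding windows count and score as expected", {
  set.seed(13)
  x <- matrix(rnorm(4 * 150), 4)
  wins <- sliding_window_fc(x, window = 100, step = 1)
  expect_equal(length(wins), 150 - 100 + 1)
  expect_equal(attr(wins, "starts")[1], 1)
  expect_equal(dynamic_fc_quality(x, x, window = 100), 1)
  expect_error(sliding_window_fc(x[, 1:50], window = 100), "shorter")
  # 100 scans at TR 1.94 s span 194 s
  expect_equal(100 * 1.94, 194)
})

test_that("prediction quality is the mean region-wise correlation", {
  set.seed(14)
  emp <- matrix(rnorm(6 * 500), 6)
  expect_equal(prediction_quality(emp, emp), 1)
  expect_equal(prediction_quality(-emp, emp), -1)
  # noise attenuation follows 1 / sqrt(1 + 1/SNR)
  snr <- 4
  noisy <- emp + matrix(rnorm(6 * 500, sd = sqrt(1 / snr)), 6)
  expect_equal(prediction_quality(noisy, emp), 1 / sqrt(1 + 1 / snr),
               tolerance = 0.03)
  expect_error(prediction_quality(emp[1:2, ], emp), "shape")
})

test_that("Welch spectra are normalized and recover power-law slopes", {
  set.seed(15)
  white <- rnorm(2^13)
  psd <- welch_psd(white, fs = 1)
  expect_equal(sum(psd$power), 1, tolerance = 1e-6)
  fit_w <- welch_powerlaw(white, fs = 1, band = c(0.01, 0.25))
  expect_lt(abs(fit_w$beta), 0.1)
  colored <- spectral_noise(2^14, rate = 1, slope = -0.8)
  fit_c <- welch_powerlaw(colored, fs = 1, band = c(0.005, 0.25))
  expect_equal(fit_c$beta, -0.8, tolerance = 0.05)
  expect_error(welch_powerlaw(white[1:64], fs = 1, band = c(0.001, 0.002)),
               "unresolvable")
})

test_that("DFA recovers known exponents and rejects periodic signals", {
  set.seed(16)
  v_white <- dfa_scalefree_test(rnorm(4096))
  expect_equal(v_white$dfa_exponent, 0.5, tolerance = 0.1)
  expect_true(v_white$is_scale_free)
  # fractional Gaussian noise with H = 0.8 has spectral slope 1 - 2H = -0.6
  fgn <- spectral_noise(4096, rate = 1, slope = -0.6)
  v_fgn <- dfa_scalefree_test(fgn)
  expect_equal(v_fgn$dfa_exponent, 0.8, tolerance = 0.1)
  # strong periodicity: fluctuation function saturates, power law loses
  t <- seq_len(4096)
  periodic <- sin(2 * pi * 0.05 * t) + 0.1 * rnorm(4096)
  v_per <- dfa_scalefree_test(periodic)
  expect_false(v_per$is_scale_free)
  expect_error(dfa_scalefree_test(rnorm(100)), "512")
})

test_that("the moving average matches a brute-force windowed mean", {
  set.seed(17)
  v <- rnorm(500)
  expect_equal(moving_average_rate(v, window_ms = 1, fs = 1000), v)
  expect_equal(moving_average_rate(rep(3, 100), window_ms = 50, fs = 1000),
               rep(3, 100))
  expect_equal(moving_average_rate(v, window_ms = 37, fs = 1000),
               oracle_moving_mean(v, 37), tolerance = 1e-12)
  m <- matrix(rnorm(200), 2)
  mm <- moving_average_rate(m, window_ms = 20, fs = 1000)
  expect_equal(mm[2, ], oracle_moving_mean(m[2, ], 20), tolerance = 1e-12)
})
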