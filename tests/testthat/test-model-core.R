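test_that("default parameters carry the canonical dynamic mean-field values", {
  p <- model_parameters()
  expect_equal(p$I0, 0.382)
  expect_equal(c(p$a_E, p$b_E, p$d_E, p$tau_E, p$W_E), c(310, 125, 0.16, 100, 1))
  expect_equal(c(p$a_I, p$b_I, p$d_I, p$tau_I, p$W_I), c(615, 177, 0.087, 10, 0.7))
  expect_equal(c(p$gamma_E, p$gamma_I), c(6.41e-4, 1.0e-3))
  expect_equal(c(p$w_plus, p$J_NMDA), c(1.4, 0.15))
  expect_error(model_parameters(tau_E = -1), "time constants")
  expect_error(model_parameters(G = -0.1), "G must")
})

test_that("input currents sum background, recurrence, coupling, inhibition and drive", {
  C1 <- structural_connectome(matrix(0, 1, 1))
  p_off <- model_parameters(recurrence_enabled = FALSE)
  cur <- compute_input_currents(region_state(0, 0), 0, C1, 1, p_off)
  expect_equal(cur$I_E, 0.382)
  expect_equal(cur$I_I, 0.7 * 0.382)

  p_on <- model_parameters(recurrence_enabled = TRUE)
  cur <- compute_input_currents(region_state(0.1, 0.05), 0, C1, 1, p_on)
  expect_equal(cur$I_E, 0.382 + 1.4 * 0.15 * 0.1 - 0.05)

  # two coupled nodes: long-range term G * C %*% S_E evaluated by hand
  C2 <- tiny_connectome()
  p2 <- model_parameters(G = 0.5, recurrence_enabled = FALSE)
  cur <- compute_input_currents(region_state(c(0.2, 0.2), c(0, 0)),
                                c(0, 0), C2, c(1, 1), p2)
  expect_equal(cur$I_E, rep(0.382 + 0.5 * 0.2, 2))

  expect_error(compute_input_currents(region_state(0, 0), c(0, 0), C1, 1, p_on),
               "drive sample")
  expect_error(compute_input_currents(region_state(0, 0), NaN, C1, 1, p_on),
               "finite")
})

test_that("f-I curve matches direct evaluation and handles its singularity", {
  p <- model_parameters()
  # removable singularity at a*I = b: limit is 1/d
  expect_equal(firing_rate(125 / 310, "E", p), 1 / 0.16)
  expect_equal(firing_rate(177 / 615, "I", p), 1 / 0.087)
  # direct scalar evaluation away from the singularity
  expect_equal(firing_rate(0.4, "E", p), (310 * 0.4 - 125) / (1 - exp(-0.16 * (310 * 0.4 - 125))),
               tolerance = 1e-12)
  expect_equal(firing_rate(0.4, "E", p), 5.7634, tolerance = 1e-4)
  expect_equal(firing_rate(0.3, "I", p), 7.5 / (1 - exp(-0.6525)), tolerance = 1e-12)
  expect_equal(firing_rate(0.3, "I", p), 15.6491, tolerance = 1e-4)
  # continuity across the singularity
  eps <- 1e-7
  I_star <- 125 / 310
  expect_equal(firing_rate(I_star + eps, "E", p), firing_rate(I_star - eps, "E", p),
               tolerance = 1e-4)
})

test_that("f-I curve is nonnegative and strictly increasing on [-1, 2] nA", {
  p <- model_parameters()
  grid <- seq(-1, 2, by = 0.01)
  for (pop in c("E", "I")) {
    r <- firing_rate(grid, pop, p)
    expect_true(all(r >= 0))
    expect_true(all(diff(r) > 0))
  }
})

test_that("gating derivatives match the stated forms and fixed point", {
  p <- model_parameters()
  # S_E = 1: excitatory derivative is exactly -1/tau_E whatever the rate
  d <- gating_derivatives(region_state(c(1, 1), c(0, 0)), c(0, 500), c(0, 0), p)
  expect_equal(d$dS_E, rep(-1 / 100, 2))
  # S_I = 0, r_I = 10 Hz
  d <- gating_derivatives(region_state(0, 0), 0, 10, p)
  expect_equal(d$dS_I, 1e-3 * 10)
  # inhibitory fixed point S_I* = tau_I * gamma_I * r_I
  r_I <- 7.3
  d <- gating_derivatives(region_state(0, 10 * 1e-3 * r_I), 0, r_I, p)
  expect_equal(d$dS_I, 0)
})

test_that("a state at the network fixed point is left unchanged by step", {
  C <- structural_connectome(matrix(0, 1, 1))
  p <- model_parameters()
  # settle far past the transient, then take the settled state as fixed point
  tr <- simulate_network(C, NULL, J = 1, p = p, duration_s = 60,
                         record_vars = c("S_E", "S_I"))
  n_rec <- length(tr$time)
  st <- region_state(tr$S_E[, n_rec], tr$S_I[, n_rec])
  st2 <- step(st, 0, C, 1, p, dt = 0.1)
  expect_lt(abs(st2$S_E - st$S_E), 1e-8)
  expect_lt(abs(st2$S_I - st$S_I), 1e-8)
})

test_that("noise-free stepping is deterministic", {
  C <- tiny_connectome()
  p <- model_parameters(G = 0.3)
  st <- region_state(c(0.3, 0.6), c(0.1, 0.2))
  a <- step(st, c(0.5, -0.5), C, c(1, 1.2), p)
  b <- step(st, c(0.5, -0.5), C, c(1, 1.2), p)
  expect_identical(a$S_E, b$S_E)
  expect_identical(a$S_I, b$S_I)
})

test_that("the R-level step and the compiled integrator agree exactly", {
  C <- make_synthetic_connectome(3, seed = 2)
  d <- make_am_alpha(3, duration_s = 1)
  p <- model_parameters(G = 0.4, w_BG_E = 0.02, w_BG_I = 0.2,
                        recurrence_enabled = FALSE)
  st <- region_state(rep(0.1, 3), rep(0.1, 3))
  # the 11th record holds the state at the start of step 100
  for (k in 1:100) {
    di <- (k - 1) %/% 10 + 1
    st <- step(st, d$values[, di], C, rep(1, 3), p, dt = 0.1)
  }
  tr <- simulate_network(C, d, J = 1, p = p, duration_s = 0.011,
                         record_vars = c("S_E", "S_I"))
  expect_identical(st$S_E, unname(tr$S_E[, 11]))
  expect_identical(st$S_I, unname(tr$S_I[, 11]))
})

test_that("coarse-step trajectories agree with a fine-step reference oracle", {
  set.seed(42)
  p <- model_parameters(G = 0.2, w_BG_E = 0.05, w_BG_I = 0.2,
                        recurrence_enabled = FALSE)
  C <- tiny_connectome()
  for (i in 1:3) {
    S_E0 <- runif(2, 0, 0.5)
    S_I0 <- runif(2, 0, 0.3)
    drv <- runif(2, -1, 1)
    tr <- simulate_network(C, drive_timeseries(matrix(drv, 2, 600), 1000),
                           J = 1, p = p, duration_s = 0.5, dt = 0.1,
                           init = region_state(S_E0, S_I0),
                           record_every = 1,
                           record_vars = c("S_E", "S_I"))
    # last record holds the state after 4999 steps (t = 499.9 ms), past the
    # gating transients where first-order step error dominates
    n_rec <- length(tr$time)
    ref <- oracle_integrate(S_E0, S_I0, function(t) drv, C$weights,
                            c(1, 1), p, 499.9, dt = 0.01)
    expect_lt(max(abs(tr$S_E[, n_rec] - ref$S_E)), 1e-4)
    expect_lt(max(abs(tr$S_I[, n_rec] - ref$S_I)), 1e-4)
  }
})

test_that("simulate_network enforces its contracts", {
  C <- tiny_connectome()
  p <- model_parameters()
  d <- make_am_alpha(2, duration_s = 2)
  expect_error(simulate_network(C, d, duration_s = 5), "shorter")
  expect_error(simulate_network(C, d, J = c(1, -1)), "positive")
  # zero-duration request: empty trace with valid metadata
  tr0 <- simulate_network(C, NULL, duration_s = 0)
  expect_equal(length(tr0$time), 0)
  expect_equal(ncol(tr0$S_E), 0)
  expect_equal(tr0$record_every, 10L)
})

test_that("gating variables stay bounded for strong random drive", {
  set.seed(7)
  C <- make_synthetic_connectome(4, seed = 5)
  vals <- matrix(rnorm(4 * 5000, sd = 3), 4)
  d <- drive_timeseries(vals, 1000)
  p <- model_parameters(G = 0.5, w_BG_E = 0.3, w_BG_I = 0.6,
                        recurrence_enabled = FALSE)
  tr <- simulate_network(C, d, J = 1, p = p,
                         record_vars = c("S_E", "S_I", "r_E", "r_I"))
  expect_true(all(tr$S_E >= 0 & tr$S_E <= 1))
  expect_true(all(tr$S_I >= 0))
  expect_true(all(tr$r_E >= 0))
  expect_true(all(tr$r_I >= 0))
})

test_that("noise-driven runs reproduce under a fixed seed", {
  C <- tiny_connectome()
  p <- model_parameters(noise_sigma = 0.01)
  a <- simulate_network(C, NULL, duration_s = 2, p = p, seed = 11,
                        record_vars = "S_E")
  b <- simulate_network(C, NULL, duration_s = 2, p = p, seed = 11,
                        record_vars = "S_E")
  cdiff <- simulate_network(C, NULL, duration_s = 2, p = p, seed = 12,
                            record_vars = "S_E")
  expect_identical(a$S_E, b$S_E)
  expect_false(identical(a$S_E, cdiff$S_E))
})

test_that("drive injection uses sample-and-hold over 10 model steps", {
  C <- structural_connectome(matrix(0, 1, 1))
  p <- model_parameters(w_BG_E = 1, recurrence_enabled = FALSE)
  vals <- matrix(seq(0.1, 1, by = 0.1), 1)  # 10 drive samples
  d <- drive_timeseries(vals, 1000)
  tr <- simulate_network(C, d, J = 1, p = p, duration_s = 0.01,
                         record_every = 1, record_vars = "injected")
  # recorded at 10 kHz: each 1 kHz drive value must repeat 10 times
  expect_equal(unname(tr$injected[1, ]), rep(vals[1, ], each = 10))
})
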