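# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately written as plain, slow R so they share no code
# path with the package internals they check.

# analytic signal via direct frequency-domain construction (Hilbert oracle)
oracle_analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# brute-force centered moving mean with partial edge windows
oracle_moving_mean <- function(v, w) {
  n <- length(v)
  h1 <- (w - 1) %/% 2
  h2 <- w - 1 - h1
  sapply(seq_len(n), function(i) mean(v[max(1, i - h1):min(n, i + h2)]))
}

# brute-force rising-zero-crossing cycle census with a length filter (ms)
oracle_cycle_census <- function(ref, fs, lo_ms, hi_ms) {
  s <- sign(ref)
  z <- which(s[-length(s)] < 0 & s[-1] >= 0) + 1
  if (length(z) < 2) return(0)
  lens <- diff(z) / fs * 1000
  sum(lens >= lo_ms & lens <= hi_ms)
}

# reference Euler integration of the gating equations in plain R at a small
# step; independent of both the package's R step() and the C++ core
oracle_integrate <- function(S_E0, S_I0, drive_fun, C, J, p, duration_ms,
                             dt) {
  S_E <- S_E0; S_I <- S_I0
  n_steps <- round(duration_ms / dt)
  phi <- function(I, a, b, d) {
    x <- a * I - b
    ifelse(abs(x) < 1e-12, 1 / d, x / (1 - exp(-d * x)))
  }
  for (k in seq_len(n_steps)) {
    t_ms <- (k - 1) * dt
    drv <- drive_fun(t_ms)
    I_E <- p$W_E * p$I0 + p$G * as.numeric(C %*% S_E) - J * S_I +
      p$w_BG_E * drv
    I_I <- p$W_I * p$I0 - S_I + p$w_BG_I * drv
    if (p$recurrence_enabled) {
      I_E <- I_E + p$w_plus * p$J_NMDA * S_E
      I_I <- I_I + p$J_NMDA * S_E
    }
    r_E <- pmax(phi(I_E, p$a_E, p$b_E, p$d_E), 0)
    r_I <- pmax(phi(I_I, p$a_I, p$b_I, p$d_I), 0)
    S_E <- S_E + dt * (-S_E / p$tau_E + (1 - S_E) * p$gamma_E * r_E)
    S_I <- S_I + dt * (-S_I / p$tau_I + p$gamma_I * r_I)
    S_E <- pmin(pmax(S_E, 0), 1)
    S_I <- pmax(S_I, 0)
  }
  list(S_E = S_E, S_I = S_I)
}

# reference Balloon-Windkessel integration in plain R at a finer step
oracle_bold <- function(x, hp, dt_in, refine = 10) {
  dt <- dt_in / refine
  s <- 0; f <- 1; v <- 1; q <- 1
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    for (k in seq_len(refine)) {
      E <- 1 - (1 - hp$rho)^(1 / f)
      ds <- x[i] - hp$kappa * s - hp$gamma_h * (f - 1)
      df <- s
      dv <- (f - v^(1 / hp$alpha_h)) / hp$tau_h
      dq <- (f * E / hp$rho - q * v^(1 / hp$alpha_h) / v) / hp$tau_h
      s <- s + dt * ds; f <- f + dt * df
      v <- v + dt * dv; q <- q + dt * dq
    }
    out[i] <- 100 * hp$V0 *
      (hp$k1 * (1 - q) + hp$k2 * (1 - q / v) + hp$k3 * (1 - v))
  }
  out
}

# tiny deterministic two-node connectome used in several unit tests
tiny_connectome <- function() {
  structural_connectome(matrix(c(0, 1, 1, 0), 2), normalize = FALSE)
}
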