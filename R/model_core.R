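#' Region state of the network
#'
#' Synaptic gating variables of all regions: `S_E` in \[0, 1\] (slow,
#' NMDA-like) and `S_I >= 0` (fast, GABA-like). Firing rates and input
#' currents are derived quantities, recomputed from the state.
#'
#' @param S_E,S_I numeric vectors of equal length N.
#' @return An object of class `region_state`.
#' @examples
#' region_state(rep(0.1, 4), rep(0.1, 4))
#' @export
region_state <- function(S_E, S_I) {
  if (length(S_E) != length(S_I)) stop("S_E and S_I must have equal length")
  if (!all(is.finite(S_E)) || !all(is.finite(S_I)))
    stop("state variables must be finite")
  if (any(S_E < 0 | S_E > 1)) stop("S_E must lie in [0, 1]")
  if (any(S_I < 0)) stop("S_I must be non-negative")
  structure(list(S_E = as.numeric(S_E), S_I = as.numeric(S_I)),
            class = "region_state")
}

#' Input currents to the excitatory and inhibitory populations
#'
#' Sums the current contributions for every region: background input
#' `W * I0`, optional local excitatory recurrence, long-range excitatory
#' coupling `G * C %*% S_E` (excitatory population only), local feedback
#' inhibition `-J * S_I` (excitatory) / `-S_I` (inhibitory), and the injected
#' drive scaled by `w_BG_E` / `w_BG_I`.
#'
#' @param state a [region_state()].
#' @param drive_sample numeric vector, one injected-current sample per region
#'   (dimensionless z-scored units; scaled internally by the drive weights).
#' @param C a [structural_connectome()].
#' @param J numeric vector of positive feedback-inhibition weights (nA).
#' @param p a [model_parameters()].
#' @return List with numeric vectors `I_E` and `I_I` (nA).
#' @examples
#' p <- model_parameters(recurrence_enabled = FALSE)
#' C <- structural_connectome(matrix(0, 1, 1))
#' compute_input_currents(region_state(0, 0), 0, C, 1, p)
#' @export
compute_input_currents <- function(state, drive_sample, C, J, p) {
  n <- length(state$S_E)
  if (nrow(C$weights) != n) stop("state dimension does not match connectome")
  if (length(drive_sample) != n) stop("drive sample length does not match state")
  if (length(J) != n) stop("J length does not match state")
  if (!all(is.finite(drive_sample))) stop("drive sample must be finite")
  long_range <- p$G * as.numeric(C$weights %*% state$S_E)
  I_E <- p$W_E * p$I0 + long_range - J * state$S_I + p$w_BG_E * drive_sample
  I_I <- p$W_I * p$I0 - state$S_I + p$w_BG_I * drive_sample
  if (p$recurrence_enabled) {
    I_E <- I_E + p$w_plus * p$J_NMDA * state$S_E
    I_I <- I_I + p$J_NMDA * state$S_E
  }
  list(I_E = I_E, I_I = I_I)
}

#' Population transfer function (f-I curve)
#'
#' Converts input current to population firing rate,
#' `r(I) = (a*I - b) / (1 - exp(-d*(a*I - b)))`. The function is total: the
#' removable singularity at `a*I = b` is evaluated by series expansion
#' (limit `1/d`), and the output is non-negative for all finite inputs.
#'
#' @param I input current (nA), vectorized.
#' @param pop `"E"` or `"I"`, selecting the excitatory or inhibitory
#'   parameter triple (a, b, d).
#' @param p a [model_parameters()].
#' @return Firing rate(s) in Hz.
#' @examples
#' firing_rate(125 / 310, "E", model_parameters())  # limit value 1/d_E
#' @export
firing_rate <- function(I, pop = c("E", "I"), p = model_parameters()) {
  pop <- match.arg(pop)
  if (pop == "E") { a <- p$a_E; b <- p$b_E; d <- p$d_E }
  else            { a <- p$a_I; b <- p$b_I; d <- p$d_I }
  x <- a * I - b
  r <- numeric(length(x))
  near <- abs(x) < 1e-6
  # second-order expansion of x / (1 - exp(-d x)) around x = 0
  r[near] <- 1 / d + x[near] / 2 + d * x[near]^2 / 12
  xf <- x[!near]
  r[!near] <- xf / (1 - exp(-d * xf))
  pmax(r, 0)
}

#' Time derivatives of the synaptic gating variables
#'
#' `dS_E/dt = -S_E/tau_E + (1 - S_E) * gamma_E * r_E` and
#' `dS_I/dt = -S_I/tau_I + gamma_I * r_I`, in units of 1/ms with rates in Hz
#' and time constants in ms.
#'
#' @param state a [region_state()].
#' @param r_E,r_I firing rates (Hz), one per region.
#' @param p a [model_parameters()].
#' @return List with vectors `dS_E` and `dS_I` (per ms).
#' @export
gating_derivatives <- function(state, r_E, r_I, p) {
  list(dS_E = -state$S_E / p$tau_E + (1 - state$S_E) * p$gamma_E * r_E,
       dS_I = -state$S_I / p$tau_I + p$gamma_I * r_I)
}

#' Advance the network state by one Euler step
#'
#' One forward-Euler update of the gating variables through
#' [compute_input_currents()], [firing_rate()] and [gating_derivatives()].
#' After the update `S_E` is clamped to \[0, 1\] and `S_I` to \[0, Inf).
#' When `p$noise_sigma > 0`, independent Gaussian noise of that standard
#' deviation (nA) is added to each population's input current (noise-driven
#' control model); draws use R's RNG stream.
#'
#' @inheritParams compute_input_currents
#' @param dt step size in ms (default 0.1, i.e. a 10 kHz model rate).
#' @return The updated `region_state`.
#' @export
step <- function(state, drive_sample, C, J, p, dt = 0.1) {
  if (dt <= 0) stop("dt must be positive")
  cur <- compute_input_currents(state, drive_sample, C, J, p)
  if (p$noise_sigma > 0) {
    n <- length(state$S_E)
    cur$I_E <- cur$I_E + p$noise_sigma * stats::rnorm(n)
    cur$I_I <- cur$I_I + p$noise_sigma * stats::rnorm(n)
  }
  r_E <- firing_rate(cur$I_E, "E", p)
  r_I <- firing_rate(cur$I_I, "I", p)
  d <- gating_derivatives(state, r_E, r_I, p)
  S_E <- state$S_E + dt * d$dS_E
  S_I <- state$S_I + dt * d$dS_I
  if (any(!is.finite(S_E)) || any(!is.finite(S_I))) {
    bad <- which(!is.finite(S_E) | !is.finite(S_I))[1]
    stop(sprintf("integration diverged (non-finite state) in region %d", bad))
  }
  region_state(pmin(pmax(S_E, 0), 1), pmax(S_I, 0))
}

#' Simulate the hybrid network
#'
#' Integrates the coupled gating equations with a fixed-step Euler scheme at
#' `1000 * oversample` Hz (default 10 kHz), holding each drive sample constant
#' for `oversample` consecutive steps (sample-and-hold injection of the 1 kHz
#' drive). State and derived series are recorded every `record_every` steps
#' (default: every 10th step, i.e. at the drive rate of 1 kHz). Per-node mean
#' excitatory firing rates over the *entire* integration (all steps, no
#' decimation or discard) are always returned; they are the quantity feedback
#' inhibition control regulates.
#'
#' @param C a [structural_connectome()].
#' @param drive a [drive_timeseries()] sampled at 1000 Hz, or `NULL` for zero
#'   drive.
#' @param J feedback-inhibition weights, scalar or length-N vector (nA).
#' @param p a [model_parameters()].
#' @param duration_s simulated duration in seconds; must not exceed the drive
#'   duration. Defaults to the drive duration.
#' @param dt Euler step in ms; `1000 / (dt * drive$sample_rate)` must be a
#'   whole number of steps per drive sample.
#' @param init a [region_state()] or `NULL` for the default `S_E = S_I = 0.1`.
#' @param record_every store every `record_every`-th step (default:
#'   one record per drive sample).
#' @param record_vars character subset of
#'   `c("S_E","S_I","r_E","r_I","I_E","I_I","long_range","injected")`;
#'   use `character(0)` to record nothing but the rate summaries (fast path
#'   for feedback-inhibition tuning).
#' @param seed optional integer seed applied before integration when noise is
#'   enabled, for reproducible noise-driven runs.
#' @return An object of class `simulation_trace`: list with `time` (ms, at the
#'   recorded samples), one N x T_rec matrix per recorded variable, `dt`,
#'   `record_every`, `mean_r_E` (per-node whole-series mean, Hz) and
#'   `grand_mean_r_E`.
#' @examples
#' C <- structural_connectome(matrix(0, 1, 1))
#' tr <- simulate_network(C, NULL, J = 1, p = model_parameters(),
#'                        duration_s = 1)
#' tr$grand_mean_r_E
#' @export
simulate_network <- function(C, drive = NULL, J = 1, p = model_parameters(),
                             duration_s = NULL, dt = 0.1, init = NULL,
                             record_every = NULL,
                             record_vars = c("S_E", "S_I", "r_E", "r_I",
                                             "I_E", "I_I", "long_range",
                                             "injected"),
                             seed = NULL) {
  n <- n_regions(C)
  if (is.null(drive)) {
    if (is.null(duration_s))
      stop("duration_s is required when no drive is given")
    drive_values <- matrix(0, n, max(1L, ceiling(duration_s * 1000)))
    drive_rate <- 1000
  } else {
    stopifnot(inherits(drive, "drive_timeseries"))
    if (nrow(drive$values) != n)
      stop("drive region count does not match connectome")
    drive_values <- drive$values
    drive_rate <- drive$sample_rate
    if (is.null(duration_s)) duration_s <- drive_duration(drive)
    if (duration_s > drive_duration(drive) + 1e-9)
      stop("drive is shorter than the requested duration")
  }
  steps_per_sample <- (1000 / drive_rate) / dt
  if (abs(steps_per_sample - round(steps_per_sample)) > 1e-9)
    stop("dt must divide the drive sampling interval exactly")
  steps_per_sample <- as.integer(round(steps_per_sample))
  if (is.null(record_every)) record_every <- steps_per_sample
  n_steps <- as.integer(round(duration_s * 1000 / dt))
  if (length(J) == 1L) J <- rep(J, n)
  if (length(J) != n) stop("J must be scalar or length-N")
  if (any(J <= 0)) stop("J must be positive")
  if (is.null(init)) init <- region_state(rep(0.1, n), rep(0.1, n))
  if (!is.null(seed)) set.seed(seed)

  all_vars <- c("S_E", "S_I", "r_E", "r_I", "I_E", "I_I",
                "long_range", "injected")
  record_vars <- intersect(all_vars, record_vars)

  if (n_steps == 0L) {
    out <- list(time = numeric(0))
    for (v in record_vars) out[[v]] <- matrix(numeric(0), n, 0)
    out$dt <- dt; out$record_every <- as.integer(record_every)
    out$mean_r_E <- rep(NA_real_, n); out$grand_mean_r_E <- NA_real_
    out$region_labels <- C$region_labels
    class(out) <- "simulation_trace"
    return(out)
  }

  res <- simulate_core_cpp(C$weights, drive_values, as.numeric(J),
                           p, dt, steps_per_sample,
                           as.integer(record_every), n_steps,
                           init$S_E, init$S_I,
                           all_vars %in% record_vars)
  out <- list(time = res$time)
  for (v in record_vars) {
    out[[v]] <- res[[v]]
    rownames(out[[v]]) <- C$region_labels
  }
  out$dt <- dt
  out$record_every <- as.integer(record_every)
  out$mean_r_E <- as.numeric(res$mean_r_E)
  names(out$mean_r_E) <- C$region_labels
  out$grand_mean_r_E <- mean(out$mean_r_E)
  out$region_labels <- C$region_labels
  class(out) <- "simulation_trace"
  out
}

#' @export
print.simulation_trace <- function(x, ...) {
  n_rec <- length(x$time)
  cat(sprintf("Simulation trace: %d regions, %d recorded samples (dt = %g ms, every %d steps)\n",
              length(x$mean_r_E), n_rec, x$dt, x$record_every))
  cat(sprintf("  grand mean excitatory rate: %.3f Hz\n", x$grand_mean_r_E))
  cat(sprintf("  recorded variables: %s\n",
              paste(intersect(c("S_E", "S_I", "r_E", "r_I", "I_E", "I_I",
                                "long_range", "injected"), names(x)),
                    collapse = ", ")))
  invisible(x)
}

#' Write recorded trace variables to CSV files
#'
#' One file per recorded variable, named `<prefix>_<var>.csv`, rows = regions.
#'
#' @param trace a `simulation_trace`.
#' @param prefix output path prefix.
#' @return Invisibly, the vector of written paths.
#' @export
write_trace <- function(trace, prefix) {
  vars <- intersect(c("S_E", "S_I", "r_E", "r_I", "I_E", "I_I",
                      "long_range", "injected"), names(trace))
  paths <- character(0)
  for (v in vars) {
    path <- paste0(prefix, "_", v, ".csv")
    utils::write.table(trace[[v]], path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
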