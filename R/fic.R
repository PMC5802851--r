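#' One feedback-inhibition-control weight update
#'
#' Local greedy update of the per-region inhibitory coupling weights:
#' `J_i <- J_i + (r_i - target) * tau`. Regions firing above the set-point
#' get stronger feedback inhibition, regions below get weaker. Results are
#' floored at a small positive value to preserve positivity.
#'
#' @param J numeric vector of current weights (nA).
#' @param node_mean_rates per-region mean excitatory firing rates over the
#'   whole simulated series (Hz).
#' @param tau adaptive tuning factor (> 0), scalar or one value per region.
#' @param target_rate set-point in Hz (default 3.06, the isolated-node mean
#'   rate of the original model).
#' @return Updated weight vector.
#' @examples
#' fic_update(rep(1, 3), c(4.06, 3.06, 2.06), tau = 0.005)
#' @export
fic_update <- function(J, node_mean_rates, tau, target_rate = 3.06) {
  if (!is.numeric(tau) || !all(is.finite(tau)) || any(tau <= 0) ||
      !(length(tau) %in% c(1L, length(J))))
    stop("tau must be positive and finite (scalar or one value per region)")
  if (!all(is.finite(node_mean_rates)))
    stop("node mean rates must be finite")
  if (length(J) != length(node_mean_rates))
    stop("J and node_mean_rates must have equal length")
  pmax(J + (node_mean_rates - target_rate) * tau, 1e-6)
}

#' Adapt the FIC tuning factor between iterations
#'
#' Secant-style step-size adaptation. If the global rate error did not
#' improve relative to the previous iteration, the tuning factor is halved.
#' Otherwise it is set to the magnitude ratio of the total weight change to
#' the global rate change,
#' `tau = |sum_i (J_i^{k-1} - J_i^k)| / |rhat_{k-1} - rhat_k|`.
#' Degenerate steps (no weight change, or no rate change) keep the previous
#' tuning factor.
#'
#' @param J_prev,J_curr weight vectors of the previous and current iteration.
#' @param rhat_prev,rhat_curr global mean excitatory rates (Hz) of those
#'   iterations.
#' @param tau_curr tuning factor used in the current iteration.
#' @param target_rate set-point (Hz).
#' @return The tuning factor for the next iteration.
#' @export
adapt_tau <- function(J_prev, J_curr, rhat_prev, rhat_curr, tau_curr,
                      target_rate = 3.06) {
  if (abs(rhat_curr - target_rate) >= abs(rhat_prev - target_rate))
    return(0.5 * tau_curr)
  dJ <- sum(J_prev - J_curr)
  dr <- rhat_prev - rhat_curr
  if (dr == 0 || dJ == 0) return(tau_curr)
  abs(dJ) / abs(dr)
}

#' Feedback inhibition control tuning
#'
#' Iteratively tunes the per-region inhibitory weights `J_i` so that every
#' excitatory population attains a whole-series mean firing rate close to the
#' set-point. Each iteration simulates the entire series, computes per-region
#' mean rates and updates `J` via [fic_update()]. After `max_iterations`
#' iterations the weights of the iteration with minimal global error
#' `|rhat_k - target|` are selected. Non-stationary injected drive makes
#' whole-series rate means essential; a short transient cannot stand in for
#' them.
#'
#' Two tuning-factor adaptations are available. The default `"node"` mode
#' keeps one factor per region, set to the secant magnitude
#' `|dJ_i / dr_i|` of that region's last step (clipped to
#' `[1e-4, tau_cap]`) and halved whenever the region's rate error changes
#' sign (overshoot). Because the rate-versus-weight sensitivity varies
#' strongly across regions of a heterogeneous connectome, per-region factors
#' converge where a single shared factor oscillates. The `"global"` mode is
#' that shared-factor variant — one secant-adapted factor for all regions via
#' [adapt_tau()], halved when the global error fails to improve.
#'
#' @param C a [structural_connectome()].
#' @param drive a [drive_timeseries()] or `NULL` for zero drive.
#' @param p a [model_parameters()].
#' @param duration_s simulated seconds per iteration (defaults to the drive
#'   duration).
#' @param target_rate set-point (Hz), default 3.06.
#' @param max_iterations number of tuning iterations (default 12).
#' @param tau0 initial tuning factor (default 0.005).
#' @param J0 initial weights (default all 1).
#' @param global_J logical; if `TRUE`, run the no-FIC control variant that
#'   varies a single global inhibitory weight (the mean update is applied to
#'   all regions identically).
#' @param tau_mode `"node"` (per-region adaptive factors, default) or
#'   `"global"` (one shared factor adapted via [adapt_tau()]).
#' @param tau_cap upper clip for per-region tuning factors (nA per Hz).
#' @param dt Euler step (ms).
#' @param seed optional seed forwarded to each simulation (noise-driven runs).
#' @return List of class `fic_result`: `J` (selected weights),
#'   `selected_iteration`, `node_rates` (per-region mean rates of the
#'   selected iteration), and `diagnostics`, a data.frame with one row per
#'   iteration (mean tau, global mean rate, global error, per-node max
#'   error).
#' @examples
#' C <- structural_connectome(matrix(0, 2, 2))
#' fit <- fic_tune(C, NULL, model_parameters(), duration_s = 5,
#'                 max_iterations = 3)
#' fit$J
#' @export
fic_tune <- function(C, drive, p, duration_s = NULL, target_rate = 3.06,
                     max_iterations = 12, tau0 = 0.005, J0 = NULL,
                     global_J = FALSE, tau_mode = c("node", "global"),
                     tau_cap = 0.5, dt = 0.1, seed = NULL) {
  tau_mode <- match.arg(tau_mode)
  n <- n_regions(C)
  J <- if (is.null(J0)) rep(1, n) else rep(J0, length.out = n)
  tau <- rep(tau0, if (tau_mode == "node" && !global_J) n else 1)
  J_hist <- list()
  rate_hist <- list()
  rhat <- numeric(0)
  tau_hist <- numeric(0)

  for (k in seq_len(max_iterations)) {
    tr <- tryCatch(
      simulate_network(C, drive, J = J, p = p, duration_s = duration_s,
                       dt = dt, record_vars = character(0), seed = seed),
      error = function(e)
        stop(sprintf("FIC iteration %d: simulation failed (%s)", k,
                     conditionMessage(e)))
    )
    J_hist[[k]] <- J
    rate_hist[[k]] <- tr$mean_r_E
    rhat[k] <- tr$grand_mean_r_E
    tau_hist[k] <- mean(tau)

    if (k < max_iterations) {
      if (k >= 2L) {
        if (length(tau) > 1L) {
          ek <- rate_hist[[k]] - target_rate
          ep <- rate_hist[[k - 1]] - target_rate
          dJ <- J_hist[[k - 1]] - J_hist[[k]]
          dr <- rate_hist[[k - 1]] - rate_hist[[k]]
          sec <- abs(dr) > 1e-6 & dJ != 0
          tau[sec] <- pmin(pmax(abs(dJ[sec] / dr[sec]), 1e-4), tau_cap)
          flip <- sign(ek) != sign(ep)
          tau[flip] <- 0.5 * tau[flip]
        } else {
          tau <- adapt_tau(J_hist[[k - 1]], J_hist[[k]], rhat[k - 1],
                           rhat[k], tau, target_rate)
        }
      }
      err <- rate_hist[[k]] - target_rate
      if (global_J) err <- rep(mean(err), n)
      J <- fic_update(J, target_rate + err, tau, target_rate)
    }
  }

  global_err <- abs(rhat - target_rate)
  sel <- which.min(global_err)
  diagnostics <- data.frame(
    iteration = seq_len(max_iterations),
    tau = tau_hist,
    global_mean_rate = rhat,
    global_error = global_err,
    max_node_error = vapply(rate_hist,
                            function(r) max(abs(r - target_rate)), numeric(1))
  )
  structure(list(J = J_hist[[sel]],
                 selected_iteration = sel,
                 node_rates = rate_hist[[sel]],
                 target_rate = target_rate,
                 diagnostics = diagnostics),
            class = "fic_result")
}

#' @export
print.fic_result <- function(x, ...) {
  cat(sprintf("FIC tuning: selected iteration %d of %d\n",
              x$selected_iteration, nrow(x$diagnostics)))
  cat(sprintf("  global mean rate %.4f Hz (target %g), max node error %.4f Hz\n",
              x$diagnostics$global_mean_rate[x$selected_iteration],
              x$target_rate,
              x$diagnostics$max_node_error[x$selected_iteration]))
  invisible(x)
}

#' Write FIC diagnostics and weights
#'
#' Writes `<prefix>_diagnostics.csv` (one row per iteration),
#' `<prefix>_J.csv` (selected weights) and `<prefix>_summary.json`.
#'
#' @param fit a `fic_result`.
#' @param prefix output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_fic <- function(fit, prefix) {
  p1 <- paste0(prefix, "_diagnostics.csv")
  p2 <- paste0(prefix, "_J.csv")
  p3 <- paste0(prefix, "_summary.json")
  utils::write.csv(fit$diagnostics, p1, row.names = FALSE)
  utils::write.csv(data.frame(region = names(fit$node_rates), J = fit$J,
                              mean_rate = fit$node_rates), p2,
                   row.names = FALSE)
  jsonlite::write_json(
    list(selected_iteration = fit$selected_iteration,
         target_rate = fit$target_rate,
         global_mean_rate =
           fit$diagnostics$global_mean_rate[fit$selected_iteration]),
    p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
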