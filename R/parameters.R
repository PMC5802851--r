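#' Model parameters for the hybrid dynamic mean-field network
#'
#' Constructs the full parameter set of the coupled excitatory/inhibitory
#' neural-mass equations. Defaults are the canonical dynamic mean-field values
#' (currents in nA, rates in Hz, time in ms): with these values an isolated
#' node with local recurrence enabled and unit inhibitory weight settles to a
#' mean excitatory firing rate close to 3.06 Hz, the set-point used by
#' feedback inhibition control.
#'
#' @param W_E,W_I dimensionless scalings of the effective external input for
#'   the excitatory and inhibitory population.
#' @param I0 overall effective external input (nA).
#' @param a_E,a_I gain of the excitatory/inhibitory f-I curve (nC^-1).
#' @param b_E,b_I threshold of the f-I curve (Hz).
#' @param d_E,d_I curvature constant of the f-I curve (s).
#' @param tau_E,tau_I synaptic gating time constants (ms); NMDA-like slow
#'   excitation vs GABA-like fast inhibition.
#' @param gamma_E,gamma_I kinetic rate parameters (per ms per Hz).
#' @param w_plus local excitatory recurrence weight (dimensionless).
#' @param J_NMDA excitatory synaptic coupling (nA).
#' @param G global long-range coupling scaling factor (dimensionless, >= 0).
#' @param w_BG_E,w_BG_I scalings applied to the injected drive current for the
#'   excitatory and inhibitory population (dimensionless, >= 0).
#' @param noise_sigma standard deviation of additive Gaussian current noise
#'   per integration step (nA); 0 disables noise. Used by the noise-driven
#'   control model only.
#' @param recurrence_enabled logical; include the local excitatory recurrence
#'   terms `w_plus * J_NMDA * S_E` (E->E) and `J_NMDA * S_E` (E->I). The
#'   drive-injection reading of the model omits them; the noise-driven
#'   original model and the isolated-node calibration require them.
#'
#' @return An object of class `model_parameters` (a validated list).
#' @examples
#' p <- model_parameters()
#' p$I0
#' @export
model_parameters <- function(W_E = 1, W_I = 0.7, I0 = 0.382,
                             a_E = 310, b_E = 125, d_E = 0.16,
                             a_I = 615, b_I = 177, d_I = 0.087,
                             tau_E = 100, tau_I = 10,
                             gamma_E = 6.41e-4, gamma_I = 1.0e-3,
                             w_plus = 1.4, J_NMDA = 0.15,
                             G = 0, w_BG_E = 0, w_BG_I = 0,
                             noise_sigma = 0, recurrence_enabled = TRUE) {
  p <- list(W_E = W_E, W_I = W_I, I0 = I0,
            a_E = a_E, b_E = b_E, d_E = d_E,
            a_I = a_I, b_I = b_I, d_I = d_I,
            tau_E = tau_E, tau_I = tau_I,
            gamma_E = gamma_E, gamma_I = gamma_I,
            w_plus = w_plus, J_NMDA = J_NMDA,
            G = G, w_BG_E = w_BG_E, w_BG_I = w_BG_I,
            noise_sigma = noise_sigma,
            recurrence_enabled = isTRUE(recurrence_enabled))
  num <- p[setdiff(names(p), "recurrence_enabled")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))))
    stop("all model parameters must be finite numeric scalars")
  if (tau_E <= 0 || tau_I <= 0) stop("time constants must be positive")
  if (a_E <= 0 || a_I <= 0) stop("f-I gains must be positive")
  if (G < 0) stop("G must be non-negative")
  if (w_BG_E < 0 || w_BG_I < 0) stop("drive scalings must be non-negative")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Hybrid network model parameters\n")
  cat(sprintf("  I0 = %g nA, W_E = %g, W_I = %g\n", x$I0, x$W_E, x$W_I))
  cat(sprintf("  f-I: a_E = %g, b_E = %g, d_E = %g | a_I = %g, b_I = %g, d_I = %g\n",
              x$a_E, x$b_E, x$d_E, x$a_I, x$b_I, x$d_I))
  cat(sprintf("  gating: tau_E = %g ms, tau_I = %g ms, gamma_E = %g, gamma_I = %g\n",
              x$tau_E, x$tau_I, x$gamma_E, x$gamma_I))
  cat(sprintf("  coupling: G = %g, w_plus = %g, J_NMDA = %g, recurrence %s\n",
              x$G, x$w_plus, x$J_NMDA,
              if (x$recurrence_enabled) "on" else "off"))
  cat(sprintf("  drive: w_BG_E = %g, w_BG_I = %g, noise_sigma = %g nA\n",
              x$w_BG_E, x$w_BG_I, x$noise_sigma))
  invisible(x)
}

#' Balloon-Windkessel hemodynamic parameters
#'
#' Constants of the four-state hemodynamic model (vasodilatory signal s,
#' inflow f, venous volume v, deoxyhemoglobin q) and the static nonlinear
#' BOLD readout. Defaults are the canonical set used throughout the dynamic
#' mean-field model family.
#'
#' @param kappa rate of vasodilatory signal decay (s^-1).
#' @param gamma_h rate of flow-dependent autoregulation (s^-1).
#' @param tau_h hemodynamic transit time (s).
#' @param alpha_h Grubb vessel stiffness exponent.
#' @param rho resting oxygen extraction fraction.
#' @param V0 resting venous blood volume fraction.
#' @param k1,k2,k3 BOLD signal coefficients; defaults `7*rho`, `2`,
#'   `2*rho - 0.2`.
#' @return An object of class `hemodynamic_parameters`.
#' @examples
#' hemodynamic_parameters()$tau_h
#' @export
hemodynamic_parameters <- function(kappa = 0.65, gamma_h = 0.41, tau_h = 0.98,
                                   alpha_h = 0.32, rho = 0.34, V0 = 0.02,
                                   k1 = 7 * rho, k2 = 2, k3 = 2 * rho - 0.2) {
  p <- list(kappa = kappa, gamma_h = gamma_h, tau_h = tau_h,
            alpha_h = alpha_h, rho = rho, V0 = V0, k1 = k1, k2 = k2, k3 = k3)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))))
    stop("all hemodynamic parameters must be finite numeric scalars")
  if (any(unlist(p[c("kappa", "gamma_h", "tau_h", "alpha_h", "rho", "V0")]) <= 0))
    stop("hemodynamic model constants must be positive")
  structure(p, class = "hemodynamic_parameters")
}

#' @export
print.hemodynamic_parameters <- function(x, ...) {
  cat("Balloon-Windkessel parameters\n")
  cat(sprintf("  kappa = %g /s, gamma = %g /s, tau = %g s, alpha = %g\n",
              x$kappa, x$gamma_h, x$tau_h, x$alpha_h))
  cat(sprintf("  rho = %g, V0 = %g, k1 = %g, k2 = %g, k3 = %g\n",
              x$rho, x$V0, x$k1, x$k2, x$k3))
  invisible(x)
}
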