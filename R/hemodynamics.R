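#' Balloon-Windkessel BOLD forward model
#'
#' Transforms excitatory synaptic gating into a BOLD signal through the
#' four-state hemodynamic model: neural activity drives a vasodilatory
#' signal, which drives blood inflow; volume and deoxyhemoglobin follow
#' through the balloon equations, and BOLD is a static nonlinear function of
#' volume and deoxyhemoglobin content. Neurovascular coupling is mediated
#' exclusively by excitatory synaptic activity. Integration is explicit Euler
#' at the input sampling interval (1 ms for the canonical 1 kHz gating
#' series).
#'
#' @param S_E N x T matrix of excitatory synaptic gating (or a
#'   `simulation_trace` whose `S_E` is used), sampled at `sample_rate`.
#' @param hp a [hemodynamic_parameters()].
#' @param sample_rate input sampling rate in Hz (default 1000).
#' @return N x T numeric matrix of BOLD signal (percent-signal-change units)
#'   at the input rate.
#' @examples
#' b <- balloon_windkessel(matrix(0.16, 1, 2000))
#' @export
balloon_windkessel <- function(S_E, hp = hemodynamic_parameters(),
                               sample_rate = 1000) {
  if (inherits(S_E, "simulation_trace")) {
    if (is.null(S_E$S_E)) stop("trace does not contain a recorded S_E series")
    S_E <- S_E$S_E
  }
  S_E <- as.matrix(S_E)
  if (!all(is.finite(S_E))) stop("S_E must be finite")
  balloon_windkessel_cpp(S_E, hp, 1 / sample_rate)
}

#' Downsample a 1 kHz BOLD series to scanner resolution
#'
#' Keeps every `TR * rate`-th sample (every 1940th at the default TR of
#' 1.94 s) and then discards the first `discard` retained scans so the
#' hemodynamic state has stabilized. No additional anti-alias filtering is
#' applied: the hemodynamic model itself strongly attenuates frequencies
#' above ~0.15 Hz.
#'
#' @param bold_full N x T matrix at `sample_rate` Hz.
#' @param TR repetition time in seconds (default 1.94).
#' @param discard number of initial scans to drop (default 11, i.e. 21.34 s).
#' @param sample_rate input rate in Hz (default 1000).
#' @return An object of class `bold_series`: list with `values` (N x M
#'   matrix), `TR` and `discarded_scans`. Scan `m` (1-based) corresponds to
#'   simulation time `(discard + m) * TR` seconds.
#' @export
downsample_to_TR <- function(bold_full, TR = 1.94, discard = 11,
                             sample_rate = 1000) {
  bold_full <- as.matrix(bold_full)
  stride <- as.integer(round(TR * sample_rate))
  idx <- seq(stride, ncol(bold_full), by = stride)
  if (length(idx) <= discard + 1L)
    stop("series too short: fewer than ", discard + 2L, " scans available")
  idx <- idx[-seq_len(discard)]
  structure(list(values = bold_full[, idx, drop = FALSE],
                 TR = TR, discarded_scans = as.integer(discard)),
            class = "bold_series")
}

#' Construct a BOLD series container directly
#'
#' @param values N x M matrix (regions x scans).
#' @param TR repetition time (s).
#' @param discarded_scans scans dropped before the first stored one.
#' @return A `bold_series`.
#' @export
bold_series <- function(values, TR = 1.94, discarded_scans = 11L) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("BOLD values must be finite")
  structure(list(values = values, TR = TR,
                 discarded_scans = as.integer(discarded_scans)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("BOLD series: %d regions x %d scans, TR = %g s (%d initial scans discarded)\n",
              nrow(x$values), ncol(x$values), x$TR, x$discarded_scans))
  invisible(x)
}

#' Read / write BOLD series as CSV (regions x scans, no header)
#' @param path file path.
#' @param TR,discarded_scans metadata to attach on read.
#' @return `read_bold` returns a `bold_series`; `write_bold` invisibly
#'   returns `path`.
#' @export
read_bold <- function(path, TR = 1.94, discarded_scans = 11L) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  bold_series(unname(m), TR, discarded_scans)
}

#' @rdname read_bold
#' @param bold a `bold_series`.
#' @export
write_bold <- function(bold, path) {
  utils::write.table(bold$values, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Full forward pipeline: gating trace to scanner-resolution BOLD
#'
#' Convenience wrapper: [balloon_windkessel()] on the trace's `S_E` followed
#' by [downsample_to_TR()].
#'
#' @param trace a `simulation_trace` with recorded `S_E` at 1 kHz.
#' @inheritParams downsample_to_TR
#' @param hp a [hemodynamic_parameters()].
#' @return A `bold_series`.
#' @export
trace_to_bold <- function(trace, hp = hemodynamic_parameters(), TR = 1.94,
                          discard = 11) {
  rate <- 1000 / (trace$dt * trace$record_every)
  full <- balloon_windkessel(trace, hp, sample_rate = rate)
  downsample_to_TR(full, TR = TR, discard = discard, sample_rate = rate)
}
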