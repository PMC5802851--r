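#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift — essential for
#' cycle-locked averaging. The default `order = 2` per pass yields a
#' 4th-order effective response.
#'
#' @param x numeric vector, or matrix filtered row-wise.
#' @param lo,hi band edges in Hz, `lo < hi <` Nyquist.
#' @param fs sampling rate (Hz).
#' @param order Butterworth order per pass.
#' @return Filtered series of the same shape. Edge spans of roughly one
#'   filter settling time remain distorted; downstream analyses trim them.
#' @examples
#' t <- seq(0, 10, by = 1e-3)
#' y <- bandpass(sin(2 * pi * 10 * t), 8, 12, 1000)
#' @export
bandpass <- function(x, lo, hi, fs, order = 2) {
  nyq <- fs / 2
  if (!(lo < hi && hi < nyq)) stop("require lo < hi < Nyquist frequency")
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  filt1 <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.matrix(x)) t(apply(x, 1, filt1)) else filt1(x)
}

# analytic signal via frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous alpha-band power envelope
#'
#' Band-pass filters the series (default 8-10 Hz, the band used for
#' alpha-power time courses), takes the magnitude of the analytic signal
#' (Hilbert transform), and discards the first and last `trim_s` seconds to
#' control for filter and Hilbert edge effects.
#'
#' @param x numeric vector or matrix (rows = regions).
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges (Hz).
#' @param trim_s seconds trimmed from each end (default 50).
#' @return For a vector input, the envelope with attribute `"trimmed"` = the
#'   number of samples removed from each end; for a matrix, one row per
#'   region.
#' @export
alpha_power_envelope <- function(x, fs = 1000, lo = 8, hi = 10, trim_s = 50) {
  len <- if (is.matrix(x)) ncol(x) else length(x)
  if (len / fs <= 2 * trim_s + 20)
    stop("series too short for the requested edge trim (need > ",
         2 * trim_s + 20, " s)")
  filtered <- bandpass(x, lo, hi, fs)
  trim <- as.integer(round(trim_s * fs))
  keep <- (trim + 1):(len - trim)
  env1 <- function(v) Mod(analytic_signal(v))[keep]
  out <- if (is.matrix(filtered)) t(apply(filtered, 1, env1)) else env1(filtered)
  attr(out, "trimmed") <- trim
  out
}

#' Canonical double-gamma hemodynamic response function
#'
#' @param t time points in seconds.
#' @param peak_delay,undershoot_delay gamma shape parameters (s); response
#'   peaks near 6 s with an undershoot near 16 s.
#' @param undershoot_ratio peak-to-undershoot amplitude ratio.
#' @return HRF values, peak normalized to 1.
#' @export
canonical_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                          undershoot_ratio = 6) {
  h <- stats::dgamma(t, peak_delay, 1) -
    stats::dgamma(t, undershoot_delay, 1) / undershoot_ratio
  h / max(h)
}

#' Alpha regressor: HRF-convolved power envelope as an fMRI predictor
#'
#' Convolves an alpha-power envelope with the canonical HRF, samples the
#' result on the scan grid, and searches integer shifts of up to
#' `max_shift` scans in both directions (7 candidates by default) for the
#' shift with the most negative mean region-wise correlation with the given
#' fMRI series — the sign convention reflecting the empirical
#' anti-correlation between alpha power and BOLD.
#'
#' @param envelope numeric vector (a single envelope applied to all regions)
#'   or matrix with one row per region, sampled at `env_rate`.
#' @param bold a [bold_series()] (simulated or empirical).
#' @param env_rate envelope sampling rate (Hz).
#' @param t_start time (s) of the envelope's first sample on the simulation
#'   clock (e.g. the trim offset of [alpha_power_envelope()]).
#' @param max_shift maximum shift magnitude in scans (default 3).
#' @return List: `regressor` (values at the unshifted scan grid),
#'   `best_shift` (scans), `correlation` (mean region-wise r at the best
#'   shift), `by_shift` (data.frame of all candidates).
#' @export
alpha_regressor <- function(envelope, bold, env_rate = 1000, t_start = 0,
                            max_shift = 3) {
  env <- if (is.matrix(envelope)) envelope else matrix(envelope, nrow = 1)
  if (max(apply(env, 1, stats::sd)) == 0)
    stop("degenerate input: constant envelope has no correlation structure")
  hrf <- canonical_hrf(seq(0, 32, by = 1 / env_rate))
  conv1 <- function(v) {
    n <- length(v) + length(hrf) - 1L
    re <- Re(stats::fft(stats::fft(c(v, numeric(n - length(v)))) *
                          stats::fft(c(hrf, numeric(n - length(hrf)))),
                        inverse = TRUE)) / n
    re[seq_along(v)] / env_rate
  }
  conv <- t(apply(env, 1, conv1))

  TR <- bold$TR
  n_scans <- ncol(bold$values)
  scan_times <- (bold$discarded_scans + seq_len(n_scans)) * TR
  grid_idx <- function(shift) {
    idx <- round((scan_times - t_start + shift * TR) * env_rate) + 1L
    ifelse(idx >= 1L & idx <= ncol(conv), idx, NA_integer_)
  }
  shifts <- seq(-max_shift, max_shift)
  res <- lapply(shifts, function(s) {
    idx <- grid_idx(s)
    ok <- !is.na(idx)
    if (sum(ok) < 3) return(NA_real_)
    reg <- conv[, idx[ok], drop = FALSE]
    mean(vapply(seq_len(n_scans_regions <- nrow(bold$values)), function(i) {
      r <- reg[min(i, nrow(reg)), ]
      if (stats::sd(r) == 0) return(NA_real_)
      stats::cor(r, bold$values[i, ok])
    }, numeric(1)), na.rm = TRUE)
  })
  by_shift <- data.frame(shift = shifts, mean_r = unlist(res))
  best <- which.min(by_shift$mean_r)
  idx0 <- grid_idx(0)
  list(regressor = conv[, idx0[!is.na(idx0)], drop = FALSE],
       best_shift = shifts[best],
       correlation = by_shift$mean_r[best],
       by_shift = by_shift)
}

# rising zero crossings of a reference series; returns cycle start indices
rising_crossings <- function(ref) {
  s <- sign(ref)
  which(s[-length(s)] < 0 & s[-1] >= 0) + 1L
}

# accepted alpha cycles: list of (start, end) index pairs with length filter
accepted_cycles <- function(ref, fs, accept_ms) {
  z <- rising_crossings(ref)
  if (length(z) < 2) return(list())
  starts <- z[-length(z)]
  ends <- z[-1] - 1L
  len_ms <- (ends - starts + 1L) / fs * 1000
  keep <- len_ms >= accept_ms[1] & len_ms <= accept_ms[2]
  Map(c, starts[keep], ends[keep])
}

#' Grand-average waveforms time-locked to alpha cycles
#'
#' Detects rising zero crossings of the (band-passed, 8-12 Hz) alpha
#' reference, keeps cycles whose length falls inside the acceptance window
#' (default 95-105 ms, i.e. near-10 Hz cycles), resamples each accepted
#' cycle of every supplied series to a common length, and averages over
#' cycles (and over regions for matrix series).
#'
#' @param series named list of numeric vectors or N x T matrices, all
#'   sample-aligned with `alpha_ref`.
#' @param alpha_ref alpha-band reference series (vector).
#' @param fs sampling rate (Hz).
#' @param accept_ms length-2 acceptance window in ms.
#' @param out_len number of samples of the common resampled cycle.
#' @return Object of class `grand_average`: list with `waveforms` (named
#'   list of length-`out_len` vectors), `phase` (0-1 cycle fraction),
#'   `n_cycles`, `accept_ms`.
#' @export
cycle_locked_average <- function(series, alpha_ref, fs = 1000,
                                 accept_ms = c(95, 105), out_len = 101) {
  cyc <- accepted_cycles(alpha_ref, fs, accept_ms)
  if (length(cyc) == 0)
    stop("no alpha cycles within the acceptance window")
  phase <- seq(0, 1, length.out = out_len)
  avg_one <- function(x) {
    m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
    acc <- numeric(out_len)
    cnt <- 0L
    for (cy in cyc) {
      seg_idx <- cy[1]:cy[2]
      xin <- seq(0, 1, length.out = length(seg_idx))
      for (i in seq_len(nrow(m))) {
        acc <- acc + stats::approx(xin, m[i, seg_idx], xout = phase)$y
        cnt <- cnt + 1L
      }
    }
    acc / cnt
  }
  structure(list(waveforms = lapply(series, avg_one),
                 phase = phase, n_cycles = length(cyc),
                 accept_ms = accept_ms),
            class = "grand_average")
}

#' @export
print.grand_average <- function(x, ...) {
  cat(sprintf("Grand-average waveforms over %d alpha cycles (%g-%g ms): %s\n",
              x$n_cycles, x$accept_ms[1], x$accept_ms[2],
              paste(names(x$waveforms), collapse = ", ")))
  invisible(x)
}

#' Phase-binned firing-rate histogram
#'
#' Divides each accepted alpha cycle into `n_bins` equal segments, averages
#' the firing rate within each segment, normalizes by that cycle's mean
#' rate, and averages the normalized profiles across cycles (and regions).
#' A flat profile of 1.0 means firing is phase-independent; the hybrid
#' model's signature is a maximum in the trough segment and a minimum in
#' the peak segment of the alpha cycle.
#'
#' @param rates numeric vector or N x T matrix of firing rates aligned with
#'   `alpha_ref`.
#' @param alpha_ref alpha-band reference (vector); cycles start at rising
#'   zero crossings, so the peak falls in the first half and the trough in
#'   the second half of the cycle.
#' @param fs sampling rate (Hz).
#' @param n_bins number of phase bins (default 6).
#' @param accept_ms cycle-length acceptance window (ms).
#' @return Numeric vector of `n_bins` normalized mean rates, with attribute
#'   `"n_cycles"` (cycles used) and `"skipped"` (cycles dropped for
#'   zero mean rate).
#' @export
phase_bin_firing <- function(rates, alpha_ref, fs = 1000, n_bins = 6,
                             accept_ms = c(95, 105)) {
  cyc <- accepted_cycles(alpha_ref, fs, accept_ms)
  if (length(cyc) == 0)
    stop("no alpha cycles within the acceptance window")
  m <- if (is.matrix(rates)) rates else matrix(rates, nrow = 1)
  acc <- numeric(n_bins)
  used <- 0L
  skipped <- 0L
  for (cy in cyc) {
    idx <- cy[1]:cy[2]
    bins <- cut(seq_along(idx), n_bins, labels = FALSE)
    for (i in seq_len(nrow(m))) {
      seg <- m[i, idx]
      mu <- mean(seg)
      if (mu == 0) { skipped <- skipped + 1L; next }
      acc <- acc + tapply(seg, bins, mean) / mu
      used <- used + 1L
    }
  }
  if (used == 0L) stop("all cycles had zero mean rate")
  out <- as.numeric(acc / used)
  attr(out, "n_cycles") <- used
  attr(out, "skipped") <- skipped
  out
}

#' Static functional connectivity
#'
#' Pairwise Pearson correlation matrix of regional BOLD series. Regions with
#' constant series get `NA` rows/columns (reported via a warning) and are
#' excluded from similarity computations.
#'
#' @param bold a [bold_series()] or N x M matrix (rows = regions).
#' @return N x N correlation matrix.
#' @export
functional_connectivity <- function(bold) {
  v <- if (inherits(bold, "bold_series")) bold$values else as.matrix(bold)
  if (ncol(v) < 3) stop("need at least 3 scans for FC")
  const <- apply(v, 1, stats::sd) == 0
  if (any(const))
    warning(sum(const), " constant region series excluded from FC")
  fc <- suppressWarnings(stats::cor(t(v)))
  fc[const, ] <- NA
  fc[, const] <- NA
  fc
}

#' Similarity of two FC matrices
#'
#' Pearson correlation of the strictly-subdiagonal entries of two
#' functional-connectivity matrices, the standard scalar summary of FC
#' agreement.
#'
#' @param A,B square matrices of equal size.
#' @return Correlation coefficient.
#' @export
fc_similarity <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("FC matrices must have equal dimensions")
  a <- A[lower.tri(A)]
  b <- B[lower.tri(B)]
  ok <- is.finite(a) & is.finite(b)
  stats::cor(a[ok], b[ok])
}

#' Sliding-window functional connectivity
#'
#' FC computed in a window slid across the scan series (defaults: 100 scans
#' = 194 s at TR 1.94 s, step 1 scan).
#'
#' @param bold a [bold_series()] or matrix.
#' @param window window length in scans.
#' @param step step width in scans.
#' @return List of FC matrices, one per window position; attribute
#'   `"starts"` holds the first scan index of each window.
#' @export
sliding_window_fc <- function(bold, window = 100, step = 1) {
  v <- if (inherits(bold, "bold_series")) bold$values else as.matrix(bold)
  if (ncol(v) < window) stop("series shorter than the window")
  starts <- seq(1, ncol(v) - window + 1, by = step)
  out <- lapply(starts, function(s)
    functional_connectivity(v[, s:(s + window - 1), drop = FALSE]))
  attr(out, "starts") <- starts
  out
}

#' Window-wise dynamic FC prediction quality
#'
#' Mean over sliding-window positions of the FC similarity between
#' corresponding windows of two BOLD series.
#'
#' @param sim,emp [bold_series()] objects or matrices of equal shape.
#' @inheritParams sliding_window_fc
#' @return Mean window-wise FC similarity.
#' @export
dynamic_fc_quality <- function(sim, emp, window = 100, step = 1) {
  a <- sliding_window_fc(sim, window, step)
  b <- sliding_window_fc(emp, window, step)
  mean(mapply(fc_similarity, a, b))
}

#' Region-wise time-series prediction quality
#'
#' Mean Pearson correlation over corresponding region pairs (region i of the
#' simulation against region i of the target only).
#'
#' @param sim,emp [bold_series()] objects or N x M matrices with matched
#'   regions and scan counts.
#' @return Mean correlation.
#' @export
prediction_quality <- function(sim, emp) {
  a <- if (inherits(sim, "bold_series")) sim$values else as.matrix(sim)
  b <- if (inherits(emp, "bold_series")) emp$values else as.matrix(emp)
  if (!all(dim(a) == dim(b)))
    stop("simulated and target series must have identical shape")
  mean(vapply(seq_len(nrow(a)),
              function(i) stats::cor(a[i, ], b[i, ]), numeric(1)))
}

#' Welch power spectral density
#'
#' Hann-windowed, mean-detrended, 50%-overlapping segment average
#' periodogram. Matrix input yields the PSD averaged across rows after
#' per-row normalization by total power.
#'
#' @param x numeric vector or matrix (rows averaged).
#' @param fs sampling rate (Hz).
#' @param seg_frac segment length as a fraction of the series (default 1/4).
#' @param normalize divide each PSD by its total power before averaging.
#' @return List with `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, seg_frac = 0.25, normalize = TRUE) {
  one <- function(v) {
    n <- length(v)
    L <- max(8L, as.integer(floor(n * seg_frac)))
    hop <- max(1L, L %/% 2L)
    win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
    starts <- seq(1L, n - L + 1L, by = hop)
    nf <- L %/% 2L
    acc <- numeric(nf)
    for (s in starts) {
      seg <- v[s:(s + L - 1L)]
      seg <- (seg - mean(seg)) * win
      sp <- Mod(stats::fft(seg))^2
      acc <- acc + sp[2:(nf + 1L)]
    }
    p <- acc / length(starts) / (fs * sum(win^2))
    if (normalize && sum(p) > 0) p <- p / sum(p)
    list(freq = (1:nf) * fs / L, power = p)
  }
  if (is.matrix(x)) {
    per <- apply(x, 1, one, simplify = FALSE)
    list(freq = per[[1]]$freq,
         power = rowMeans(sapply(per, `[[`, "power")))
  } else one(x)
}

#' Power-law fit of the Welch spectrum
#'
#' Fits `P = a * f^beta` by least squares in log-log coordinates over the
#' stated frequency band (default 0.01-0.17 Hz, the scanner-resolution
#' band between drift confounds and the Nyquist region at TR = 1.94 s).
#'
#' @param x numeric vector, matrix (rows = regions, averaged), or a
#'   [bold_series()] (its TR sets `fs`).
#' @param fs sampling rate (Hz); ignored when `x` is a `bold_series`.
#' @param band length-2 fit band in Hz.
#' @return Object of class `power_law_fit`: `beta`, `a`, `band`,
#'   `r_squared`, plus the PSD (`freq`, `power`).
#' @export
welch_powerlaw <- function(x, fs = NULL, band = c(0.01, 0.17)) {
  if (inherits(x, "bold_series")) {
    fs <- 1 / x$TR
    x <- x$values
  }
  if (is.null(fs)) stop("fs is required for matrix/vector input")
  psd <- welch_psd(x, fs)
  sel <- psd$freq >= band[1] & psd$freq <= band[2] & psd$power > 0
  if (sum(sel) < 4)
    stop("fit band unresolvable: fewer than 4 spectral estimates in [",
         band[1], ", ", band[2], "] Hz; use a longer series")
  lf <- log(psd$freq[sel]); lp <- log(psd$power[sel])
  fit <- stats::lm(lp ~ lf)
  structure(list(beta = unname(stats::coef(fit)[2]),
                 a = exp(unname(stats::coef(fit)[1])),
                 band = band,
                 r_squared = summary(fit)$r.squared,
                 freq = psd$freq, power = psd$power),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit P = a f^beta on [%g, %g] Hz: beta = %.3f (R^2 = %.3f)\n",
              x$band[1], x$band[2], x$beta, x$r_squared))
  invisible(x)
}

#' Detrended fluctuation analysis with model comparison
#'
#' First-order DFA: the cumulative profile is divided into non-overlapping
#' boxes of logarithmically spaced sizes, linearly detrended per box, and
#' the root-mean-square fluctuation `F(n)` computed per box size. Scale
#' invariance is then *tested*, not assumed: a straight line in
#' log-log space (power law) is compared against curved alternatives
#' (quadratic and saturating-exponential) by small-sample-corrected AIC
#' under a Gaussian likelihood; the series is called scale-free only when
#' the straight line wins. A plain straight-line fit without this
#' comparison would accept many non-power-law series.
#'
#' @param x numeric vector, length >= 512.
#' @param n_sizes number of box sizes (>= 12), log-spaced on
#'   `[min_box, length(x)/4]`.
#' @param min_box smallest box size in samples.
#' @return Object of class `scale_free_verdict`: `dfa_exponent` (slope of
#'   the straight-line fit), `is_scale_free`, `aicc` (named vector of model
#'   scores), `box_sizes`, `fluctuation`.
#' @export
dfa_scalefree_test <- function(x, n_sizes = 14, min_box = 10) {
  n <- length(x)
  if (n < 512) stop("need at least 512 samples for DFA")
  if (n_sizes < 12) stop("need at least 12 box sizes")
  max_box <- n %/% 4L
  if (max_box <= 2 * min_box)
    stop("insufficient box-size span: series too short for min_box")
  sizes <- unique(as.integer(round(exp(
    seq(log(min_box), log(max_box), length.out = n_sizes)))))
  y <- cumsum(x - mean(x))
  fluct <- vapply(sizes, function(s) {
    nb <- n %/% s
    res2 <- 0
    tt <- seq_len(s)
    for (b in seq_len(nb)) {
      seg <- y[((b - 1) * s + 1):(b * s)]
      r <- stats::lm.fit(cbind(1, tt), seg)$residuals
      res2 <- res2 + sum(r^2)
    }
    sqrt(res2 / (nb * s))
  }, numeric(1))

  lx <- log(sizes); ly <- log(fluct)
  m <- length(lx)
  aicc_of <- function(rss, k) {
    m * log(rss / m) + 2 * k + 2 * k * (k + 1) / max(m - k - 1, 1)
  }
  fit_lin <- stats::lm(ly ~ lx)
  scores <- c(power_law = aicc_of(sum(stats::resid(fit_lin)^2), 3))
  fit_quad <- stats::lm(ly ~ lx + I(lx^2))
  scores["quadratic"] <- aicc_of(sum(stats::resid(fit_quad)^2), 4)
  sat <- tryCatch({
    st <- list(a = max(ly), b = max(ly) - min(ly), c = stats::median(lx))
    fit_sat <- suppressWarnings(
      stats::nls(ly ~ a - b * exp(-(lx - min(lx)) / c), start = st,
                 control = stats::nls.control(warnOnly = TRUE)))
    aicc_of(sum(stats::resid(fit_sat)^2), 4)
  }, error = function(e) Inf)
  scores["saturating"] <- sat

  is_sf <- names(which.min(scores)) == "power_law"
  structure(list(dfa_exponent = unname(stats::coef(fit_lin)[2]),
                 is_scale_free = is_sf,
                 aicc = scores,
                 box_sizes = sizes,
                 fluctuation = fluct),
            class = "scale_free_verdict")
}

#' @export
print.scale_free_verdict <- function(x, ...) {
  cat(sprintf("DFA exponent %.3f; scale-free: %s (AICc margins: %s)\n",
              x$dfa_exponent, x$is_scale_free,
              paste(sprintf("%s %.1f", names(x$aicc), x$aicc - min(x$aicc)),
                    collapse = ", ")))
  invisible(x)
}

#' Centered moving average
#'
#' Window means with partial windows at the edges (output length equals
#' input length). Used to extract the slow modulation of firing-rate series
#' from under the alpha-rate carrier. The default window of 1000 ms spans an
#' integer number of carrier cycles for any integer-Hz alpha carrier, so the
#' carrier ripple cancels exactly regardless of whether the rhythm sits at
#' 9, 10 or 11 Hz, while the slow (0.01-0.03 Hz) modulation of interest
#' passes through unattenuated.
#'
#' @param x numeric vector or matrix (smoothed row-wise).
#' @param window_ms window length in ms.
#' @param fs sampling rate (Hz).
#' @return Smoothed series of the same shape.
#' @export
moving_average_rate <- function(x, window_ms = 1000, fs = 1000) {
  w <- max(1L, as.integer(round(window_ms * fs / 1000)))
  ma1 <- function(v) {
    n <- length(v)
    h1 <- (w - 1L) %/% 2L
    h2 <- w - 1L - h1
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - h1, 1L)
    hi <- pmin(seq_len(n) + h2, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  if (is.matrix(x)) t(apply(x, 1, ma1)) else ma1(x)
}
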