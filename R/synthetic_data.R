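#' Artificial alpha-band drive: single high-power burst
#'
#' A zero-mean sinusoidal carrier (default 10 Hz) with unit baseline envelope
#' and one smooth high-power burst centred mid-series, replicated across all
#' regions. The burst envelope is a raised cosine rising from 1 to
#' `burst_amplitude_ratio` and back; long stable epochs before and after the
#' burst let model activity settle. Used to expose the inhibitory
#' half-wave-rectification mechanism: cycle-averaged inhibitory firing grows
#' with alpha power because large negative half-cycles are clipped at 0 Hz.
#'
#' @param n_regions number of regions to replicate the signal across.
#' @param duration_s series length in seconds (>= burst duration).
#' @param carrier_freq carrier frequency in Hz; the alpha band is 8-12 Hz.
#' @param burst_amplitude_ratio envelope peak relative to baseline
#'   (default 4).
#' @param burst_duration_s full width of the raised-cosine burst (default
#'   10 s).
#' @param sample_rate sampling rate (Hz).
#' @return A [drive_timeseries()] with attribute `"envelope"` holding the
#'   programmed envelope.
#' @examples
#' d <- make_burst_alpha(2, duration_s = 30)
#' @export
make_burst_alpha <- function(n_regions = 1, duration_s = 300,
                             carrier_freq = 10, burst_amplitude_ratio = 4,
                             burst_duration_s = 10, sample_rate = 1000) {
  if (carrier_freq < 8 || carrier_freq > 12)
    stop("carrier frequency must lie in the alpha band (8-12 Hz)")
  if (burst_duration_s > duration_s)
    stop("burst longer than the series")
  t <- seq(0, duration_s - 1 / sample_rate, by = 1 / sample_rate)
  env <- rep(1, length(t))
  centre <- duration_s / 2
  in_burst <- abs(t - centre) <= burst_duration_s / 2
  env[in_burst] <- 1 + (burst_amplitude_ratio - 1) *
    0.5 * (1 + cos(2 * pi * (t[in_burst] - centre) / burst_duration_s))
  x <- env * sin(2 * pi * carrier_freq * t)
  d <- drive_timeseries(matrix(rep(x, each = n_regions), nrow = n_regions),
                        sample_rate)
  attr(d, "envelope") <- env
  d
}

#' Artificial alpha-band drive: slow amplitude modulation
#'
#' A sinusoidal carrier whose amplitude is modulated by a sum of slow
#' oscillations (default components at 0.01, 0.02 and 0.03 Hz, the band of
#' empirical alpha-power fluctuations), with equal modulation depth per
#' component. The envelope is strictly positive,
#' `env(t) = 1 + depth * mean_k(sin(2 pi f_k t))`, oscillating between
#' `1 - depth` and `1 + depth` times baseline; the default depth of 0.8
#' spans 0.2x to 1.8x so negative carrier half-cycles reach the inhibitory
#' rectification regime without numerical extremes.
#'
#' @inheritParams make_burst_alpha
#' @param am_frequencies slow modulation frequencies in Hz, each in
#'   \[0.005, 0.1\].
#' @param depth total peak modulation depth (0 < depth < 1).
#' @return A [drive_timeseries()] with attribute `"envelope"`.
#' @examples
#' d <- make_am_alpha(1, duration_s = 120, am_frequencies = 0.02)
#' @export
make_am_alpha <- function(n_regions = 1, duration_s = 300, carrier_freq = 10,
                          am_frequencies = c(0.01, 0.02, 0.03), depth = 0.8,
                          sample_rate = 1000) {
  if (carrier_freq < 8 || carrier_freq > 12)
    stop("carrier frequency must lie in the alpha band (8-12 Hz)")
  if (length(am_frequencies) == 0)
    stop("am_frequencies must be non-empty")
  if (depth <= 0 || depth >= 1) stop("depth must lie in (0, 1)")
  t <- seq(0, duration_s - 1 / sample_rate, by = 1 / sample_rate)
  mod <- rowMeans(sapply(am_frequencies, function(f) sin(2 * pi * f * t)))
  env <- 1 + depth * mod
  x <- env * sin(2 * pi * carrier_freq * t)
  d <- drive_timeseries(matrix(rep(x, each = n_regions), nrow = n_regions),
                        sample_rate)
  attr(d, "envelope") <- env
  d
}

#' Surrogate broadband source activity
#'
#' Stand-in for empirical region-wise EEG source activity: per-region
#' 1/f-shaped broadband noise (default power-spectral slope -0.5, echoing
#' wide-band EEG power spectra) plus an alpha-band (8-12 Hz) oscillation
#' whose amplitude fluctuates with a slow random envelope (0.01-0.1 Hz).
#' Each region is z-scored at the native 200 Hz rate and then spline-upsampled
#' to 1 kHz, mirroring the empirical preprocessing chain.
#'
#' @param n_regions number of regions (independent realizations).
#' @param duration_s series length in seconds (>= 60).
#' @param seed integer seed; same seed gives identical output.
#' @param alpha_freq alpha carrier frequency (Hz).
#' @param alpha_weight amplitude of the alpha component relative to the
#'   broadband background before z-scoring.
#' @param slope power-spectral exponent of the broadband background.
#' @param native_rate generation rate before upsampling (Hz).
#' @param sample_rate output rate after spline interpolation (Hz).
#' @return A [drive_timeseries()] at `sample_rate`.
#' @examples
#' d <- make_surrogate_source_activity(2, 60, seed = 1)
#' @export
make_surrogate_source_activity <- function(n_regions, duration_s, seed,
                                           alpha_freq = 10, alpha_weight = 1,
                                           slope = -0.5, native_rate = 200,
                                           sample_rate = 1000) {
  if (duration_s < 60) stop("duration must be at least 60 s")
  set.seed(seed)
  n_t <- as.integer(round(duration_s * native_rate))
  t <- (seq_len(n_t) - 1) / native_rate
  out <- matrix(0, n_regions, as.integer(round(duration_s * sample_rate)))
  t_out <- (seq_len(ncol(out)) - 1) / sample_rate
  for (i in seq_len(n_regions)) {
    bb <- spectral_noise(n_t, native_rate, slope)
    # slow random envelope: smoothed positive modulation in 0.01-0.1 Hz
    env <- spectral_noise(n_t, native_rate, 0, lo = 0.01, hi = 0.1)
    env <- 1 + 0.5 * env / max(abs(env), 1e-12)
    alpha <- env * sin(2 * pi * alpha_freq * t + stats::runif(1, 0, 2 * pi))
    x <- bb + alpha_weight * alpha
    x <- (x - mean(x)) / stats::sd(x)
    out[i, ] <- stats::spline(t, x, xout = t_out, method = "fmm")$y
  }
  drive_timeseries(out, sample_rate)
}

#' Spectrally synthesized noise with a prescribed power-law spectrum
#'
#' Generates unit-variance noise whose power spectrum follows `|f|^slope`,
#' optionally band-limited, by assigning random phases to the target
#' amplitude spectrum in the frequency domain. This is the reference
#' generator for exponent-recovery checks of the spectral and DFA
#' estimators (a slope of `1 - 2 H` corresponds to fractional Gaussian
#' noise with Hurst exponent `H`).
#'
#' @param n number of samples.
#' @param rate sampling rate (Hz).
#' @param slope power-spectral exponent (0 = white noise).
#' @param lo,hi optional band limits (Hz); components outside are zeroed.
#' @return Numeric vector of length `n`. Uses R's RNG; seed with
#'   [set.seed()] for reproducibility.
#' @export
spectral_noise <- function(n, rate, slope, lo = NULL, hi = NULL) {
  freqs <- seq(0, rate / 2, length.out = n %/% 2 + 1)
  amp <- numeric(length(freqs))
  pos <- freqs > 0
  amp[pos] <- freqs[pos]^(slope / 2)
  if (!is.null(lo)) amp[freqs < lo] <- 0
  if (!is.null(hi)) amp[freqs > hi] <- 0
  phases <- stats::runif(length(freqs), 0, 2 * pi)
  half <- amp * exp(1i * phases)
  half[1] <- 0
  if (n %% 2 == 0) half[length(half)] <- Re(half[length(half)])
  spec <- c(half, Conj(rev(half[2:(length(half) - (n %% 2 == 0))])))
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Randomly permute drive samples in time
#'
#' Independent uniform permutation of the time samples of each region
#' (different permutation per region), preserving the per-region value
#' multiset while destroying all temporal structure. This is the
#' permutation-control input: it retains the drive's amplitude distribution
#' but cannot carry subject-specific temporal information.
#'
#' @param drive a [drive_timeseries()].
#' @param seed integer seed.
#' @return A permuted [drive_timeseries()].
#' @export
permute_drive <- function(drive, seed) {
  set.seed(seed)
  v <- drive$values
  for (i in seq_len(nrow(v)))
    v[i, ] <- v[i, sample.int(ncol(v))]
  drive_timeseries(v, drive$sample_rate)
}

#' Synthetic structural connectome
#'
#' Random symmetric nonnegative coupling matrix with heavy-tailed
#' (log-normal) weight magnitudes, zero diagonal and max-normalization to 1 —
#' emulating the wide weight variability of tractography-derived connectomes
#' that feedback inhibition control must compensate.
#'
#' @param n_regions number of regions (>= 2).
#' @param density fraction of nonzero upper-triangular entries, in (0, 1\].
#' @param seed integer seed.
#' @param sdlog log-scale standard deviation of the weight distribution.
#'   The default 2 mirrors tractography fiber-count distributions, which
#'   span orders of magnitude; after max-normalization most weights are then
#'   small relative to the strongest connection, as in empirical connectomes.
#' @return A [structural_connectome()].
#' @examples
#' C <- make_synthetic_connectome(8, seed = 1)
#' @export
make_synthetic_connectome <- function(n_regions, density = 0.6, seed = 1,
                                      sdlog = 2) {
  if (n_regions < 2) stop("need at least 2 regions")
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  set.seed(seed)
  m <- matrix(0, n_regions, n_regions)
  ut <- which(upper.tri(m))
  n_edges <- max(1L, round(density * length(ut)))
  picked <- sample(ut, n_edges)
  m[picked] <- stats::rlnorm(n_edges, meanlog = 0, sdlog = sdlog)
  m <- m + t(m)
  structural_connectome(m, normalize = TRUE)
}
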