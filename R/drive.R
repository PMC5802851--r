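#' Per-region drive time series
#'
#' Container for the injected current time series `I_BG` (one row per region,
#' one column per sample). Drive derived from recorded source activity is
#' z-scored per region before injection; the model rescales it by the
#' `w_BG_E` / `w_BG_I` weights.
#'
#' @param values N x T numeric matrix (regions x samples), finite.
#' @param sample_rate sampling rate in Hz (canonically 1000 after spline
#'   upsampling).
#' @return An object of class `drive_timeseries`.
#' @examples
#' d <- drive_timeseries(matrix(rnorm(2000), 2), 1000)
#' d$sample_rate
#' @export
drive_timeseries <- function(values, sample_rate = 1000) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("drive values must be finite (no NaN/Inf)")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be a positive number")
  structure(list(values = values, sample_rate = sample_rate),
            class = "drive_timeseries")
}

#' @export
print.drive_timeseries <- function(x, ...) {
  cat(sprintf("Drive time series: %d regions x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$sample_rate,
              ncol(x$values) / x$sample_rate))
  invisible(x)
}

#' Duration of a drive series in seconds
#' @param drive a `drive_timeseries`.
#' @export
drive_duration <- function(drive) ncol(drive$values) / drive$sample_rate

#' Read / write drive time series as delimited text
#'
#' Rows are regions, columns are samples; no header. The sample rate is not
#' stored in the file and must be supplied on read.
#'
#' @param path file path.
#' @param sample_rate sampling rate (Hz) of the stored series.
#' @return `read_drive` returns a `drive_timeseries`; `write_drive` invisibly
#'   returns `path`.
#' @export
read_drive <- function(path, sample_rate = 1000) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  drive_timeseries(unname(m), sample_rate)
}

#' @rdname read_drive
#' @param drive a `drive_timeseries`.
#' @export
write_drive <- function(drive, path) {
  utils::write.table(drive$values, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
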