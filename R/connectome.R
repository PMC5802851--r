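#' Structural connectome container
#'
#' Wraps an N x N nonnegative coupling matrix `C_ij` (strength of white-matter
#' interaction between region pairs). Weights are conventionally divided by
#' their maximum so the strongest connection equals 1; the diagonal is zero
#' (no self-coupling through the long-range term).
#'
#' @param weights square numeric matrix of nonnegative, finite coupling
#'   strengths.
#' @param region_labels optional character vector of region names; defaults to
#'   `"R1" ... "RN"`.
#' @param normalize divide `weights` by `max(weights)` (when positive) so the
#'   maximum entry becomes 1. Default `TRUE`.
#' @return An object of class `structural_connectome` with elements `weights`
#'   and `region_labels`.
#' @examples
#' C <- structural_connectome(matrix(c(0, 2, 2, 0), 2))
#' max(C$weights)  # 1 after normalization
#' @export
structural_connectome <- function(weights, region_labels = NULL, normalize = TRUE) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("connectome weights must be square")
  if (!all(is.finite(weights))) stop("connectome weights must be finite")
  if (any(weights < 0)) stop("connectome weights must be nonnegative")
  diag(weights) <- 0
  if (normalize && max(weights) > 0) weights <- weights / max(weights)
  n <- nrow(weights)
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(n))
  if (length(region_labels) != n) stop("region_labels length must match matrix size")
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights, region_labels = region_labels),
            class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf("Structural connectome: %d regions, density %.2f, max weight %g\n",
              nrow(x$weights),
              mean(x$weights[upper.tri(x$weights)] > 0),
              max(x$weights)))
  invisible(x)
}

#' @rdname structural_connectome
#' @param x a `structural_connectome`.
#' @export
n_regions <- function(x) UseMethod("n_regions")

#' @export
n_regions.structural_connectome <- function(x) nrow(x$weights)

#' @export
n_regions.drive_timeseries <- function(x) nrow(x$values)

#' Read / write a connectome as a plain-text matrix
#'
#' The on-disk format is a whitespace- or comma-separated N x N numeric
#' matrix with no header; `read_connectome` sniffs the delimiter.
#'
#' @param path file path.
#' @param normalize passed to [structural_connectome()]; set `FALSE` to keep
#'   raw weights.
#' @return `read_connectome` returns a `structural_connectome`;
#'   `write_connectome` invisibly returns `path`.
#' @export
read_connectome <- function(path, normalize = TRUE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  structural_connectome(unname(m), normalize = normalize)
}

#' @rdname read_connectome
#' @param C a `structural_connectome`.
#' @export
write_connectome <- function(C, path) {
  utils::write.table(C$weights, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
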