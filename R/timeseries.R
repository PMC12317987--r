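#' Multichannel source time-course container
#'
#' The basic data object of the pipeline: an L-sample by M-channel numeric
#' matrix of source-level activity at a known sampling rate, optionally
#' tagged with a frequency band and with the sample indices at which
#' concatenated trials start.
#'
#' @param values numeric matrix, samples in rows, channels in columns.
#'   A plain vector is treated as a single channel.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of region/channel names; defaults
#'   to `ch1, ch2, ...`.
#' @param band optional band tag, one of `"theta"`, `"alpha"`, `"beta"`.
#' @param trial_boundaries integer vector of 1-based sample indices at which
#'   trials start; defaults to a single trial starting at sample 1. Must be
#'   strictly increasing and within `1..L`.
#' @return An object of class `ts_matrix`.
#' @export
#' @examples
#' x <- ts_matrix(matrix(rnorm(512), 256, 2), fs = 256)
#' dim(x$values)
ts_matrix <- function(values, fs, channel_labels = NULL, band = NULL,
                      trial_boundaries = 1L) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0) stop_ncreann("time series must have at least one sample")
  if (anyNA(values) || any(!is.finite(values)))
    stop_ncreann("time series contains missing or non-finite values")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_ncreann("'fs' must be a single positive sampling rate in Hz")
  M <- ncol(values)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(M))
  if (length(channel_labels) != M)
    stop_ncreann("'channel_labels' length must match the number of channels")
  if (!is.null(band)) band <- match.arg(band, c("theta", "alpha", "beta"))
  tb <- as.integer(trial_boundaries)
  if (length(tb) == 0 || tb[1] != 1L)
    stop_ncreann("'trial_boundaries' must start with sample 1")
  if (any(diff(tb) <= 0) || any(tb > nrow(values)))
    stop_ncreann("'trial_boundaries' must be strictly increasing and <= L")
  colnames(values) <- channel_labels
  structure(list(values = values, fs = fs, channel_labels = channel_labels,
                 band = band, trial_boundaries = tb),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> %d samples x %d channels @ %g Hz (%.3g s)\n",
              nrow(x$values), ncol(x$values), x$fs, nrow(x$values) / x$fs))
  if (!is.null(x$band)) cat("  band:", x$band, "\n")
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat("  trials:", length(x$trial_boundaries), "\n")
  invisible(x)
}

#' @export
dim.ts_matrix <- function(x) dim(x$values)

n_channels <- function(x) ncol(x$values)
n_samples <- function(x) nrow(x$values)

# Per-trial sample index ranges implied by the boundaries.
trial_ranges <- function(x) {
  L <- n_samples(x)
  starts <- x$trial_boundaries
  ends <- c(starts[-1] - 1L, L)
  Map(function(s, e) c(s, e), starts, ends)
}

#' Frequency band edges
#'
#' Canonical oscillatory band limits used throughout the pipeline:
#' theta 4-7 Hz, alpha 8-12 Hz, beta 15-30 Hz.
#'
#' @param band `"theta"`, `"alpha"` or `"beta"`.
#' @return Numeric vector `c(low, high)` in Hz.
#' @export
#' @examples
#' band_edges("alpha")
band_edges <- function(band) {
  switch(match.arg(band, c("theta", "alpha", "beta")),
         theta = c(4, 7), alpha = c(8, 12), beta = c(15, 30))
}
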