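#' Zero-phase band-pass filter
#'
#' Filters every channel with a windowed-sinc (Hamming) FIR band-pass,
#' applied forward and backward so the net phase response is zero and
#' directed-connectivity estimates are not distorted by filter lag. Channel
#' means are removed before filtering (the passbands exclude DC). The filter
#' order is `3.3 * fs / min(lower_edge, bandwidth)` rounded up to even,
#' which keeps the transition width below both the distance to DC and the
#' band width, so the gain at band center is ~1 and one octave outside the
#' edges is well under 0.1.
#'
#' @param series a [ts_matrix()].
#' @param band `"theta"` (4-7 Hz), `"alpha"` (8-12 Hz) or `"beta"`
#'   (15-30 Hz).
#' @return A filtered [ts_matrix()] tagged with the band.
#' @export
#' @examples
#' x <- ts_matrix(sin(2 * pi * 10 * (0:2047) / 256), fs = 256)
#' y <- bandpass(x, "alpha")
bandpass <- function(series, band) {
  stopifnot(inherits(series, "ts_matrix"))
  edges <- band_edges(band)
  fs <- series$fs
  if (fs <= 2 * edges[2])
    stop_ncreann("sampling rate too low for the ", band, " band")
  n <- ceiling(3.3 * fs / min(edges[1], diff(edges)))
  if (n %% 2 == 1) n <- n + 1
  h <- signal::fir1(n, edges / (fs / 2), type = "pass")
  L <- n_samples(series)
  if (L < 3 * length(h))
    stop_ncreann("series too short to filter: need at least ",
                 3 * length(h), " samples, have ", L)
  filt <- apply(series$values, 2, function(x) {
    x <- x - mean(x)
    zp_filter(zp_filter(x, h), h)    # forward-backward: zero net phase
  })
  out <- series
  out$values <- filt
  colnames(out$values) <- series$channel_labels
  out$band <- band
  out
}

# One centered pass of a symmetric odd-length FIR kernel with mirror
# padding at both ends; output has the same length as the input.
zp_filter <- function(x, h) {
  half <- (length(h) - 1) / 2
  L <- length(x)
  xp <- c(rev(x[2:(half + 1)]), x, rev(x[(L - half):(L - 1)]))
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[(half + 1):(half + L)])
}

#' Cut post-stimulus epochs out of a continuous series
#'
#' Extracts one fixed-length window per stimulus onset. The window is
#' half-open: with the default `c(0, 1000)` ms each epoch holds
#' `round(fs * 1.0)` samples starting at the onset sample.
#'
#' @param series a [ts_matrix()].
#' @param onsets 1-based sample indices of stimulus onsets.
#' @param window `c(start, end)` in ms relative to onset.
#' @return List of single-trial [ts_matrix()] epochs.
#' @export
select_epochs <- function(series, onsets, window = c(0, 1000)) {
  stopifnot(inherits(series, "ts_matrix"))
  fs <- series$fs
  n_ep <- round(fs * diff(window) / 1000)
  off <- round(fs * window[1] / 1000)
  L <- n_samples(series)
  lapply(seq_along(onsets), function(t) {
    a <- onsets[t] + off
    b <- a + n_ep - 1
    if (a < 1 || b > L)
      stop_ncreann(sprintf(
        "epoch %d (onset sample %d) exceeds the series [1, %d]", t,
        onsets[t], L))
    ts_matrix(series$values[a:b, , drop = FALSE], fs = fs,
              channel_labels = series$channel_labels, band = series$band)
  })
}

#' Concatenate single-trial epochs into one training series
#'
#' Joins epochs end to end (the model-fitting stage needs one long series)
#' while recording each epoch's start sample in `trial_boundaries`, so that
#' lag vectors are never built across trial joins.
#'
#' @param epochs list of [ts_matrix()] epochs sharing channels, sampling
#'   rate and band.
#' @return One [ts_matrix()] of length equal to the summed epoch lengths.
#' @export
concatenate_trials <- function(epochs) {
  if (length(epochs) == 0) stop_ncreann("no epochs to concatenate")
  ref <- epochs[[1]]
  for (e in epochs) {
    stopifnot(inherits(e, "ts_matrix"))
    if (!identical(e$channel_labels, ref$channel_labels))
      stop_ncreann("epochs have mixed channel sets")
    if (e$fs != ref$fs) stop_ncreann("epochs have mixed sampling rates")
    if (!identical(e$band, ref$band)) stop_ncreann("epochs have mixed bands")
  }
  lens <- vapply(epochs, n_samples, integer(1))
  ts_matrix(do.call(rbind, lapply(epochs, `[[`, "values")), fs = ref$fs,
            channel_labels = ref$channel_labels, band = ref$band,
            trial_boundaries = cumsum(c(1L, lens[-length(lens)])))
}

#' Standardize channels to zero mean and unit variance
#'
#' Centers and scales every channel, keeping the per-channel parameters so
#' the transform can be inverted exactly. Network training operates on
#' standardized data; connectivity is computed on the same scale, which is
#' what makes the strengths unitless.
#'
#' @param series a [ts_matrix()].
#' @return List with `series` (standardized [ts_matrix()]), `center` and
#'   `scale` (per-channel mean and sd).
#' @export
standardize <- function(series) {
  stopifnot(inherits(series, "ts_matrix"))
  mu <- colMeans(series$values)
  sdv <- apply(series$values, 2, sd)
  bad <- which(sdv == 0)
  if (length(bad))
    stop_ncreann("constant channel cannot be standardized: ",
                 paste(series$channel_labels[bad], collapse = ", "))
  out <- series
  out$values <- sweep(sweep(series$values, 2, mu), 2, sdv, "/")
  colnames(out$values) <- series$channel_labels
  list(series = out, center = mu, scale = sdv)
}

#' Invert a standardization
#'
#' @param series standardized [ts_matrix()].
#' @param center,scale parameters returned by [standardize()].
#' @return The de-standardized [ts_matrix()].
#' @export
unstandardize <- function(series, center, scale) {
  out <- series
  out$values <- sweep(sweep(series$values, 2, scale, "*"), 2, center, "+")
  colnames(out$values) <- series$channel_labels
  out
}

#' Build lag-vector regression samples
#'
#' Turns a (possibly concatenated) series into the supervised samples the
#' autoregressive network trains on: for every admissible time n, the input
#' row stacks the p past samples of all M channels
#' (`x_1(n-1), ..., x_M(n-1), x_1(n-2), ..., x_M(n-p)`) and the target row
#' is `x(n)`. Rows whose lag window would cross a trial boundary are
#' excluded, so no sample mixes data from two trials.
#'
#' @param series a [ts_matrix()].
#' @param p model order (past samples per channel).
#' @return An object of class `regression_samples` with matrices `inputs`
#'   (N x M*p) and `targets` (N x M), the order `p`, channel count `M`, and
#'   `source_sample_index` giving the series sample n of each row.
#' @export
#' @examples
#' x <- ts_matrix(matrix(rnorm(100), 50, 2), fs = 256)
#' s <- build_regression_samples(x, p = 5)
#' dim(s$inputs)
build_regression_samples <- function(series, p) {
  stopifnot(inherits(series, "ts_matrix"))
  p <- as.integer(p)
  if (p < 1) stop_ncreann("'p' must be >= 1")
  M <- n_channels(series)
  ranges <- trial_ranges(series)
  lens <- vapply(ranges, function(r) r[2] - r[1] + 1L, integer(1))
  if (any(lens <= p))
    stop_ncreann("model order p = ", p,
                 " is not smaller than the shortest trial (",
                 min(lens), " samples)")
  ins <- vector("list", length(ranges))
  tgs <- vector("list", length(ranges))
  idx <- vector("list", length(ranges))
  for (t in seq_along(ranges)) {
    r <- ranges[[t]]
    seg <- series$values[r[1]:r[2], , drop = FALSE]
    emb <- stats::embed(seg, p + 1)   # cols: all channels lag0, lag1, .., lagp
    ins[[t]] <- emb[, (M + 1):(M * (p + 1)), drop = FALSE]
    tgs[[t]] <- emb[, 1:M, drop = FALSE]
    idx[[t]] <- (r[1] + p):r[2]
  }
  structure(list(inputs = do.call(rbind, ins), targets = do.call(rbind, tgs),
                 p = p, M = M,
                 channel_labels = series$channel_labels,
                 source_sample_index = unlist(idx)),
            class = "regression_samples")
}

#' @export
print.regression_samples <- function(x, ...) {
  cat(sprintf("<regression_samples> %d rows, M = %d channels, order p = %d\n",
              nrow(x$inputs), x$M, x$p))
  invisible(x)
}
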