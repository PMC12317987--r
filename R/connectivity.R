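#' Linear part of the fitted network
#'
#' First-order Taylor expansion of the trained network at the standardized
#' input mean (the zero vector): the linear coefficient of lagged channel i
#' (lag tau) on output channel j is
#' `sum_k W2[j, k] * act'(b1[k]) * W1[k, (i, tau)]`. With identity
#' activation this is exactly `W2 %*% W1` and the nonlinear remainder is
#' identically zero.
#'
#' @param model an `nmvar_model`.
#' @return List of p matrices `A[[tau]]` (M x M, rows = target channel,
#'   columns = source channel), the linear VAR coefficients implied by the
#'   network.
#' @export
taylor_linear_part <- function(model) {
  stopifnot(inherits(model, "nmvar_model"))
  J0 <- taylor_jacobian(model)
  M <- model$M
  lapply(seq_len(model$p), function(tau)
    J0[, ((tau - 1) * M + 1):(tau * M), drop = FALSE])
}

# Jacobian of the network at the zero input, M x (M*p).
taylor_jacobian <- function(model) {
  d <- if (model$activation == "tanh") 1 - tanh(model$b1)^2
       else rep(1, length(model$b1))
  model$W2 %*% (model$W1 * d)
}

#' Linear and non-linear directed connectivity from a fitted network
#'
#' Decomposes the fitted predictor into its linear part (the Taylor
#' expansion at the operating point) and the non-linear remainder, and
#' aggregates both into unitless M x M directed-strength matrices:
#' \describe{
#'   \item{lC}{`lC[i, j]` = mean over lags tau of the absolute linear
#'     coefficient of channel i (lag tau) on channel j.}
#'   \item{NC}{`NC[i, j]` = mean over samples n and lags tau of the
#'     absolute deviation of the instantaneous Jacobian
#'     `d xhat_j / d x_i(n - tau)` from the Taylor coefficient.}
#' }
#' Both matrices are oriented source-in-rows: entry (i, j) is the strength
#' of the directed influence i -> j. Diagonal entries are self-influences;
#' they are computed but excluded from group-level statistics.
#'
#' When `model` is an `ncreann_fit`, connectivity is computed per fold
#' model and averaged, which damps initialization variance.
#'
#' @param model an `nmvar_model` or an `ncreann_fit`.
#' @param samples the `regression_samples` the model was trained on (the
#'   Jacobian is averaged over these inputs).
#' @param band,condition optional labels carried into the result.
#' @return An object of class `connectivity_result` with matrices `lc` and
#'   `nc`.
#' @export
compute_lc_nc <- function(model, samples, band = NULL, condition = NULL) {
  stopifnot(inherits(samples, "regression_samples"))
  if (inherits(model, "ncreann_fit")) {
    parts <- lapply(model$models, compute_lc_nc, samples = samples)
    out <- parts[[1]]
    out$lc <- Reduce(`+`, lapply(parts, `[[`, "lc")) / length(parts)
    out$nc <- Reduce(`+`, lapply(parts, `[[`, "nc")) / length(parts)
    out$band <- band
    out$condition <- condition
    return(out)
  }
  stopifnot(inherits(model, "nmvar_model"))
  X <- samples$inputs
  if (nrow(X) == 0) stop_ncreann("empty sample set")
  M <- model$M
  p <- model$p
  J0 <- taylor_jacobian(model)
  lc <- t(apply_lag_mean(abs(J0), M, p))        # -> [source, target]
  nc <- matrix(0, M, M)
  if (model$activation == "tanh") {
    A <- sweep(X %*% t(model$W1), 2, model$b1, "+")
    Dact <- 1 - tanh(A)^2                        # N x H
    for (j in seq_len(M)) {
      Jn <- (Dact * matrix(model$W2[j, ], nrow(X), ncol(model$W2),
                           byrow = TRUE)) %*% model$W1   # N x (M*p)
      dev <- abs(sweep(Jn, 2, J0[j, ]))
      nc[, j] <- apply_lag_mean(matrix(colMeans(dev), 1), M, p)
    }
  }
  labs <- samples$channel_labels %||% paste0("ch", seq_len(M))
  dimnames(lc) <- dimnames(nc) <- list(source = labs, target = labs)
  structure(list(lc = lc, nc = nc, M = M, p = p, channel_labels = labs,
                 band = band, condition = condition),
            class = "connectivity_result")
}

# Average a (rows x M*p) matrix over its p lag blocks -> rows x M.
apply_lag_mean <- function(mat, M, p) {
  out <- matrix(0, nrow(mat), M)
  for (tau in seq_len(p))
    out <- out + mat[, ((tau - 1) * M + 1):(tau * M), drop = FALSE]
  out / p
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> M = %d regions (%s%s)\n", x$M,
              x$band %||% "broadband",
              if (is.null(x$condition)) "" else paste0(", ", x$condition)))
  cat("linear lC (source rows -> target cols):\n")
  print(round(x$lc, 4))
  cat("non-linear NC:\n")
  print(round(x$nc, 4))
  invisible(x)
}

#' Long-format edge table of a connectivity result
#'
#' @param x a `connectivity_result`.
#' @param drop_diagonal drop self-influence entries (default TRUE).
#' @return Data frame with columns `source`, `target`, `measure`
#'   (`lC`/`NC`) and `value`.
#' @export
edge_table <- function(x, drop_diagonal = TRUE) {
  stopifnot(inherits(x, "connectivity_result"))
  grid <- expand.grid(source = x$channel_labels, target = x$channel_labels,
                      stringsAsFactors = FALSE)
  tab <- rbind(
    data.frame(grid, measure = "lC", value = as.vector(x$lc)),
    data.frame(grid, measure = "NC", value = as.vector(x$nc)))
  if (!is.null(x$band)) tab$band <- x$band
  if (!is.null(x$condition)) tab$condition <- x$condition
  if (drop_diagonal) tab <- tab[tab$source != tab$target, ]
  rownames(tab) <- NULL
  tab
}

#' Time-shifted surrogate of a multichannel series
#'
#' Independently circularly shifts every channel by a random offset drawn
#' uniformly from `[L/8, 7L/8]` samples. Each channel's marginal
#' distribution and autocorrelation are preserved (up to wraparound at the
#' join), while the temporal alignment between channels - and with it any
#' directed coupling - is destroyed. Trial boundaries are carried over
#' unchanged so the surrogate is refit under the identical protocol.
#'
#' @param series a [ts_matrix()].
#' @param seed RNG seed for the per-channel offsets.
#' @return A surrogate [ts_matrix()].
#' @export
time_shifted_surrogate <- function(series, seed = 1L) {
  stopifnot(inherits(series, "ts_matrix"))
  L <- n_samples(series)
  if (L < 40) stop_ncreann("series too short for time-shifted surrogates")
  lo <- max(1L, floor(L / 8))
  hi <- floor(7 * L / 8)
  set.seed(seed)
  offs <- sample(lo:hi, n_channels(series), replace = TRUE)
  out <- series
  for (c in seq_len(n_channels(series))) {
    k <- offs[c]
    out$values[, c] <- series$values[c((k + 1):L, 1:k), c]
  }
  attr(out, "offsets") <- offs
  out
}

#' Surrogate significance test of directed connectivity
#'
#' Runs the full estimation (standardize, build lag samples, train the
#' network, decompose into lC and NC) on the observed series and on
#' `n_surrogates` time-shifted surrogates with identical hyperparameters
#' (fresh weight initialization per surrogate under derived child seeds).
#' An edge is significant when its randomization p-value
#' `(1 + #\{null >= observed\}) / (n + 1)` is at most
#' `1 - percentile/100`. Non-significant edges are reported as `NA` in the
#' masked matrices.
#'
#' @param series a [ts_matrix()] (band-filtered, epoched, concatenated).
#' @param config an [nmvar_config()].
#' @param n_surrogates number of surrogate datasets (default 100).
#' @param percentile one-sided significance percentile (default 95).
#' @param seed master seed for surrogate offsets and refits.
#' @param band,condition labels carried into the results.
#' @return An object of class `surrogate_null`: the observed
#'   `connectivity_result`, null arrays (`n x M x M`), p-value and logical
#'   significance matrices per measure, masked matrices (`lc_masked`,
#'   `nc_masked`), and the count of dropped surrogates.
#' @export
significance_mask <- function(series, config = nmvar_config(),
                              n_surrogates = 100L, percentile = 95,
                              seed = 1L, band = NULL, condition = NULL) {
  stopifnot(inherits(series, "ts_matrix"))
  fit_one <- function(x, cfg) {
    std <- standardize(x)
    smp <- build_regression_samples(std$series, cfg$p)
    fit <- fit_ncreann(smp, cfg, standardization = std[c("center", "scale")])
    compute_lc_nc(fit, smp)
  }
  obs <- fit_one(series, config)
  M <- obs$M
  null_lc <- array(NA_real_, c(n_surrogates, M, M))
  null_nc <- array(NA_real_, c(n_surrogates, M, M))
  dropped <- 0L
  for (s in seq_len(n_surrogates)) {
    res <- tryCatch({
      surr <- time_shifted_surrogate(series, seed = child_seed(seed, 303, s))
      cfg <- config
      cfg$seed <- child_seed(seed, 404, s)
      fit_one(surr, cfg)
    }, error = function(e) {
      message("surrogate ", s, " dropped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) dropped <- dropped + 1L
    else {
      null_lc[s, , ] <- res$lc
      null_nc[s, , ] <- res$nc
    }
  }
  if (dropped > 0.2 * n_surrogates)
    stop_ncreann(dropped, " of ", n_surrogates,
                 " surrogates failed to train; refusing to report")
  n_eff <- n_surrogates - dropped
  alpha <- 1 - percentile / 100
  pval <- function(null_arr, obs_mat) {
    p <- matrix(NA_real_, M, M)
    for (i in seq_len(M)) for (j in seq_len(M)) {
      nv <- null_arr[, i, j]
      nv <- nv[!is.na(nv)]
      p[i, j] <- (1 + sum(nv >= obs_mat[i, j])) / (length(nv) + 1)
    }
    dimnames(p) <- dimnames(obs_mat)
    p
  }
  p_lc <- pval(null_lc, obs$lc)
  p_nc <- pval(null_nc, obs$nc)
  sig_lc <- p_lc <= alpha
  sig_nc <- p_nc <= alpha
  lc_masked <- obs$lc; lc_masked[!sig_lc] <- NA
  nc_masked <- obs$nc; nc_masked[!sig_nc] <- NA
  structure(list(observed = obs, null_lc = null_lc, null_nc = null_nc,
                 p_lc = p_lc, p_nc = p_nc, sig_lc = sig_lc, sig_nc = sig_nc,
                 lc_masked = lc_masked, nc_masked = nc_masked,
                 n_surrogates = n_surrogates, n_used = n_eff,
                 dropped = dropped, percentile = percentile,
                 band = band, condition = condition),
            class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf(
    "<surrogate_null> %d/%d surrogates used, %gth percentile rule\n",
    x$n_used, x$n_surrogates, x$percentile))
  off <- row(x$sig_lc) != col(x$sig_lc)
  cat(sprintf("  significant off-diagonal edges: lC %d/%d, NC %d/%d\n",
              sum(x$sig_lc[off]), sum(off), sum(x$sig_nc[off]), sum(off)))
  invisible(x)
}
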