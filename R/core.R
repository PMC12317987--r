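#' Configuration of the autoregressive network estimator
#'
#' Collects every tunable of the nonlinear MVAR network fit: the model
#' order, the one-hidden-layer perceptron size, and the incremental
#' back-propagation protocol (momentum, adaptive learning rate, early
#' stopping, permuted cross-validation folds with an 80/10/10
#' train/validation/test split).
#'
#' @param p model order: past samples per channel entering the lag vector.
#' @param hidden_units hidden-layer width H.
#' @param activation `"tanh"` or `"identity"` (the latter reduces the
#'   network to a linear VAR fit, useful as an oracle).
#' @param init_range weights are initialized uniformly in this interval.
#' @param learning_rate initial per-sample learning rate eta.
#' @param momentum momentum coefficient alpha in `[0, 1)`.
#' @param lr_up,lr_down multiplicative learning-rate adaptation: after an
#'   epoch whose training error decreases, eta is multiplied by `lr_up`;
#'   an epoch whose error grows by more than `max_error_increase` is
#'   rejected (weights restored) and eta is multiplied by `lr_down`.
#' @param max_error_increase tolerated ratio of epoch-over-epoch training
#'   error before an epoch is rejected.
#' @param max_epochs hard cap on training epochs.
#' @param patience early stopping: epochs without validation improvement
#'   before training halts (best-validation weights are restored).
#' @param n_folds number of cross-validation folds (2..10). Rows are
#'   permuted once under the seed and cut into ten blocks; fold k tests on
#'   block k, validates on the next block, and trains on the rest, so with
#'   10 folds every row is tested exactly once.
#' @param seed integer seed governing the permutation and the per-fold
#'   weight initialization.
#' @param perm_seed optional separate seed for the row permutation; when
#'   `NULL` (default) the permutation follows `seed`. Fixing `perm_seed`
#'   while varying `seed` isolates weight-initialization variability from
#'   split variability.
#' @return An object of class `nmvar_config`.
#' @export
nmvar_config <- function(p = 5L, hidden_units = 10L, activation = "tanh",
                         init_range = c(-0.5, 0.5), learning_rate = 0.001,
                         momentum = 0.9, lr_up = 1.05, lr_down = 0.7,
                         max_error_increase = 1.04, max_epochs = 500L,
                         patience = 20L, n_folds = 10L, seed = 1L,
                         perm_seed = NULL) {
  activation <- match.arg(activation, c("tanh", "identity"))
  if (p < 1) stop_ncreann("'p' must be >= 1")
  if (hidden_units < 1) stop_ncreann("'hidden_units' must be >= 1")
  if (momentum < 0 || momentum >= 1) stop_ncreann("'momentum' must be in [0, 1)")
  if (learning_rate <= 0) stop_ncreann("'learning_rate' must be > 0")
  if (n_folds < 2 || n_folds > 10)
    stop_ncreann("'n_folds' must be between 2 and 10")
  if (length(init_range) != 2 || init_range[1] >= init_range[2])
    stop_ncreann("'init_range' must be an increasing interval")
  structure(list(p = as.integer(p), hidden_units = as.integer(hidden_units),
                 activation = activation, init_range = init_range,
                 learning_rate = learning_rate, momentum = momentum,
                 lr_up = lr_up, lr_down = lr_down,
                 max_error_increase = max_error_increase,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 perm_seed = if (!is.null(perm_seed)) as.integer(perm_seed)),
            class = "nmvar_config")
}

#' Select the autoregressive model order by information criteria
#'
#' Fits linear VAR models of order 1..`p_max` by least squares on a common
#' effective sample (rows valid at `p_max`) and scores each with the Akaike
#' and Schwartz (Bayesian) information criteria,
#' `log det(Sigma_hat) + k * penalty / N` with `k = p * M^2` free
#' coefficients. The pipeline default order is the Schwartz choice (the
#' more parsimonious criterion).
#'
#' @param series a [ts_matrix()].
#' @param p_max largest order to consider.
#' @return List with `table` (per-order criteria), `aic_order`,
#'   `bic_order` and `selected` (= `bic_order`).
#' @export
select_model_order <- function(series, p_max = 10L) {
  stopifnot(inherits(series, "ts_matrix"))
  M <- n_channels(series)
  L <- n_samples(series)
  if (p_max >= L / (2 * M))
    stop_ncreann("'p_max' too large for the series length (need p_max < L/2M)")
  full <- build_regression_samples(series, p_max)
  N <- nrow(full$inputs)
  Y <- full$targets
  tab <- data.frame(p = seq_len(p_max), aic = NA_real_, bic = NA_real_,
                    logdet = NA_real_)
  for (p in seq_len(p_max)) {
    X <- full$inputs[, seq_len(M * p), drop = FALSE]
    B <- qr.solve(X, Y)
    E <- Y - X %*% B
    Sig <- crossprod(E) / N
    ld <- determinant(Sig, logarithm = TRUE)$modulus[1]
    k <- p * M^2
    tab$logdet[p] <- ld
    tab$aic[p] <- ld + 2 * k / N
    tab$bic[p] <- ld + log(N) * k / N
  }
  list(table = tab, aic_order = which.min(tab$aic),
       bic_order = which.min(tab$bic), selected = which.min(tab$bic))
}

#' Fit the nonlinear MVAR network
#'
#' Trains one multilayer perceptron (one hidden layer, tanh units) per
#' cross-validation fold to predict the current samples of all channels
#' from the lag vector. Training follows incremental error back-propagation
#' with momentum, a multiplicative adaptive learning rate with epoch
#' rejection, and early stopping on the validation split with
#' best-validation weight restore. The rows are permuted once under the
#' configured seed and split 80/10/10 per fold.
#'
#' @param samples a `regression_samples` object from
#'   [build_regression_samples()].
#' @param config an [nmvar_config()].
#' @param standardization optional list with `center` and `scale` from
#'   [standardize()], stored on each model for later de-standardization.
#' @return An object of class `ncreann_fit`: `models` (one `nmvar_model`
#'   per fold), `metrics` (per-fold data frame of MSE and R-squared on the
#'   train/validation/test splits), `aggregates`, and `config`.
#' @export
fit_ncreann <- function(samples, config = nmvar_config(),
                        standardization = NULL) {
  stopifnot(inherits(samples, "regression_samples"),
            inherits(config, "nmvar_config"))
  if (samples$p != config$p)
    stop_ncreann("sample order (p = ", samples$p,
                 ") does not match config (p = ", config$p, ")")
  X <- samples$inputs
  Y <- samples$targets
  N <- nrow(X)
  M <- samples$M
  D <- ncol(X)
  H <- config$hidden_units
  if (N < 200)
    stop_ncreann("too few regression rows to train (", N, " < 200)")
  n_par <- H * (D + 1) + M * (H + 1)
  if (N < 10 * n_par)
    warning(sprintf("only %d rows for %d network parameters (< 10x)",
                    N, n_par), call. = FALSE)

  set.seed(child_seed(config$perm_seed %||% config$seed, 101))
  perm <- sample.int(N)
  cuts <- floor(seq(0, N, length.out = 11))   # ten blocks of ~N/10
  block <- function(g) perm[(cuts[g] + 1):cuts[g + 1]]

  act_id <- if (config$activation == "tanh") 0L else 1L
  models <- vector("list", config$n_folds)
  rows <- vector("list", config$n_folds)
  for (k in seq_len(config$n_folds)) {
    test_idx <- block(k)
    val_idx <- block(if (k == 10) 1 else k + 1)
    train_idx <- setdiff(perm, c(test_idx, val_idx))
    set.seed(child_seed(config$seed, 202, k))
    lo <- config$init_range[1]; hi <- config$init_range[2]
    W1 <- matrix(runif(H * D, lo, hi), H, D)
    b1 <- runif(H, lo, hi)
    W2 <- matrix(runif(M * H, lo, hi), M, H)
    b2 <- runif(M, lo, hi)
    res <- train_mlp_cpp(X, Y, train_idx - 1L, val_idx - 1L,
                         W1, b1, W2, b2, act_id,
                         config$learning_rate, config$momentum,
                         config$lr_up, config$lr_down,
                         config$max_error_increase,
                         config$max_epochs, config$patience)
    if (isTRUE(res$diverged))
      stop_ncreann(sprintf(
        "training diverged in fold %d (last train MSE %.3g); lower the learning rate",
        k, utils::tail(res$train_mse, 1)[1] %||% NA))
    model <- structure(list(W1 = res$W1, b1 = as.numeric(res$b1),
                            W2 = res$W2, b2 = as.numeric(res$b2),
                            activation = config$activation,
                            p = config$p, M = M,
                            channel_labels = samples$channel_labels,
                            standardization = standardization,
                            history = list(train_mse = res$train_mse,
                                           val_mse = res$val_mse,
                                           lr = res$lr,
                                           accepted = res$accepted)),
                       class = "nmvar_model")
    models[[k]] <- model
    m_tr <- compute_metrics(Y[train_idx, , drop = FALSE],
                            predict(model, X[train_idx, , drop = FALSE]))
    m_va <- compute_metrics(Y[val_idx, , drop = FALSE],
                            predict(model, X[val_idx, , drop = FALSE]))
    m_te <- compute_metrics(Y[test_idx, , drop = FALSE],
                            predict(model, X[test_idx, , drop = FALSE]))
    rows[[k]] <- data.frame(fold = k, epochs = res$epochs,
                            mse_train = m_tr$mse, r2_train = m_tr$r2,
                            mse_val = m_va$mse, r2_val = m_va$r2,
                            mse_test = m_te$mse, r2_test = m_te$r2)
  }
  metrics <- do.call(rbind, rows)
  structure(list(models = models, metrics = metrics,
                 aggregates = list(min_r2_test = min(metrics$r2_test),
                                   max_mse_test = max(metrics$mse_test),
                                   max_gap = max(abs(metrics$r2_test -
                                                     metrics$r2_train))),
                 config = config,
                 fold_blocks = lapply(seq_len(config$n_folds), block)),
            class = "ncreann_fit")
}

#' @export
print.ncreann_fit <- function(x, ...) {
  cat(sprintf("<ncreann_fit> %d folds, M = %d, p = %d, H = %d (%s)\n",
              length(x$models), x$models[[1]]$M, x$config$p,
              x$config$hidden_units, x$config$activation))
  cat(sprintf("  test R2: %.3f .. %.3f, max |R2_test - R2_train| = %.3f\n",
              min(x$metrics$r2_test), max(x$metrics$r2_test),
              x$aggregates$max_gap))
  invisible(x)
}

#' Evaluate the fitted network on lag-vector inputs
#'
#' @param object an `nmvar_model`.
#' @param inputs numeric matrix (rows of length M*p) or a single row vector.
#' @param ... unused.
#' @return Matrix of predicted current samples, one column per channel.
#' @export
predict.nmvar_model <- function(object, inputs, ...) {
  if (is.vector(inputs)) inputs <- matrix(inputs, nrow = 1)
  if (ncol(inputs) != ncol(object$W1))
    stop_ncreann("input rows must have length M*p = ", ncol(object$W1))
  A <- inputs %*% t(object$W1)
  A <- sweep(A, 2, object$b1, "+")
  Hc <- if (object$activation == "tanh") tanh(A) else A
  P <- Hc %*% t(object$W2)
  sweep(P, 2, object$b2, "+")
}

#' Pooled fit metrics
#'
#' Mean squared error pooled over channels, and R-squared
#' `1 - SS_res / SS_tot` with total sums of squares taken around each
#' channel's own mean and pooled across channels.
#'
#' @param targets,predictions numeric matrices of equal dimension
#'   (rows = samples, columns = channels).
#' @return List with `mse` and `r2`.
#' @export
#' @examples
#' compute_metrics(cbind(0:3), cbind(c(0, 1, 2, 5)))
compute_metrics <- function(targets, predictions) {
  targets <- as.matrix(targets)
  predictions <- as.matrix(predictions)
  if (!all(dim(targets) == dim(predictions)))
    stop_ncreann("'targets' and 'predictions' must have equal dimensions")
  if (nrow(targets) < 2) stop_ncreann("need at least 2 rows")
  ss_tot <- sum(sweep(targets, 2, colMeans(targets))^2)
  if (ss_tot == 0) stop_ncreann("targets have zero variance")
  ss_res <- sum((targets - predictions)^2)
  list(mse = ss_res / length(targets), r2 = 1 - ss_res / ss_tot)
}
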