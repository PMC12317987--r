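hand_model <- function(W1, b1, W2, b2, activation = "tanh", p = 1,
                       M = ncol(W1) / p) {
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 activation = activation, p = p, M = M,
                 channel_labels = paste0("ch", seq_len(M))),
            class = "nmvar_model")
}

hand_samples <- function(X, p, M) {
  structure(list(inputs = X, targets = matrix(0, nrow(X), M), p = p, M = M,
                 channel_labels = paste0("ch", seq_len(M)),
                 source_sample_index = seq_len(nrow(X))),
            class = "regression_samples")
}

test_that("Taylor linear part reduces to the weight product", {
  set.seed(20)
  W1 <- matrix(rnorm(12), 3, 4); W2 <- matrix(rnorm(6), 2, 3)
  lin <- hand_model(W1, rep(0.7, 3), W2, c(0, 0), activation = "identity",
                    p = 2)
  A <- taylor_linear_part(lin)
  expect_equal(A[[1]], (W2 %*% W1)[, 1:2])
  expect_equal(A[[2]], (W2 %*% W1)[, 3:4])

  th0 <- hand_model(W1, rep(0, 3), W2, c(0, 0), p = 2)   # tanh'(0) = 1
  expect_equal(taylor_linear_part(th0)[[1]], (W2 %*% W1)[, 1:2])

  one <- hand_model(matrix(c(0.8, -0.3), 1, 2), 0.5, matrix(1.2, 1, 1), 0)
  expect_equal(taylor_linear_part(one)[[1]],
               1.2 * (1 - tanh(0.5)^2) * matrix(c(0.8, -0.3), 1, 2),
               tolerance = 1e-12)
})

test_that("NC vanishes for linear networks and under input shrinkage", {
  set.seed(21)
  W1 <- matrix(rnorm(8), 4, 2); W2 <- matrix(rnorm(8), 2, 4)
  X <- matrix(rnorm(60), 30, 2)
  lin <- hand_model(W1, rnorm(4), W2, c(0, 0), activation = "identity")
  cl <- compute_lc_nc(lin, hand_samples(X, 1, 2))
  expect_true(all(cl$nc == 0))

  th <- hand_model(W1, rnorm(4), W2, c(0, 0))
  ncs <- vapply(c(1, 0.1, 0.01), function(s)
    max(compute_lc_nc(th, hand_samples(X * s, 1, 2))$nc), numeric(1))
  expect_true(all(diff(ncs) < 0))
  expect_lt(ncs[3], 0.02 * ncs[1])   # near-linear decay in the input scale
})

test_that("lC and NC match hand-computed Jacobians", {
  # single hidden unit, 2 channels, p = 1, three fixed input rows
  W1 <- matrix(c(0.6, -0.4), 1, 2); b1 <- 0.2
  W2 <- matrix(c(1.5, -0.8), 2, 1); b2 <- c(0, 0)
  X <- matrix(c(0.5, -1, 0.3, 0.2, 0.8, -0.6), 3, 2)
  mdl <- hand_model(W1, b1, W2, b2)
  got <- compute_lc_nc(mdl, hand_samples(X, 1, 2))
  # exact Jacobian of output j wrt input i: W2[j] * (1 - tanh(a)^2) * W1[i]
  a <- as.numeric(X %*% t(W1)) + b1
  d <- 1 - tanh(a)^2
  d0 <- 1 - tanh(b1)^2
  lc_exp <- nc_exp <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    lc_exp[i, j] <- abs(W2[j, 1] * d0 * W1[1, i])
    nc_exp[i, j] <- mean(abs(W2[j, 1] * d * W1[1, i] -
                             W2[j, 1] * d0 * W1[1, i]))
  }
  expect_equal(unname(got$lc), lc_exp, tolerance = 1e-8)
  expect_equal(unname(got$nc), nc_exp, tolerance = 1e-8)
})

test_that("time-shifted surrogates permute channels circularly", {
  x <- var1_coupled(L = 4096, seed = 22)
  s <- time_shifted_surrogate(x, seed = 1)
  for (c in 1:2)
    expect_equal(sort(s$values[, c]), sort(x$values[, c]))
  ac <- function(v) cor(v[-1], v[-length(v)])
  expect_lt(abs(ac(s$values[, 1]) - ac(x$values[, 1])), 0.05)

  offs <- sapply(1:100, function(k)
    attr(time_shifted_surrogate(x, seed = k), "offsets"))
  expect_true(all(offs > 0))
  expect_true(any(offs[1, ] != offs[2, ]))
  expect_true(all(offs >= floor(4096 / 8) & offs <= floor(7 * 4096 / 8)))
})

test_that("significance masking follows the percentile rule", {
  x <- white_noise_ts(M = 2, L = 1024, seed = 23)
  cfg <- fast_config(1, seed = 7, max_epochs = 20, patience = 5)
  sn <- significance_mask(x, cfg, n_surrogates = 10, seed = 31)
  expect_equal(sn$n_used, 10)
  alpha <- 0.05
  expect_equal(sn$sig_nc, sn$p_nc <= alpha)
  expect_true(all(is.na(sn$lc_masked[!sn$sig_lc])))
  expect_true(all(sn$lc_masked[sn$sig_lc] ==
                  sn$observed$lc[sn$sig_lc] | !any(sn$sig_lc)))
  # an observed value below every null must be non-significant
  below <- which(apply(sn$null_nc, c(2, 3), min) > sn$observed$nc)
  if (length(below)) expect_true(all(!sn$sig_nc[below]))
})

test_that("direction is recovered on a one-way coupled system", {
  wins <- 0
  for (seed in 1:5) {
    conn <- quick_connectivity(var1_coupled(a21 = 0.5, L = 4000,
                                            seed = seed),
                               fast_config(1, seed = seed + 40))
    wins <- wins + (conn$lc["ch1", "ch2"] > conn$lc["ch2", "ch1"])
  }
  expect_gte(wins, 4)
})

test_that("fold averaging damps weight-initialization variability", {
  # fix the row permutation so repetitions differ only in initial weights
  x <- var1_coupled(a21 = 0.5, L = 3000, seed = 77)
  smp <- build_regression_samples(standardize(x)$series, 1)
  single <- avg <- numeric(10)
  for (r in 1:10) {
    fit <- fit_ncreann(smp, fast_config(1, seed = r, n_folds = 4,
                                        max_epochs = 15, patience = 5,
                                        perm_seed = 123))
    per_fold <- vapply(fit$models, function(m)
      compute_lc_nc(m, smp)$lc[1, 2], numeric(1))
    single[r] <- per_fold[1]
    avg[r] <- mean(per_fold)
  }
  expect_lt(var(avg), var(single))
})
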