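# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files are read.

# Two-channel VAR(1) with one directed coupling 1 -> 2 of strength `a21`.
var1_coupled <- function(a21 = 0.5, diag_a = 0.5, L = 8000, seed = 1) {
  A <- matrix(c(diag_a, 0, a21, diag_a), 2, 2, byrow = TRUE)
  simulate_nmvar(ground_truth_spec(2, A, noise_sd = 1, length = L,
                                   seed = seed))
}

# Quadratic coupling 1 -> 2 on top of independent AR(1) channels.
quad_coupled <- function(coef = 1.0, L = 2048, seed = 1) {
  nl <- data.frame(target = 2, source = 1, lag = 1, form = "quadratic",
                   coef = coef)
  simulate_nmvar(ground_truth_spec(
    2, list(diag(0.5, 2)), nonlinear_terms = nl, noise_sd = 1,
    length = L, seed = seed))
}

white_noise_ts <- function(M = 2, L = 2048, seed = 1) {
  simulate_nmvar(ground_truth_spec(M, NULL, noise_sd = 1, length = L,
                                   seed = seed))
}

# Fast training configuration for tests.
fast_config <- function(p, seed = 1, n_folds = 2, max_epochs = 60,
                        patience = 10, ...) {
  nmvar_config(p = p, n_folds = n_folds, max_epochs = max_epochs,
               patience = patience, seed = seed, ...)
}

# Standardize + lag samples + fit + fold-averaged connectivity in one call.
quick_connectivity <- function(series, config) {
  smp <- build_regression_samples(standardize(series)$series, config$p)
  compute_lc_nc(fit_ncreann(smp, config), smp)
}

# Brute-force clustering reference, by a different algorithmic route than
# the implementation: build the boolean eps-adjacency matrix, close it
# under matrix multiplication to full reachability, read components off
# the unique closure rows, then drop components below min_pts.
brute_force_dbscan <- function(xyz, eps, min_pts) {
  n <- nrow(xyz)
  if (n == 0) return(integer(0))
  adj <- as.matrix(dist(xyz)) <= eps
  diag(adj) <- TRUE
  repeat {
    nxt <- adj | ((adj %*% adj) > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  lab <- match(apply(adj, 1, paste, collapse = ""),
               unique(apply(adj, 1, paste, collapse = "")))
  sizes <- tabulate(lab)
  lab[sizes[lab] < min_pts] <- 0L
  lab
}

# Compare two labelings as partitions (label values may differ).
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (any((a == 0) != (b == 0))) return(FALSE)
  split_a <- split(seq_along(a)[a > 0], a[a > 0])
  split_b <- split(seq_along(b)[b > 0], b[b > 0])
  setequal(lapply(split_a, sort), lapply(split_b, sort))
}

# Per-subject 2x2 cell matrix (A = repetition, B = alternation;
# 1 = no overlap, 2 = full overlap) from a behavioral summary.
cells_from_summary <- function(summ, measure = "hit_rate") {
  cbind(
    A1 = summ[[measure]][summ$response_relation == "repetition" &
                         summ$overlap == "none"],
    A2 = summ[[measure]][summ$response_relation == "repetition" &
                         summ$overlap == "full"],
    B1 = summ[[measure]][summ$response_relation == "alternation" &
                         summ$overlap == "none"],
    B2 = summ[[measure]][summ$response_relation == "alternation" &
                         summ$overlap == "full"])
}
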