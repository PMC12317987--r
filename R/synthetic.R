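#' Ground-truth specification for a coupled nMVAR simulation
#'
#' Describes a generating nonlinear multivariate autoregressive process:
#' current samples of M channels are a linear combination of p past samples
#' of all channels, plus optional smooth nonlinear terms, plus i.i.d.
#' Gaussian noise. Simulations from such a spec are the ground truth against
#' which the estimator is validated.
#'
#' @param n_channels number of channels M.
#' @param linear_coeffs list of per-lag M x M matrices `A[[tau]]`;
#'   `A[[tau]][j, i]` is the effect of channel i at lag tau on channel j
#'   (rows = target, columns = source). `NULL` means no linear dynamics.
#' @param nonlinear_terms data frame (or NULL) with columns `target`,
#'   `source`, `lag`, `form`, `coef`. Supported forms: `"quadratic"`
#'   (`c * x_i(n - tau)^2`), `"tanh"` (`c * tanh(x_i(n - tau))`) and
#'   `"product"` (`c * x_i(n - tau) * x_j(n - tau)` with j the target
#'   channel, a source-by-target interaction).
#' @param noise_sd innovation standard deviation, scalar or per channel.
#' @param length number of samples L to return (after burn-in).
#' @param burn_in transient samples discarded before recording; must be at
#'   least `10 * p`.
#' @param seed RNG seed.
#' @return An object of class `ground_truth_spec`.
#' @export
#' @examples
#' sp <- ground_truth_spec(2, list(matrix(c(0.5, 0.4, 0, 0.5), 2, 2)),
#'                         noise_sd = 1, length = 1000, seed = 1)
ground_truth_spec <- function(n_channels, linear_coeffs = NULL,
                              nonlinear_terms = NULL, noise_sd = 1,
                              length = 1000L, burn_in = 500L, seed = 1L) {
  M <- as.integer(n_channels)
  if (M < 1) stop_ncreann("'n_channels' must be >= 1")
  if (is.null(linear_coeffs)) linear_coeffs <- list(matrix(0, M, M))
  if (is.matrix(linear_coeffs)) linear_coeffs <- list(linear_coeffs)
  linear_coeffs <- lapply(linear_coeffs, function(a) {
    a <- as.matrix(a)
    if (!all(dim(a) == c(M, M)))
      stop_ncreann("each linear coefficient matrix must be ", M, " x ", M)
    a
  })
  p <- length(linear_coeffs)
  if (length(as.integer(length)) != 1 || as.integer(length) <= 0)
    stop_ncreann("'length' must be a positive sample count")
  if (burn_in < 10 * p)
    stop_ncreann("'burn_in' must be at least 10 * model order (", 10 * p, ")")
  noise_sd <- rep_len(as.double(noise_sd), M)
  if (any(noise_sd < 0)) stop_ncreann("'noise_sd' must be >= 0")
  if (!is.null(nonlinear_terms)) {
    nonlinear_terms <- as.data.frame(nonlinear_terms)
    need <- c("target", "source", "lag", "form", "coef")
    if (!all(need %in% names(nonlinear_terms)))
      stop_ncreann("'nonlinear_terms' needs columns ",
                   paste(need, collapse = ", "))
    if (!all(nonlinear_terms$form %in% c("quadratic", "tanh", "product")))
      stop_ncreann("nonlinear 'form' must be quadratic, tanh or product")
    if (any(nonlinear_terms$lag > p))
      stop_ncreann("nonlinear term lag exceeds the linear order p = ", p)
    if (any(nonlinear_terms$target > M | nonlinear_terms$source > M |
            nonlinear_terms$target < 1 | nonlinear_terms$source < 1))
      stop_ncreann("nonlinear term channel index out of range")
  }
  rho <- companion_spectral_radius(linear_coeffs)
  if (rho >= 1)
    stop_ncreann(sprintf(paste0(
      "linear part is non-stationary: companion spectral radius %.4f >= 1; ",
      "shrink the coefficients"), rho))
  structure(list(n_channels = M, linear_coeffs = linear_coeffs,
                 nonlinear_terms = nonlinear_terms, noise_sd = noise_sd,
                 length = as.integer(length), burn_in = as.integer(burn_in),
                 seed = as.integer(seed), order = p,
                 spectral_radius = rho),
            class = "ground_truth_spec")
}

# Spectral radius of the VAR(p) companion matrix [A1 ... Ap; I 0].
companion_spectral_radius <- function(A) {
  M <- nrow(A[[1]]); p <- length(A)
  C <- matrix(0, M * p, M * p)
  for (tau in seq_len(p)) C[1:M, ((tau - 1) * M + 1):(tau * M)] <- A[[tau]]
  if (p > 1) C[(M + 1):(M * p), 1:(M * (p - 1))] <- diag(M * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Simulate a coupled nonlinear MVAR process
#'
#' Generates `spec$length` samples of the process described by a
#' [ground_truth_spec()] after discarding the burn-in transient. Each
#' channel at time n is the linear lag sum over all channels, plus the
#' listed nonlinear terms, plus Gaussian innovation noise.
#'
#' @param spec a [ground_truth_spec()].
#' @return A [ts_matrix()] with `fs = 256` Hz (override via attribute-level
#'   helpers downstream if needed) and one trial.
#' @param fs sampling rate stamped on the output, Hz.
#' @export
#' @examples
#' x <- simulate_nmvar(ground_truth_spec(1, matrix(0.9), noise_sd = 1,
#'                                       length = 500, seed = 7))
simulate_nmvar <- function(spec, fs = 256) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  M <- spec$n_channels
  p <- spec$order
  Ltot <- spec$length + spec$burn_in
  set.seed(spec$seed)
  eps <- matrix(rnorm(Ltot * M), Ltot, M) %*% diag(spec$noise_sd, M)
  x <- matrix(0, Ltot, M)
  x[seq_len(p), ] <- eps[seq_len(p), ]
  nl <- spec$nonlinear_terms
  A <- spec$linear_coeffs
  for (n in (p + 1):Ltot) {
    xn <- eps[n, ]
    for (tau in seq_len(p)) xn <- xn + as.vector(A[[tau]] %*% x[n - tau, ])
    if (!is.null(nl)) {
      for (r in seq_len(nrow(nl))) {
        xs <- x[n - nl$lag[r], nl$source[r]]
        xn[nl$target[r]] <- xn[nl$target[r]] + nl$coef[r] * switch(
          nl$form[r],
          quadratic = xs^2,
          tanh      = tanh(xs),
          product   = xs * x[n - nl$lag[r], nl$target[r]])
      }
    }
    if (any(abs(xn) > 1e9))
      stop_ncreann("simulation diverged at sample ", n,
                   "; nonlinear terms destabilize the process")
    x[n, ] <- xn
  }
  ts_matrix(x[(spec$burn_in + 1):Ltot, , drop = FALSE], fs = fs)
}

#' Band-resonant AR(2) coefficients
#'
#' Places a complex pole pair at the center frequency of an oscillatory
#' band, so a channel driven by these coefficients has its spectral peak
#' inside the band: `a1 = 2 r cos(2 pi f0 / fs)`, `a2 = -r^2`.
#'
#' @param band `"theta"`, `"alpha"` or `"beta"`.
#' @param fs sampling rate in Hz; must exceed twice the band's upper edge.
#' @param pole_radius pole magnitude r in (0, 1); closer to 1 gives a
#'   sharper spectral peak.
#' @return Numeric vector `c(a1, a2)` of lag-1 and lag-2 coefficients.
#' @export
#' @examples
#' band_resonant_coeffs("alpha", fs = 256, pole_radius = 0.95)
band_resonant_coeffs <- function(band, fs = 256, pole_radius = 0.95) {
  edges <- band_edges(band)
  if (fs <= 2 * edges[2])
    stop_ncreann("'fs' must exceed twice the band upper edge (",
                 2 * edges[2], " Hz)")
  r <- pole_radius
  if (!is.numeric(r) || r < 0 || r >= 1)
    stop_ncreann("'pole_radius' must lie in [0, 1)")
  f0 <- mean(edges)
  c(a1 = 2 * r * cos(2 * pi * f0 / fs), a2 = -r^2)
}

#' Synthetic source-power volume with blob-shaped activity
#'
#' Builds a neural-activity-index-like positive voxel volume: a constant
#' baseline plus Gaussian-profile blobs plus Gaussian noise. Used as a
#' fixture for top-percentile thresholding and cluster extraction.
#'
#' @param dims integer vector `c(nx, ny, nz)` of voxel counts.
#' @param spacing grid edge length in mm (default 5).
#' @param blobs list of blobs, each a list with `center` (voxel indices,
#'   1-based, length 3), `radius` (Gaussian sd in mm) and `amplitude`.
#' @param baseline constant added to every voxel.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed RNG seed.
#' @return A [source_volume()].
#' @export
#' @examples
#' v <- generate_source_volume(c(10, 10, 10), blobs = list(
#'   list(center = c(5, 5, 5), radius = 8, amplitude = 10)), seed = 1)
generate_source_volume <- function(dims, spacing = 5, blobs = list(),
                                   baseline = 1, noise_sd = 0, seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims <= 0))
    stop_ncreann("'dims' must be three positive voxel counts")
  for (b in blobs) {
    if (any(b$center < 1) || any(b$center > dims))
      stop_ncreann("blob center must lie inside the grid")
  }
  set.seed(seed)
  coords <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                                  k = seq_len(dims[3])))
  val <- rep(baseline, nrow(coords))
  for (b in blobs) {
    d2 <- colSums((t(coords) - b$center)^2) * spacing^2
    val <- val + b$amplitude * exp(-d2 / (2 * b$radius^2))
  }
  if (noise_sd > 0) val <- val + rnorm(length(val), sd = noise_sd)
  source_volume(array(val, dim = dims), spacing = spacing)
}

#' Behavioral generator specification
#'
#' Parameters of the synthetic prime-probe behavioral experiment: a 2x2
#' within-subject design crossing response relation (repetition vs
#' alternation) with feature overlap (no overlap vs full overlap). Cell
#' accuracies and reaction-time means are population values; subjects get
#' random intercepts.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_condition trials per subject per design cell.
#' @param accuracy_means named numeric vector of cell probabilities with
#'   names `rep_none`, `rep_full`, `alt_none`, `alt_full`.
#' @param rt_means_ms,rt_sd_ms per-cell reaction-time means and trial-level
#'   sd in ms (scalar sd is recycled).
#' @param subject_sd between-subject spread: the sd of a standard-normal
#'   subject factor applied as `subject_sd` logits to accuracy and
#'   `100 * subject_sd` ms to reaction time (independent draws).
#' @param seed RNG seed.
#' @return An object of class `behavior_gen_spec`.
#' @export
behavior_gen_spec <- function(n_subjects, trials_per_condition,
                              accuracy_means, rt_means_ms,
                              rt_sd_ms = 80, subject_sd = 0.3, seed = 1L) {
  cells <- c("rep_none", "rep_full", "alt_none", "alt_full")
  if (!all(cells %in% names(accuracy_means)))
    stop_ncreann("'accuracy_means' must name all four cells: ",
                 paste(cells, collapse = ", "))
  if (!all(cells %in% names(rt_means_ms)))
    stop_ncreann("'rt_means_ms' must name all four cells")
  accuracy_means <- accuracy_means[cells]
  rt_means_ms <- rt_means_ms[cells]
  if (any(accuracy_means < 0 | accuracy_means > 1))
    stop_ncreann("accuracies must be probabilities in [0, 1]")
  rt_sd_ms <- rep_len(as.double(rt_sd_ms), 4)
  if (any(rt_sd_ms <= 0)) stop_ncreann("'rt_sd_ms' must be > 0")
  if (n_subjects < 1 || trials_per_condition < 1)
    stop_ncreann("need at least one subject and one trial per cell")
  structure(list(n_subjects = as.integer(n_subjects),
                 trials_per_condition = as.integer(trials_per_condition),
                 accuracy_means = accuracy_means, rt_means_ms = rt_means_ms,
                 rt_sd_ms = stats::setNames(rt_sd_ms, cells),
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "behavior_gen_spec")
}

#' Simulate a prime-probe behavioral trial table
#'
#' Draws per-trial probe correctness as Bernoulli around subject-and-cell
#' accuracies (subject intercepts on the logit scale) and reaction times as
#' Gaussian around subject-and-cell means; reaction times are recorded only
#' for correct probe responses. Prime (R1) correctness is drawn at a fixed
#' 0.98 rate, independent of condition.
#'
#' @param spec a [behavior_gen_spec()].
#' @return A data frame with columns `subject`, `trial`,
#'   `response_relation` (`repetition`/`alternation`), `overlap`
#'   (`none`/`full`), `correct_R1`, `correct_R2`, `rt` (ms; `NA` for
#'   incorrect probe responses).
#' @export
generate_behavior <- function(spec) {
  stopifnot(inherits(spec, "behavior_gen_spec"))
  set.seed(spec$seed)
  cells <- names(spec$accuracy_means)
  resp <- ifelse(grepl("^rep", cells), "repetition", "alternation")
  over <- ifelse(grepl("none$", cells), "none", "full")
  k <- spec$trials_per_condition
  out <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    u <- rnorm(1, 0, spec$subject_sd)           # accuracy intercept, logits
    v <- rnorm(1, 0, spec$subject_sd) * 100     # RT intercept, ms
    rows <- vector("list", 4)
    for (ci in seq_along(cells)) {
      pc <- stats::plogis(stats::qlogis(
        min(max(spec$accuracy_means[ci], 1e-6), 1 - 1e-6)) + u)
      correct2 <- stats::rbinom(k, 1, pc) == 1
      rt <- ifelse(correct2,
                   rnorm(k, spec$rt_means_ms[ci] + v, spec$rt_sd_ms[ci]),
                   NA_real_)
      rt[!is.na(rt) & rt < 1] <- 1   # physical floor
      rows[[ci]] <- data.frame(
        subject = s, response_relation = resp[ci], overlap = over[ci],
        correct_R1 = stats::rbinom(k, 1, 0.98) == 1,
        correct_R2 = correct2, rt = rt)
    }
    out[[s]] <- do.call(rbind, rows)
  }
  tab <- do.call(rbind, out)
  tab$trial <- stats::ave(tab$subject, tab$subject, FUN = seq_along)
  tab[c("subject", "trial", "response_relation", "overlap",
        "correct_R1", "correct_R2", "rt")]
}
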