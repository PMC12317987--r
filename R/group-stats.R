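#' Per-subject behavioral summaries
#'
#' Collapses a trial table to one row per subject and design cell with the
#' hit rate (correct probe responses divided by all events in the cell,
#' misses and false responses included in the denominator) and the mean
#' reaction time over correct probe responses. A cell with no correct
#' response gets an `NA` reaction time.
#'
#' @param table behavioral trial data frame as produced by
#'   [generate_behavior()] (columns `subject`, `response_relation`,
#'   `overlap`, `correct_R2`, `rt`).
#' @return Data frame with columns `subject`, `response_relation`,
#'   `overlap`, `n_trials`, `hit_rate` (percent) and `mean_rt` (ms).
#' @export
summarize_behavior <- function(table) {
  need <- c("subject", "response_relation", "overlap", "correct_R2", "rt")
  if (!all(need %in% names(table)))
    stop_ncreann("trial table needs columns ", paste(need, collapse = ", "))
  key <- interaction(table$subject, table$response_relation, table$overlap,
                     drop = FALSE)
  subjects <- sort(unique(table$subject))
  cells <- expand.grid(response_relation = c("repetition", "alternation"),
                       overlap = c("none", "full"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(subjects, function(s) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
      sel <- table$subject == s &
        table$response_relation == cells$response_relation[ci] &
        table$overlap == cells$overlap[ci]
      if (!any(sel))
        stop_ncreann(sprintf("subject %s has no trials in cell %s/%s", s,
                             cells$response_relation[ci], cells$overlap[ci]))
      n <- sum(sel)
      hits <- sum(table$correct_R2[sel])
      rts <- table$rt[sel & table$correct_R2]
      data.frame(subject = s,
                 response_relation = cells$response_relation[ci],
                 overlap = cells$overlap[ci], n_trials = n,
                 hit_rate = 100 * hits / n,
                 mean_rt = if (length(rts) && any(!is.na(rts)))
                   mean(rts, na.rm = TRUE) else NA_real_)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' 2x2 repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA on one value per subject and
#' design cell. Every effect has a single numerator degree of freedom, so
#' each F equals the squared paired-t statistic of the corresponding
#' subject-level contrast: `(a1 + a2) - (b1 + b2)` for the first main
#' effect, `(a1 + b1) - (a2 + b2)` for the second, and the
#' difference-of-differences for the interaction. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error) = F / (F + df_error)`.
#'
#' @param cell_means numeric matrix or data frame, one row per subject,
#'   four columns named `A1`, `A2`, `B1`, `B2` (factor one = A/B, factor
#'   two = 1/2); or any 4-column matrix taken in that order.
#' @param factor_names length-2 character vector naming the factors.
#' @return Data frame with one row per effect (`factor1`, `factor2`,
#'   `interaction`): `F`, `df1`, `df2`, `p`, `pes` (partial eta squared).
#' @export
#' @examples
#' m <- cbind(A1 = rnorm(10, 1), A2 = rnorm(10), B1 = rnorm(10),
#'            B2 = rnorm(10))
#' rm_anova_2x2(m)
rm_anova_2x2 <- function(cell_means,
                         factor_names = c("factor1", "factor2")) {
  m <- as.matrix(cell_means)
  if (ncol(m) != 4) stop_ncreann("need exactly four cell-mean columns")
  if (nrow(m) < 3) stop_ncreann("need at least 3 subjects")
  if (anyNA(m)) stop_ncreann("missing cell means; complete cases required")
  n <- nrow(m)
  contrasts <- list(
    c(1, 1, -1, -1) / 2,    # main effect of factor 1 (A vs B)
    c(1, -1, 1, -1) / 2,    # main effect of factor 2 (1 vs 2)
    c(1, -1, -1, 1))        # interaction: difference of differences
  effs <- c(factor_names, "interaction")
  out <- do.call(rbind, lapply(seq_along(contrasts), function(e) {
    d <- as.vector(m %*% contrasts[[e]])
    t_stat <- if (sd(d) == 0) 0 else mean(d) / (sd(d) / sqrt(n))
    F_stat <- t_stat^2
    p <- if (sd(d) == 0) 1 else 2 * pt(-abs(t_stat), n - 1)
    data.frame(effect = effs[e], F = F_stat, df1 = 1, df2 = n - 1, p = p,
               pes = F_stat / (F_stat + (n - 1)))
  }))
  rownames(out) <- NULL
  out
}

#' Normality-routed paired comparison
#'
#' Tests the per-subject differences for normality with a
#' Kolmogorov-Smirnov-type test (Lilliefors-corrected by default, since
#' mean and sd are estimated from the data); if normality is not rejected
#' at alpha = 0.05 a two-tailed paired t-test is used, otherwise a
#' two-tailed Wilcoxon signed-rank test with Pratt handling of zero
#' differences (normal approximation with tie correction).
#'
#' @param a,b paired numeric vectors (same subjects, length >= 5). `NA`
#'   pairs are dropped.
#' @param ks_variant `"lilliefors"` (default) or `"ks"` (plain KS against a
#'   normal with estimated parameters).
#' @return List: `test` (`"t"` or `"wilcoxon"`), `statistic` (t or Z), `p`,
#'   `n`, `ks_p`, `mean_diff`.
#' @export
paired_compare <- function(a, b, ks_variant = c("lilliefors", "ks")) {
  ks_variant <- match.arg(ks_variant)
  keep <- stats::complete.cases(a, b)
  d <- (a - b)[keep]
  n <- length(d)
  if (n < 5) stop_ncreann("need at least 5 complete pairs, have ", n)
  if (all(d == 0)) {
    return(list(test = "t", statistic = 0, p = 1, n = n, ks_p = NA_real_,
                mean_diff = 0))
  }
  ks_p <- if (sd(d) == 0) 0 else if (ks_variant == "lilliefors")
    suppressWarnings(nortest::lillie.test(d)$p.value)
  else suppressWarnings(ks.test(d, "pnorm", mean(d), sd(d))$p.value)
  if (!is.na(ks_p) && ks_p >= 0.05) {
    tt <- t.test(d)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         n = n, ks_p = ks_p, mean_diff = mean(d))
  } else {
    z <- wilcoxon_pratt(d)
    list(test = "wilcoxon", statistic = z$z, p = z$p, n = n, ks_p = ks_p,
         mean_diff = mean(d))
  }
}

# Wilcoxon signed-rank with Pratt zero handling: zeros are ranked with the
# rest, then their ranks are discarded; normal approximation with tie and
# zero corrections on the variance.
wilcoxon_pratt <- function(d) {
  r <- rank(abs(d))
  nz <- d != 0
  w_pos <- sum(r[nz & d > 0])
  n <- length(d)
  n0 <- sum(!nz)
  mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
  ties <- table(r[nz])
  sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(list(z = 0, p = 1))
  z <- (w_pos - mu) / sqrt(sig2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Pairwise-complete Spearman correlation matrix
#'
#' Correlates every pair of columns using the subjects complete on that
#' pair (mirroring analyses restricted to subjects with no missing values
#' in the required variables). Ranks use midranks for ties. Two-tailed
#' p-values come from the t approximation for n >= 10 and from the exact
#' null distribution below that (via [stats::cor.test()]). Pairs with
#' fewer than 5 complete subjects are reported as missing with a warning.
#'
#' @param values numeric matrix or data frame, subjects in rows, variables
#'   in columns; may contain `NA`.
#' @return List of matrices `r`, `p` and `n` (pairwise n used).
#' @export
#' @examples
#' spearman_matrix(cbind(a = 1:5, b = c(2, 1, 4, 3, 5)))$r
spearman_matrix <- function(values) {
  m <- as.matrix(values)
  v <- ncol(m)
  if (v < 2) stop_ncreann("need at least 2 variables")
  labs <- colnames(m) %||% paste0("v", seq_len(v))
  r <- p <- nn <- matrix(NA_real_, v, v, dimnames = list(labs, labs))
  diag(r) <- 1; diag(p) <- 0
  diag(nn) <- colSums(!is.na(m))
  for (i in seq_len(v - 1)) for (j in (i + 1):v) {
    keep <- stats::complete.cases(m[, i], m[, j])
    n <- sum(keep)
    nn[i, j] <- nn[j, i] <- n
    if (n < 5) {
      warning(sprintf("pair (%s, %s): only %d complete subjects; skipped",
                      labs[i], labs[j], n), call. = FALSE)
      next
    }
    x <- rank(m[keep, i]); y <- rank(m[keep, j])
    rs <- cor(x, y)
    r[i, j] <- r[j, i] <- rs
    p[i, j] <- p[j, i] <- if (n >= 10) {
      if (abs(rs) >= 1) 0
      else 2 * pt(-abs(rs * sqrt((n - 2) / (1 - rs^2))), n - 2)
    } else {
      suppressWarnings(stats::cor.test(m[keep, i], m[keep, j],
                                       method = "spearman")$p.value)
    }
  }
  list(r = r, p = p, n = nn)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: sort the m p-values ascending, find the largest i
#' with `p(i) <= (i / m) * q`, and reject every p-value at or below that
#' critical value (0 if none qualifies).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q false-discovery rate (default 0.05).
#' @return List: `rejected` (logical, input order), `critical_value` (the
#'   largest rejected p-value, 0 if none), `n_rejected`.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.04, 0.05))
bh_fdr <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (length(p) == 0) stop_ncreann("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_ncreann("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= (seq_len(m) / m) * q)
  if (length(ok) == 0) {
    return(list(rejected = rep(FALSE, m), critical_value = 0,
                n_rejected = 0L))
  }
  crit <- ps[max(ok)]
  list(rejected = p <= crit, critical_value = crit,
       n_rejected = sum(p <= crit))
}
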