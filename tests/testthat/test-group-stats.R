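test_that("behavioral summaries compute hit rate over all events", {
  tab <- data.frame(
    subject = 1,
    response_relation = rep(c("repetition", "alternation"), each = 192),
    overlap = rep(rep(c("none", "full"), each = 96), 2),
    correct_R1 = TRUE,
    correct_R2 = c(rep(c(TRUE, FALSE), c(90, 6)), rep(TRUE, 96),
                   rep(c(TRUE, FALSE), c(48, 48)), rep(FALSE, 96)),
    rt = 500)
  summ <- summarize_behavior(tab)
  get <- function(rr, ov, col)
    summ[[col]][summ$response_relation == rr & summ$overlap == ov]
  expect_equal(get("repetition", "none", "hit_rate"), 93.75)
  expect_equal(get("repetition", "full", "hit_rate"), 100)
  expect_equal(get("repetition", "full", "mean_rt"), 500)
  expect_true(is.na(get("alternation", "full", "mean_rt")))
  expect_equal(get("alternation", "full", "hit_rate"), 0)
  expect_error(summarize_behavior(tab[tab$overlap == "none", ]),
               "no trials")
})

test_that("the 2x2 ANOVA matches its algebraic identities", {
  same <- matrix(rep(c(1, 2, 3, 4, 5), 4), ncol = 4)
  a0 <- rm_anova_2x2(same)
  expect_true(all(a0$F == 0))
  expect_true(all(a0$p == 1))

  set.seed(40)
  for (r in 1:50) {
    m <- matrix(rnorm(4 * 12), 12, 4)
    a <- rm_anova_2x2(m)
    d <- (m[, 1] - m[, 2]) - (m[, 3] - m[, 4])
    t_stat <- mean(d) / (sd(d) / sqrt(12))
    expect_equal(a$F[a$effect == "interaction"], t_stat^2,
                 tolerance = 1e-8)
    expect_equal(a$pes, a$F / (a$F + 11), tolerance = 1e-12)
  }
})

test_that("the ANOVA agrees with base aov on random within-subject data", {
  set.seed(41)
  for (r in 1:10) {
    n <- 10
    m <- matrix(rnorm(4 * n, sd = 2), n, 4)
    a <- rm_anova_2x2(m, factor_names = c("f1", "f2"))
    long <- data.frame(
      y = as.vector(m), subject = factor(rep(seq_len(n), 4)),
      f1 = factor(rep(c("a", "a", "b", "b"), each = n)),
      f2 = factor(rep(c("x", "y", "x", "y"), each = n)))
    fit <- summary(aov(y ~ f1 * f2 + Error(subject / (f1 * f2)),
                       data = long))
    f_aov <- c(fit[["Error: subject:f1"]][[1]][1, "F value"],
               fit[["Error: subject:f2"]][[1]][1, "F value"],
               fit[["Error: subject:f1:f2"]][[1]][1, "F value"])
    expect_equal(a$F, f_aov, tolerance = 1e-6)
  }
})

test_that("paired comparisons route by normality and match hand results", {
  expect_equal(paired_compare(1:10, 1:10)[c("statistic", "p")],
               list(statistic = 0, p = 1))

  d <- c(1, 2, 3, 2, 1, 2, 3, 2, 1, 2)
  res <- paired_compare(d, rep(0, 10))
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(res$test, "t")
  expect_equal(res$statistic, t_hand, tolerance = 1e-4)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 9), tolerance = 1e-4)

  routed <- 0
  for (seed in 1:100) {
    set.seed(seed)
    dd <- rexp(50, rate = 0.2)   # strongly skewed differences
    routed <- routed + (paired_compare(dd, rep(0, 50))$test == "wilcoxon")
  }
  expect_gte(routed, 90)
  expect_error(paired_compare(1:3, 3:1), "at least 5")
})

test_that("Spearman correlations use pairwise-complete midranks", {
  m <- cbind(a = 1:8, b = (1:8)^3, c = -(1:8))
  sm <- spearman_matrix(m)
  expect_equal(sm$r["a", "b"], 1)
  expect_equal(sm$r["a", "c"], -1)

  # rank formula oracle: r_s = 1 - 6*sum(d^2)/(n(n^2-1)), d = (-1,1,-1,1,0)
  ex <- spearman_matrix(cbind(x = 1:5, y = c(2, 1, 4, 3, 5)))
  expect_equal(ex$r["x", "y"], 1 - 6 * 4 / (5 * 24))
  expect_equal(ex$r["x", "y"],
               cor(1:5, c(2, 1, 4, 3, 5), method = "spearman"))

  # invariance under strictly monotone transforms
  set.seed(42)
  u <- rnorm(20); v <- rnorm(20)
  base <- spearman_matrix(cbind(u, v))$r[1, 2]
  tr <- spearman_matrix(cbind(exp(u), atan(v)))$r[1, 2]
  expect_equal(base, tr, tolerance = 1e-12)

  # missing entries: pairwise n bookkeeping and the n < 5 warning
  mm <- cbind(x = c(1:6, NA, NA), y = c(2, 1, 4, 3, 6, 5, 7, 8),
              z = c(1, 2, NA, NA, NA, NA, 3, 4))
  ws <- testthat::capture_warnings(sm2 <- spearman_matrix(mm))
  expect_match(ws, "complete subjects", all = TRUE)
  expect_equal(sm2$n["x", "y"], 6)
  expect_true(is.na(sm2$r["x", "z"]))
})

test_that("Benjamini-Hochberg step-up matches enumeration and p.adjust", {
  r <- bh_fdr(c(0.001, 0.01, 0.02, 0.04, 0.05), q = 0.05)
  expect_true(all(r$rejected))
  expect_equal(r$critical_value, 0.05)

  expect_equal(bh_fdr(rep(1, 6))$n_rejected, 0L)
  expect_equal(bh_fdr(rep(1, 6))$critical_value, 0)
  expect_true(bh_fdr(0.04)$rejected)

  set.seed(43)
  for (r in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    got <- bh_fdr(p, q = 0.05)
    expect_identical(got$rejected, p.adjust(p, "BH") <= 0.05)
  }
})
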