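test_that("exact Wilcoxon p matches full sign enumeration, ties included", {
  set.seed(42)
  cases <- c(
    lapply(3:12, function(n) rnorm(n)),                      # continuous
    lapply(4:10, function(n) sample(-3:3, n, replace = TRUE)), # ties + zeros
    list(1:5, c(-2, -2, 2, 2), c(1, 1, 1, -1))
  )
  for (d in cases) {
    if (all(d == 0)) next
    expect_equal(wilcoxon_signed_rank(d, mode = "exact")$p_value,
                 wsr_enum_p(d), tolerance = 1e-12)
  }
})

test_that("Wilcoxon conventions: zeros dropped, symmetry, degenerate input", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5), mode = "exact")$p_value,
               0.0625)
  expect_warning(res <- wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  expect_equal(res$p_value, 1)
  expect_error(wilcoxon_signed_rank(numeric()), "empty")
  set.seed(7)
  for (n in c(8, 40)) {
    d <- rnorm(n)
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcoxon_signed_rank(-d)$p_value)
  }
  # zeros do not change the result beyond being dropped
  d <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(c(d, 0, 0))$p_value,
               wilcoxon_signed_rank(d)$p_value)
})

test_that("Wilcoxon agrees with stats::wilcox.test in both regimes", {
  set.seed(11)
  d_small <- round(rnorm(10), 3)     # no ties, no zeros -> exact comparable
  expect_equal(wilcoxon_signed_rank(d_small, mode = "exact")$p_value,
               wilcox.test(d_small, exact = TRUE)$p.value, tolerance = 1e-10)
  d_big <- rnorm(45)
  expect_equal(wilcoxon_signed_rank(d_big, mode = "normal")$p_value,
               wilcox.test(d_big, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
  # auto switches at 25 nonzero differences
  expect_equal(wilcoxon_signed_rank(rnorm(25))$method, "exact")
  expect_equal(wilcoxon_signed_rank(rnorm(26))$method, "normal_approx")
})

test_that("BH adjustment equals the step-up oracle and propagates NA", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
  p <- c(0.01, NA, 0.4)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[!is.na(adj)], bh_stepup_oracle(p[!is.na(p)]))
  # sorted input gives non-decreasing output
  ps <- sort(runif(30))
  expect_true(all(diff(bh_adjust(ps)) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Fisher exact test equals hypergeometric enumeration", {
  set.seed(5)
  for (i in 1:30) {
    tab <- as.integer(rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1)))
    if (sum(tab[1:2]) == 0 || sum(tab[3:4]) == 0) next
    expect_equal(fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4])$p_value,
                 fisher_enum_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5)$p_value, 1)
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("two-sample Bartlett statistic matches the hand-evaluated formula", {
  x <- c(0.1, 0.2, 0.3, 0.4); y <- c(0.24, 0.25, 0.26, 0.25)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (N - 2)
  num <- (N - 2) * log(sp2) - (n1 - 1) * log(var(x)) - (n2 - 1) * log(var(y))
  corr <- 1 + (1 / (n1 - 1) + 1 / (n2 - 1) - 1 / (N - 2)) / 3
  res <- bartlett_two_sample(x, y)
  expect_equal(res$statistic, num / corr, tolerance = 1e-12)
  expect_equal(res$p_value, pchisq(num / corr, 1, lower.tail = FALSE))
  # symmetry and identity
  expect_equal(bartlett_two_sample(y, x)$statistic, res$statistic)
  same <- bartlett_two_sample(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(bartlett_two_sample(c(1, 1), c(2, 2)), "zero")
})

test_that("t-test wrapper handles paired, degenerate, and pooled cases", {
  res <- t_two_sample(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(res$p_value, 1)
  deg <- t_two_sample(c(1, 2, 3), c(0, 1, 2), paired = TRUE)
  expect_true(is.na(deg$p_value))
  expect_equal(deg$note, "zero_variance")
  expect_error(t_two_sample(1:3, 1:4, paired = TRUE), "equal lengths")
  set.seed(9)
  x <- rnorm(10); y <- rnorm(12, sd = 3)
  expect_equal(t_two_sample(x, y)$p_value,
               t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(t_two_sample(x, y, welch = TRUE)$p_value,
               t.test(x, y)$p.value)
  # permutation within group leaves the unpaired test unchanged
  expect_equal(t_two_sample(sample(x), sample(y))$p_value,
               t_two_sample(x, y)$p_value)
})

test_that("paired t power: size at null, monotonicity, normal-theory limit", {
  expect_equal(paired_t_power(30, 0, 0.1, alpha = 0.05), 0.05, tolerance = 1e-12)
  pw <- vapply(c(10, 20, 40, 80), paired_t_power, numeric(1),
               delta = 0.03, sd = 0.05, alpha = 0.05)
  expect_true(all(diff(pw) > 0))
  pd <- vapply(c(0.01, 0.02, 0.04), function(d)
    paired_t_power(30, d, 0.05, alpha = 0.05), numeric(1))
  expect_true(all(diff(pd) > 0))
  # large-n agreement with the normal-approximation power formula
  n <- 500; delta <- 0.01; s <- 0.08; a <- 0.05
  za <- qnorm(1 - a / 2); ncp <- delta * sqrt(n) / s
  normal_power <- pnorm(-za + ncp) + pnorm(-za - ncp)
  expect_equal(paired_t_power(n, delta, s, a), normal_power,
               tolerance = 0.005)
  expect_error(paired_t_power(45, 0.05, -1), "positive")
  expect_error(paired_t_power(45, 0.05, 0.02, alpha = 1.5), "alpha")
})

test_that("repeat-family coverage fraction arithmetic", {
  expect_equal(fraction_of_copies_interrogated(2000, 1e6), 0.2)
  expect_equal(fraction_of_copies_interrogated(2e6, 1e6), 100)
  expect_error(fraction_of_copies_interrogated(-1, 10), "invalid")
})
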