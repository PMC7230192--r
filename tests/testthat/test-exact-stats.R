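test_that("chi-square goodness-of-fit matches the uncorrected Pearson statistic", {
  r <- chi2_gof(c(54, 95), c(0.5, 0.5))
  expect_equal(r$statistic, 11.28188, tolerance = 1e-5)
  expect_identical(r$df, 1)
  expect_lt(r$p_value, 0.001)
  r0 <- chi2_gof(c(50, 50), c(0.5, 0.5))
  expect_identical(r0$statistic, 0)
  expect_identical(r0$p_value, 1)
  # cross-check against the standard implementation on random inputs
  set.seed(3)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    obs <- rpois(k, 20) + 1
    p <- rgamma(k, 2); p <- p / sum(p)
    ref <- suppressWarnings(stats::chisq.test(obs, p = p, correct = FALSE))
    got <- chi2_gof(obs, p)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(chi2_gof(c(5, 5), c(1, 0)), "zero expected")
  expect_error(chi2_gof(c(5, 5), c(0.6, 0.6)), "sum to 1")
})

test_that("chi-square statistic is invariant under category permutation", {
  obs <- c(12, 30, 7); p <- c(0.2, 0.5, 0.3)
  perm <- c(3, 1, 2)
  expect_equal(chi2_gof(obs, p)$statistic,
               chi2_gof(obs[perm], p[perm])$statistic)
})

test_that("Fisher 2x2 reproduces known exact p-values", {
  # KII vs KIV offspring sex ratios: printed as p = 0.001
  r <- fisher_exact_2x2(rbind(c(54, 95), c(7, 0)))
  expect_equal(r$p_value, stats::fisher.test(rbind(c(54, 95), c(7, 0)))$p.value,
               tolerance = 1e-9)
  expect_lt(abs(r$p_value - 0.001), 5e-4)
  # degenerate margin
  expect_identical(fisher_exact_2x2(rbind(c(3, 0), c(0, 0)))$p_value, 1)
  # full enumeration: two extreme tables of probability 1/choose(10,5) each
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(0, 5)))$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(rbind(c(1, 2), c(-1, 3))), "non-negative")
})

test_that("Fisher tests agree with stats::fisher.test over random small tables", {
  set.seed(7)
  for (i in 1:20) {
    tab <- random_table(2, 2)
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(fisher_exact_2x2(tab)$p_value, ref, tolerance = 1e-9)
    expect_equal(fisher_exact_rxc(tab)$p_value, ref, tolerance = 1e-9)
    # one-sided alternatives
    expect_equal(fisher_exact_2x2(tab, "greater")$p_value,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(tab, "less")$p_value,
                 stats::fisher.test(tab, alternative = "less")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Fisher r x c equals brute-force probability summation for n <= 30", {
  tabs <- list(rbind(c(1, 1), c(1, 1)),
               rbind(c(3, 1, 2), c(0, 4, 1)),
               rbind(c(2, 5), c(4, 1), c(0, 3)),
               rbind(c(6, 2, 1), c(1, 3, 5)))
  for (tab in tabs)
    expect_equal(fisher_exact_rxc(tab)$p_value, oracle_fisher_rxc(tab),
                 tolerance = 1e-9)
  expect_equal(fisher_exact_rxc(rbind(c(1, 1), c(1, 1)))$p_value, 1,
               tolerance = 1e-12)
  set.seed(19)
  for (i in 1:8) {
    tab <- random_table(2, 3)
    expect_equal(fisher_exact_rxc(tab)$p_value, oracle_fisher_rxc(tab),
                 tolerance = 1e-9, label = paste(tab, collapse = ","))
  }
})

test_that("the daughter-karyomorph 2x3 table is significant by full enumeration", {
  r <- fisher_exact_rxc(rbind(c(9, 25, 3), c(21, 6, 0)))
  expect_lt(r$p_value, 0.001)
  expect_equal(r$p_value,
               stats::fisher.test(rbind(c(9, 25, 3), c(21, 6, 0)))$p.value,
               tolerance = 1e-7)
})

test_that("the enumeration guard aborts instead of running unbounded", {
  expect_error(fisher_exact_rxc(rbind(c(40, 35, 55), c(52, 38, 41)), guard = 100),
               "guard exceeded")
})

test_that("exact binomial test uses the probability-ordering two-sided rule", {
  expect_equal(binomial_two_sided(7, 7, 0.5)$p_value, 2 * 0.5^7,
               tolerance = 1e-12)
  expect_identical(binomial_two_sided(0, 0, 0.5)$p_value, 1)
  expect_identical(binomial_two_sided(5, 10, 0.5)$p_value, 1)
  expect_error(binomial_two_sided(1, 2, 1), "inside")
  set.seed(5)
  for (i in 1:10) {
    n <- sample(5:25, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.2, 0.8)
    expect_equal(binomial_two_sided(k, n, p0)$p_value,
                 oracle_binom_two_sided(k, n, p0), tolerance = 1e-9)
    expect_equal(binomial_two_sided(k, n, p0)$p_value,
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-7)
  }
})

test_that("two-sample t matches the closed-form pooled and Welch statistics", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5, 6)
  r <- two_sample_t(x, y)
  # hand-computed pooled formula
  sp2 <- ((3 - 1) * var(x) + (6 - 1) * var(y)) / (3 + 6 - 2)
  expect_equal(r$statistic, (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 6)))
  expect_identical(r$df, 7)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  rw <- two_sample_t(x, y, welch = TRUE)
  refw <- stats::t.test(x, y)
  expect_equal(rw$statistic, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(rw$df, unname(refw$parameter), tolerance = 1e-9)
  # identical samples: t = 0, p = 1
  r0 <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(r0$statistic, 0)
  expect_identical(r0$p_value, 1)
  # p decreases monotonically with mean shift
  set.seed(2); base <- rnorm(40)
  ps <- vapply(c(0.2, 0.6, 1.2), function(d)
    two_sample_t(base, base + d)$p_value, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "zero variance")
  expect_error(two_sample_t(1, c(1, 2)), "at least two")
})

test_that("simulated type-I error of the sex-ratio chi-square is near nominal", {
  set.seed(101)
  n <- 150; reps <- 10000
  k <- rbinom(reps, n, 0.5)
  # Pearson statistic for a 1:1 split reduces to (2k - n)^2 / n
  rej <- vapply(k, function(ki)
    chi2_gof(c(ki, n - ki), c(0.5, 0.5))$p_value < 0.05, NA)
  rate <- mean(rej)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})
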