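kiii_daughters <- data.frame(dam_karyomorph = "KIII", n_dams = 19,
                             n_sons = 0, n_daughters = 27,
                             k_KII = 21, k_KIII = 6, k_KIV = 0)

test_that("progeny_counts validates and pools rows", {
  pc <- progeny_counts(data.frame(dam_karyomorph = c("KII", "KII"),
                                  n_sons = c(3, 4), n_daughters = c(5, 6),
                                  k_KII = c(1, 0), k_KIII = c(2, 2),
                                  k_KIV = c(0, 0)))
  expect_identical(nrow(pc), 1L)
  expect_identical(pc$n_sons, 7)
  expect_identical(pc$n_dams, 2L)
  expect_error(progeny_counts(data.frame(dam_karyomorph = "KV",
                                         n_sons = 1, n_daughters = 1)),
               "KII, KIII, KIV")
  expect_error(progeny_counts(data.frame(dam_karyomorph = "KII", n_sons = 1,
                                         n_daughters = 1, k_KII = 2)),
               "exceed")
})

test_that("log-likelihood has the closed-form binomial value on a sex-ratio-only row", {
  counts <- data.frame(dam_karyomorph = "KIII", n_sons = 70, n_daughters = 101)
  expect_equal(cross_log_likelihood(counts, "mech_a"),
               dbinom(70, 171, 1 / 3, log = TRUE), tolerance = 1e-12)
  expect_identical(cross_log_likelihood(NULL), 0)
  expect_identical(cross_log_likelihood(counts[0, ]), 0)
})

test_that("the standard hypothesis is rejected by the observed KIII daughters", {
  # 6 KIII daughters from KIII dams have probability 0 under standard rules
  expect_identical(cross_log_likelihood(kiii_daughters, "standard"), -Inf)
  expect_true(is.finite(cross_log_likelihood(kiii_daughters, "mech_a")))
})

test_that("Y- and X1-fertilized class odds scale exactly with the sperm weight ratio", {
  # only the ratio of sperm-class weights enters the likelihood
  for (w in c(0.5, 2, 8)) {
    p <- cross_params(w_Y = c(KII = w))
    d <- cross("KII", "KI", "mech_a", p)
    expect_equal(sum(d$norm_p[d$sex == "male"]), 0.5 * w / (1 + w),
                 tolerance = 1e-12)
  }
})

test_that("the MLE sits at the generating value for expectation-exact counts", {
  # counts constructed exactly at the default-parameter expectations
  counts <- data.frame(dam_karyomorph = "KII", n_dams = 10,
                       n_sons = 100, n_daughters = 300,
                       k_KII = 100, k_KIII = 100, k_KIV = 100)
  fit <- fit_parameters(counts, "mech_a", free = "wY_KII", profile = FALSE)
  expect_equal(unname(fit$estimates[["wY_KII"]]), 1, tolerance = 0.02)
})

test_that("sperm-weight recovery from synthetic data is within 20% at n ~ 2000", {
  des <- breeding_design(n_dams = c(KII = 240), karyotyped_fraction = 1)
  sim <- simulate_breeding_experiment(des, "mech_a",
                                      cross_params(w_Y = c(KII = 2)), seed = 402)
  expect_gt(sum(sim$counts$n_sons + sim$counts$n_daughters), 1500)
  fit <- fit_parameters(sim$counts, "mech_a", free = "wY_KII")
  w_hat <- unname(fit$estimates[["wY_KII"]])
  expect_gt(w_hat, 1.6)
  expect_lt(w_hat, 2.4)
  # the 95% profile interval brackets the truth here
  expect_true(fit$intervals["wY_KII", 1] <= 2 && 2 <= fit$intervals["wY_KII", 2])
})

test_that("estimation bias shrinks as the synthetic colony grows", {
  errs <- vapply(c(25, 240), function(nd) {
    sim <- simulate_breeding_experiment(
      breeding_design(n_dams = c(KII = nd), karyotyped_fraction = 1),
      "mech_a", cross_params(w_Y = c(KII = 2)), seed = 402)
    fit <- fit_parameters(sim$counts, "mech_a", free = "wY_KII",
                          profile = FALSE)
    abs(unname(fit$estimates[["wY_KII"]]) - 2)
  }, 0)
  expect_lt(errs[2], errs[1])
})

test_that("the observed colony data favor Y-sperm advantage in KII dams", {
  pc <- load_fixture("progeny")
  fit <- fit_parameters(pc, "mech_a", free = "wY_KII", profile = FALSE)
  expect_gt(unname(fit$estimates[["wY_KII"]]), 1)
})

test_that("a parameter without data leverage is flagged non-identifiable", {
  counts <- data.frame(dam_karyomorph = "KII", n_sons = 10, n_daughters = 30)
  fit <- fit_parameters(counts, "mech_a", free = "wY_KIV", profile = FALSE)
  expect_true(fit$convergence$non_identifiable[["wY_KIV"]])
})

test_that("hypothesis comparison ranks standard last and the mechanisms equally", {
  cmp <- compare_hypotheses(kiii_daughters,
                            c("standard", "mech_a", "mech_b", "mech_c"))
  std <- cmp[cmp$hypothesis == "standard", ]
  expect_true(std$rejected)
  expect_identical(std$logL, -Inf)
  expect_match(std$note, "impossible observation")
  expect_identical(cmp$hypothesis[nrow(cmp)], "standard")
  mech <- cmp[cmp$hypothesis != "standard", ]
  expect_true(all(is.finite(mech$logL)))
  expect_equal(mech$logL, rep(mech$logL[1], 3), tolerance = 1e-12)

  # empty data: all log-likelihoods zero, a tie
  empty <- data.frame(dam_karyomorph = character(0), n_sons = integer(0),
                      n_daughters = integer(0))
  cmp0 <- compare_hypotheses(empty, c("standard", "mech_a"))
  expect_true(all(cmp0$logL == 0))
  expect_false(any(cmp0$rejected))
  expect_error(compare_hypotheses(kiii_daughters, "mech_a"), "at least two")
})

test_that("mech_a and mech_b give identical likelihoods on random synthetic data", {
  sim <- simulate_breeding_experiment(breeding_design(), "mech_a",
                                      cross_params(w_Y = 1.7), seed = 9)
  for (p in list(cross_params(), cross_params(w_Y = 1.7, s_KII = 0.4)))
    expect_equal(cross_log_likelihood(sim$counts, "mech_a", p),
                 cross_log_likelihood(sim$counts, "mech_b", p),
                 tolerance = 1e-12)
})
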