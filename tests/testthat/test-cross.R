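# helper: raw-probability table of a cross keyed like the oracle
raw_by_key <- function(d) {
  key <- vapply(d$zygote, function(s) {
    z <- unclass(as_complement(s))
    paste(z, collapse = ".")
  }, "")
  stats::setNames(d$raw_p, key)
}

test_that("gamete tables match balanced segregation of each sex complex", {
  p <- cross_params()
  g <- gametes("KIV", "female", p, "mech_a")
  expect_identical(g$gamete, "neo-X1/neo-X3")
  expect_identical(g$prob, 1)

  g <- gametes("KII", "female", p, "mech_a")
  expect_setequal(g$gamete, c("neo-X1/neo-X3", "neo-X2"))
  expect_equal(g$prob, c(0.5, 0.5))

  g <- gametes("KIII", "female", p, "mech_a")
  expect_setequal(g$gamete, c("neo-X2", "neo-X3/neo-Y"))
  expect_equal(g$prob, c(0.5, 0.5))

  g <- gametes("KI", "male", p, "mech_a")
  expect_setequal(g$gamete, c("neo-X1/neo-X3", "neo-X3/neo-Y"))

  # segregation probability parameters shift the class weights
  g <- gametes("KII", "female", cross_params(s_KII = 0.8), "mech_a")
  expect_equal(g$prob[g$gamete == "neo-X1/neo-X3"], 0.8)

  # standard bookkeeping drops the acrocentrics; KIII dams make a nullo class
  g <- gametes("KIII", "female", p, "standard")
  expect_setequal(g$gamete, c("neo-X2", "0"))
  expect_error(gametes("UNLISTED", "female", p, "mech_a"), "unsupported karyomorph")
  expect_error(gametes("KII", "male", p, "mech_a"), "female")
})

test_that("cross() equals explicit gamete-pair enumeration on all supported crosses", {
  for (regime in c("xy_female", "standard")) {
    hyp <- if (regime == "standard") "standard" else "mech_a"
    for (dam in c("KII", "KIII", "KIV")) {
      for (w in c(0.3, 1, 2.7)) {
        p <- cross_params(w_Y = stats::setNames(w, dam))
        got <- raw_by_key(cross(dam, "KI", hyp, p))
        want <- oracle_cross_raw(dam, regime, w = w)
        expect_equal(got[sort(names(got))], want[sort(names(want))],
                     tolerance = 1e-12, label = paste(regime, dam, w))
      }
    }
  }
})

test_that("cross distributions are normalized and conserve chromosomes", {
  for (hyp in c("mech_a", "mech_b", "mech_c", "standard"))
    for (dam in c("KII", "KIII", "KIV")) {
      d <- cross(dam, "KI", hyp)
      expect_equal(sum(d$raw_p), 1, tolerance = 1e-12)
      expect_equal(sum(d$norm_p[d$viable]), 1, tolerance = 1e-12)
      expect_true(all(d$norm_p[!d$viable] == 0))
      if (hyp != "standard") {
        # every zygote carries exactly 4 elements: 2 from each balanced gamete
        sizes <- vapply(d$zygote, function(s) {
          z <- unclass(as_complement(s)); sum(z)
        }, 0L)
        # KII and KIII dams alternate 1- and 2-element gametes, so zygotes
        # hold 3 or 4 elements; KIV dams always give 2, so 4
        expect_true(all(sizes %in% if (dam == "KIV") 4L else 3:4))
      }
    }
  expect_error(cross("KII", "KII"), "only male karyomorph is KI")
  expect_error(cross("KI", "KI"), "dam must be")
})

test_that("KII x KI under XY-female defaults gives the four classes at 25% each", {
  d <- cross("KII", "KI", "mech_a")
  expect_identical(nrow(d), 4L)
  expect_setequal(d$karyomorph, c("KI", "KII", "KIII", "KIV"))
  expect_equal(d$norm_p, rep(0.25, 4))
  expect_identical(d$sex[d$karyomorph == "KI"], "male")
  expect_identical(sort(d$karyomorph[d$sex == "female"]), c("KII", "KIII", "KIV"))
})

test_that("expected sex ratios are 25%, 33% and 50% for KII, KIII, KIV dams", {
  expect_equal(expected_sex_ratio("KII", "KI", "mech_a"), 0.25)
  expect_equal(expected_sex_ratio("KIII", "KI", "mech_a"), 1 / 3)
  expect_equal(expected_sex_ratio("KIV", "KI", "mech_a"), 0.5)
  # identical under the other two XY-female mechanisms
  for (mech in c("mech_b", "mech_c"))
    expect_equal(expected_sex_ratio("KIII", "KI", mech), 1 / 3)
})

test_that("nonviable zygote fractions match each hypothesis' lethality load", {
  expect_equal(nonviable_fraction("KIII", "KI", "standard"), 0.75)
  expect_equal(nonviable_fraction("KII", "KI", "standard"), 0.25)
  expect_equal(nonviable_fraction("KIV", "KI", "mech_a"), 0)
  expect_equal(nonviable_fraction("KII", "KI", "mech_a"), 0)
  # the one XY-female lethal class: neo-Y/neo-Y from KIII dams
  expect_equal(nonviable_fraction("KIII", "KI", "mech_a"), 0.25)
})

test_that("daughter karyomorph distributions discriminate the hypotheses", {
  dd <- daughter_karyomorph_distribution("KIII", "KI", "mech_a")
  expect_equal(dd[["KII"]], 0.5)
  expect_equal(dd[["KIII"]], 0.5)
  dd <- daughter_karyomorph_distribution("KIII", "KI", "standard")
  expect_equal(dd[["KII"]], 1)
  dd <- daughter_karyomorph_distribution("KIV", "KI", "mech_a")
  expect_equal(dd[["KIV"]], 1)
})

test_that("fertilization weight w_Y shifts Y-sperm classes with correct limits", {
  # huge w: the Y-fertilized classes (KI sons, KIII daughters) approach 0.5
  d <- cross("KII", "KI", "mech_a", cross_params(w_Y = c(KII = 1e9)))
  expect_equal(d$norm_p[d$karyomorph == "KI"], 0.5, tolerance = 1e-6)
  expect_equal(d$norm_p[d$karyomorph == "KIII"], 0.5, tolerance = 1e-6)
  # w = 0: they vanish
  d <- cross("KII", "KI", "mech_a", cross_params(w_Y = c(KII = 0)))
  expect_equal(d$norm_p[d$karyomorph == "KI"], 0)
  expect_equal(d$norm_p[d$karyomorph == "KIII"], 0)
  # the odds ratio of Y- vs X1-fertilized classes equals w itself
  for (w in c(0.25, 1.5, 4)) {
    d <- cross("KII", "KI", "mech_a", cross_params(w_Y = c(KII = w)))
    expect_equal(d$norm_p[d$karyomorph == "KI"] / d$norm_p[d$karyomorph == "KIV"],
                 w, tolerance = 1e-12)
  }
  # viability renormalization preserves ratios among viable classes
  d1 <- cross("KIII", "KI", "mech_a")
  d2 <- cross("KIII", "KI", "mech_a", cross_params(v_X1X1 = 0.5))
  v1 <- d1[d1$viable, ]; v2 <- d2[d2$viable, ]
  expect_equal(v1$norm_p / v1$norm_p[1], v2$norm_p / v2$norm_p[1])
})

test_that("KIV never appears among daughters of KIII dams under any parameters", {
  set.seed(42)
  for (i in 1:20) {
    p <- cross_params(w_Y = c(KIII = runif(1, 0, 5)),
                      s_KIII = runif(1), v_X1X1 = runif(1))
    for (hyp in c("mech_a", "standard")) {
      dd <- daughter_karyomorph_distribution("KIII", "KI", hyp, p)
      expect_false("KIV" %in% names(dd)[dd > 0])
    }
  }
})
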