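infl_flat <- data.frame(year = 2018:2021, index = rep(100, 4))

mk_visit <- function(patient_id, date, amount, label = "LAB_CHEM",
                     treatment = "PD", acute = FALSE, chronic = FALSE) {
  data.frame(patient_id = patient_id, date = as.Date(date), raw_label = label,
             amount_thb = amount, treatment = treatment, acute = acute,
             chronic = chronic)
}

test_that("direct-medical aggregation: conversion, windowing, inflation", {
  # single 33.57 THB visit at factor 1 is exactly one USD
  v <- mk_visit("a", "2021-03-01", 33.57)
  out <- aggregate_direct_medical(v, inflation = infl_flat)
  expect_equal(out$mean, 1.00, tolerance = 1e-12)

  # two visits 10 days apart collapse into one 30-day observation;
  # 40 days apart gives two observations
  v2 <- rbind(mk_visit("a", "2021-03-01", 100), mk_visit("a", "2021-03-11", 50))
  o2 <- attr(aggregate_direct_medical(v2, inflation = infl_flat), "observations")
  expect_identical(nrow(o2), 1L)
  expect_equal(o2$amount_thb, 150)
  v3 <- rbind(mk_visit("a", "2021-03-01", 100), mk_visit("a", "2021-04-10", 50))
  o3 <- attr(aggregate_direct_medical(v3, inflation = infl_flat), "observations")
  expect_identical(nrow(o3), 2L)

  # inflation: a 2018 visit with index 90 vs 2021 index 100 scales by 100/90
  infl <- data.frame(year = c(2018, 2021), index = c(90, 100))
  v4 <- mk_visit("a", "2018-06-01", 90)
  o4 <- attr(aggregate_direct_medical(v4, inflation = infl), "observations")
  expect_equal(o4$amount_thb_2021, 100, tolerance = 1e-12)

  expect_error(aggregate_direct_medical(
    mk_visit("a", "2021-01-01", 1, label = "NOT_A_LABEL"),
    inflation = infl_flat), "unmapped")
  expect_error(aggregate_direct_medical(
    mk_visit("a", "2010-01-01", 1), inflation = infl_flat), "inflation")
})

test_that("aggregation conserves money and classifies the eight groups", {
  coh <- default_cohort()
  infl <- data.frame(year = 2019:2021, index = c(99, 99.5, 100))
  summ <- aggregate_direct_medical(coh$visits, inflation = infl)
  obs <- attr(summ, "observations")
  expect_equal(attr(summ, "total_usd"),
               attr(summ, "total_thb_2021") / 33.57, tolerance = 1e-9)
  expect_setequal(unique(paste(summ$treatment, summ$complication)),
                  as.vector(outer(c("PD", "HD"),
                                  c("none", "chronic", "acute", "chronic_acute"),
                                  paste)))
  # group means recover the generating 30-day cost means (gamma, known mean)
  spec <- generator_spec()
  for (tr in c("PD", "HD")) {
    for (g in c("none", "chronic")) {
      row <- summ[summ$treatment == tr & summ$complication == g, ]
      truth <- spec$cost_means_usd[[tr]][[g]] * 100 / infl$index[1]
      # windows mix 2019/2020 anchors; inflation factors 100/99..100/99.5
      expect_lt(abs(row$mean / truth - 1), 0.05)
    }
  }
})

test_that("non-medical unit costs use median and IQR", {
  out <- unit_cost_nonmedical(c(1, 2, 3, 4, 5), n_visits = 10)
  expect_equal(out$median, 3)
  expect_equal(out$total, 30)
  one <- unit_cost_nonmedical(7, n_visits = 2)
  expect_equal(one$median, 7)
  expect_equal(one$total, 14)
  # totals scale linearly in visit count
  expect_equal(unit_cost_nonmedical(c(2, 4, 9), n_visits = 8)$total,
               4 * unit_cost_nonmedical(c(2, 4, 9), n_visits = 2)$total)
})

test_that("EQ-5D scoring is additive and guards its domain", {
  tariff <- read_tariff()
  full <- data.frame(mobility = 1, selfcare = 1, activities = 1, pain = 1,
                     anxiety = 1)
  expect_equal(score_eq5d(full, tariff), 1.0)
  prof <- data.frame(mobility = 2, selfcare = 1, activities = 1, pain = 1,
                     anxiety = 2)
  # toy tariff: mobility level-2 decrement 0.10, anxiety level-2 0.11
  expect_equal(score_eq5d(prof, tariff), 1 - 0.10 - 0.11, tolerance = 1e-12)
  bad <- transform(full, pain = 9)
  expect_error(score_eq5d(bad, tariff), "outside tariff range")
  # permutation invariance over record order
  two <- rbind(full, prof)
  expect_equal(rev(score_eq5d(two[2:1, ], tariff)), score_eq5d(two, tariff))
})

test_that("IPWRA equals plain group means under randomised assignment", {
  set.seed(31)
  n <- 4000
  df <- data.frame(
    age = round(runif(n, 30, 80)), sex = rbinom(n, 1, 0.5),
    income = sample(1:3, n, TRUE), region = sample(1:4, n, TRUE),
    education = sample(1:3, n, TRUE), reimbursement = rbinom(n, 1, 0.5),
    fracture = rbinom(n, 1, 0.2), diabetes = rbinom(n, 1, 0.4),
    hypertension = rbinom(n, 1, 0.6), dyslipidaemia = rbinom(n, 1, 0.3),
    cvd = rbinom(n, 1, 0.2),
    treatment = ifelse(rbinom(n, 1, 0.5) == 1, "HD", "PD"),
    chronic = rbinom(n, 1, 0.3))
  lev <- sample(1:2, n, TRUE, prob = c(0.7, 0.3))
  df$mobility <- lev
  df$selfcare <- sample(1:2, n, TRUE)
  df$activities <- sample(1:2, n, TRUE)
  df$pain <- sample(1:2, n, TRUE)
  df$anxiety <- sample(1:2, n, TRUE)
  est <- ipwra_utility(df)
  util <- score_eq5d(df)
  for (tr in c("PD", "HD")) {
    naive <- mean(util[df$treatment == tr])
    row <- est[est$treatment == tr & est$group == "overall", ]
    expect_lt(abs(row$estimate - naive), 3 * row$se)
  }
})

test_that("IPWRA is invariant to rescaling the weights", {
  # doubling all propensity weights cannot change weighted least squares
  set.seed(4)
  n <- 500
  x <- rnorm(n); w <- runif(n, 0.5, 2); y <- 1 + x + rnorm(n)
  f1 <- lm(y ~ x, weights = w)
  f2 <- lm(y ~ x, weights = 2 * w)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
})

test_that("estimated utilities export as a parameter-file fragment", {
  coh <- default_cohort()
  est <- ipwra_utility(coh$eq5d[1:2000, ])
  frag <- utilities_to_params(est)
  expect_named(frag, c("PD", "PD_CC", "HD", "HD_CC"))
  expect_true(all(vapply(frag, function(x) x$low <= x$mean & x$mean <= x$high,
                         logical(1))))
})
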