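test_that("discount factors follow 1/(1+r)^t", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_identical(discount_factor(10, 0), 1)
  expect_error(discount_factor(1, -0.01), "non-negative")
})

test_that("transition matrix composes death first, then switching/complication", {
  p <- base_params()
  # force a known death probability via an exponential mortality model:
  # q = 1 - exp(-(1/scale)) = 0.1  =>  scale = -1/log(0.9)
  m <- mortality_model(shape = 1, scale = -1 / log(0.9), chronic_hr = 1)
  M <- build_matrix(p, m, "PD", start_age = 50, cycle = 0)
  expect_equal(M["PD", "DEATH"], 0.1, tolerance = 1e-12)
  expect_equal(M["PD", "PD"], 0.9 * (1 - 0.039 - 0.162), tolerance = 1e-12)
  expect_equal(M["PD", "HD"], 0.9 * 0.039, tolerance = 1e-12)
  expect_equal(M["PD", "PD_CC"], 0.9 * 0.162, tolerance = 1e-12)
  expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
  # structural zeros and absorbing death
  expect_identical(M["PD_CC", "PD"], 0)
  expect_identical(M["HD_CC", "HD"], 0)
  expect_identical(unname(M["DEATH", ]), c(0, 0, 0, 0, 1))

  # zero mortality, zero transitions -> identity on living states
  p0 <- fixed_params()
  p0 <- set_param_values(p0, c(tp_switch_PD = 0, tp_pd_cc_PD = 0, tp_hd_cc_PD = 0))
  m0 <- mortality_model(shape = 1, scale = 1e12)
  M0 <- build_matrix(p0, m0, "PD", start_age = 50, cycle = 0)
  expect_equal(unname(diag(M0)), rep(1, 5), tolerance = 1e-9)
})

test_that("rows sum to one for random valid parameter draws", {
  p <- base_params()
  m <- toy_mortality()
  set.seed(99)
  for (i in 1:200) {
    d <- sample_parameters(p)
    for (st in c("PD", "HD")) {
      M <- build_matrix(d, m, st, start_age = runif(1, 20, 80),
                        cycle = sample(0:30, 1))
      expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1))
    }
  }
})

test_that("competing probabilities above one renormalise with a warning", {
  p <- fixed_params()
  p <- set_param_values(p, c(tp_switch_PD = 0.6, tp_pd_cc_PD = 0.7))
  m <- toy_mortality()
  expect_warning(M <- build_matrix(p, m, "PD", 50, 0), "renormalised")
  expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
})

test_that("cohort trace conserves mass and death is non-decreasing", {
  p <- base_params()
  tr <- run_cohort(p, toy_mortality(), "PD", start_age = 40)
  expect_equal(unname(rowSums(tr$occupancy)), rep(1, nrow(tr$occupancy)),
               tolerance = 1e-10)
  expect_true(all(diff(tr$occupancy[, "DEATH"]) >= -1e-12))
  expect_identical(unname(tr$occupancy[1, ]), c(1, 0, 0, 0, 0))

  # constant annual death probability q, no other transitions:
  # occupancy of the initial state decays as (1-q)^t
  q <- 0.2
  mfn <- function(cycle) {
    M <- diag(5) * 0
    dimnames(M) <- list(STATES, STATES)
    for (s in 1:4) { M[s, s] <- 1 - q; M[s, 5] <- q }
    M[5, 5] <- 1
    M
  }
  tr2 <- run_cohort(p, toy_mortality(), "PD", start_age = 40, matrix_fn = mfn)
  t_idx <- seq_len(nrow(tr2$occupancy)) - 1
  expect_equal(tr2$occupancy[, "PD"], (1 - q)^t_idx, tolerance = 1e-12)
})

test_that("accrual matches closed forms", {
  p <- fixed_params()
  # deathless, utility 1, zero discount: LY = QALY = number of cycles
  p1 <- set_param_values(p, c(util_PD = 1, tp_switch_PD = 0, tp_pd_cc_PD = 0))
  cfg <- p1$config
  cfg$discount_rate <- 0
  cfg$age_cap <- 50  # 10 cycles from age 40
  m0 <- mortality_model(shape = 1, scale = 1e12)
  tr <- run_cohort(p1, m0, "PD", start_age = 40, config = cfg)
  out <- accrue(tr, p1, config = cfg)
  expect_equal(out$life_years, 10, tolerance = 1e-9)
  expect_equal(out$qalys, 10, tolerance = 1e-9)

  # single state alive exactly 3 cycles at annual cost C, r = 3%:
  # cost = C * (1 + 1/1.03 + 1/1.03^2) + setup
  cfg2 <- p1$config
  cfg2$discount_rate <- 0.03
  cfg2$age_cap <- 43
  cfg2$perspective <- "government"
  tr3 <- run_cohort(p1, m0, "PD", start_age = 40, config = cfg2)
  out3 <- accrue(tr3, p1, config = cfg2)
  v <- param_values(p1)
  C <- v[["cost_dm_PD"]] + 0.052 * v[["cost_acute_addon"]]
  expect_equal(out3$lifetime_cost,
               C * (1 + 1 / 1.03 + 1 / 1.03^2) + v[["cost_setup_PD"]],
               tolerance = 1e-9)
})

test_that("perspectives differ exactly by the non-medical and indirect streams", {
  p <- base_params()
  m <- cal_mortality()
  tr <- run_cohort(p, m$PD, "PD", start_age = 50)
  cfg_g <- p$config; cfg_g$perspective <- "government"
  cfg_s <- p$config; cfg_s$perspective <- "societal"
  gov <- accrue(tr, p, config = cfg_g)
  soc <- accrue(tr, p, config = cfg_s)
  # zero out non-medical and indirect costs: societal must equal government
  p0 <- set_param_values(p, setNames(rep(0, 8), grep("^cost_(dnm|ind)_",
                                                     p$params$id, value = TRUE)))
  soc0 <- accrue(tr, p0, config = cfg_s)
  expect_equal(soc0$lifetime_cost, gov$lifetime_cost, tolerance = 1e-9)
  expect_gt(soc$lifetime_cost, gov$lifetime_cost)
  expect_equal(soc$life_years, gov$life_years)
  expect_error(accrue(tr, p, config = within(cfg_g, perspective <- "payer")),
               "perspective")
})

test_that("outcomes respond monotonically to utilities, costs and discounting", {
  p <- base_params()
  m <- cal_mortality()
  base <- accrue(run_cohort(p, m$PD, "PD", 50), p)
  up_u <- set_param_values(p, c(util_PDCC = 0.65))
  expect_gt(accrue(run_cohort(up_u, m$PD, "PD", 50), up_u)$qalys, base$qalys)
  up_c <- set_param_values(p, c(cost_dm_PD = 9000))
  expect_gt(accrue(run_cohort(up_c, m$PD, "PD", 50), up_c)$lifetime_cost,
            base$lifetime_cost)
  cfg <- p$config; cfg$discount_rate <- 0.05
  hi_r <- accrue(run_cohort(p, m$PD, "PD", 50, config = cfg), p, config = cfg)
  expect_lt(hi_r$lifetime_cost, base$lifetime_cost)
  expect_lt(hi_r$life_years, base$life_years)
  expect_lt(hi_r$qalys, base$qalys)
  # QALYs never exceed life-years
  expect_lte(base$qalys, base$life_years)
})

test_that("cohort engine agrees with the individual-level microsimulation", {
  p <- base_params()
  m <- cal_mortality()
  tr <- run_cohort(p, m$PD, "PD", start_age = 60)
  coh <- accrue(tr, p)
  set.seed(123)
  mic <- microsimulate(p, m$PD, "PD", start_age = 60, n = 2e4)
  for (i in seq_len(nrow(mic))) {
    expect_lt(abs(mic$mean[i] - coh[[mic$outcome[i]]]), 3 * mic$se[i])
  }
})
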