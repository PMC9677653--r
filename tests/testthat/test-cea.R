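test_that("ICER arithmetic and dominance labels", {
  # age-60 government row of the published table
  r <- icer(37837, 2.94, 58243, 3.99)
  expect_identical(r$status, "icer")
  expect_equal(round(r$icer), 19434)
  # age-20 societal row
  expect_equal(round(icer(96355, 6.43, 166600, 8.19)$icer), 39912)
  expect_identical(icer(100, 1, 90, 2)$status, "dominant")
  expect_identical(icer(100, 2, 150, 1)$status, "dominated")
  und <- icer(100, 1, 150, 1)
  expect_identical(und$status, "undefined")
  expect_true(is.na(und$icer))
  expect_equal(und$delta_cost, 50)
})

test_that("published table is internally consistent when recomputed", {
  rc <- recompute_reference()
  # ICER cells reproduce within 1 USD (printed-input rounding)
  expect_true(all(rc$icer_dev[!is.na(rc$icer_dev)] <= 1))
  expect_true(all(rc$cost_per_ly_dev <= 1))
})

test_that("deterministic engine matches perspective decomposition and trends", {
  p <- base_params()
  cal <- cal_mortality()
  tab <- deterministic_table(p, cal, ages = c(40, 60))
  # government equals societal with non-medical/indirect costs zeroed
  p0 <- set_param_values(p, setNames(rep(0, 8), grep("^cost_(dnm|ind)_",
                                                     p$params$id, value = TRUE)))
  soc0 <- run_deterministic(p0, cal, 40, "societal")
  gov <- run_deterministic(p, cal, 40, "government")
  expect_equal(soc0$outcomes$lifetime_cost, gov$outcomes$lifetime_cost,
               tolerance = 1e-9)
  # ICER decreases with start age within each perspective
  for (pp in c("government", "societal")) {
    sub <- tab[tab$perspective == pp & tab$strategy == "HD", ]
    expect_true(all(diff(sub$icer[order(sub$age)]) < 0))
  }
  # zero costs, zero discounting: ICER collapses to 0 (cost difference 0)
  pz <- p
  pz$params$mean[pz$params$kind == "cost"] <- 0
  pz$params$low[pz$params$kind == "cost"] <- 0
  cfg <- pz$config; cfg$discount_rate <- 0
  rz <- run_deterministic(pz, cal, 60, "government", config = cfg)
  expect_equal(rz$icer$delta_cost, 0, tolerance = 1e-9)
})

test_that("tornado varies one parameter at a time and sorts by span", {
  p <- base_params()
  cal <- cal_mortality()
  tor <- tornado(p, cal, start_age = 60)
  expect_true(all(diff(tor$span[tor$defined]) <= 1e-9))
  # a degenerate interval contributes zero span: force one
  p2 <- p
  i <- which(p2$params$id == "cost_acute_addon")
  p2$params$low[i] <- p2$params$mean[i]
  p2$params$high[i] <- p2$params$mean[i]
  tor2 <- tornado(p2, cal, start_age = 60)
  expect_false("cost_acute_addon" %in% tor2$id)
  # base-case ICER lies inside (or at) each entry's low/high range for the
  # dominant cost parameters (monotone response)
  base <- attr(tor, "base_icer")
  top <- tor[1:3, ]
  expect_true(all(pmin(top$icer_low, top$icer_high) <= base + 1e-6 &
                    base <= pmax(top$icer_low, top$icer_high) + 1e-6))
})

test_that("PSA is reproducible, resamples invalid draws, and means add up", {
  p <- base_params()
  cal <- cal_mortality()
  a <- run_psa(p, cal, start_age = 60, n = 30, seed = 5)
  b <- run_psa(p, cal, start_age = 60, n = 30, seed = 5)
  expect_identical(a$cost_PD, b$cost_PD)
  expect_identical(nrow(a), 30L)
  expect_equal(mean(a$delta_cost), mean(a$cost_HD) - mean(a$cost_PD),
               tolerance = 1e-12)
  g <- glance(a, boot = 100)
  expect_true(g$se_delta_cost > 0)

  # all-fixed distributions: every iteration equals the deterministic run
  pf <- fixed_params()
  psa_f <- run_psa(pf, cal, start_age = 60, n = 3, seed = 1)
  det <- run_deterministic(pf, cal, 60, "societal")
  expect_equal(psa_f$cost_PD,
               rep(det$outcomes$lifetime_cost[1], 3), tolerance = 1e-9)
  expect_equal(psa_f$qaly_HD, rep(det$outcomes$qalys[2], 3), tolerance = 1e-9)
})

test_that("CEAC probabilities partition and honour the NMB limits", {
  p <- base_params()
  cal <- cal_mortality()
  psa <- run_psa(p, cal, start_age = 60, n = 60, seed = 2)
  cv <- ceac(psa, wtp_grid = seq(0, 60000, by = 5000))
  sums <- tapply(cv$prob, cv$wtp, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
  # lambda = 0 reduces to cost minimisation
  p0 <- cv$prob[cv$wtp == 0 & cv$strategy == "PD"]
  expect_equal(p0, mean(psa$cost_PD < psa$cost_HD) +
                 0.5 * mean(psa$cost_PD == psa$cost_HD), tolerance = 1e-12)
  # very large lambda: preference driven by QALYs alone
  cv_inf <- ceac(psa, wtp_grid = 1e9)
  expect_equal(cv_inf$prob[cv_inf$strategy == "HD"],
               mean(psa$qaly_HD > psa$qaly_PD), tolerance = 1e-6)

  # all-fixed distributions: step function at the deterministic ICER
  pf <- fixed_params()
  psa_f <- run_psa(pf, cal, start_age = 60, n = 5, seed = 1)
  det_icer <- run_deterministic(pf, cal, 60, "societal")$icer$icer
  grid <- c(floor(det_icer) - 500, ceiling(det_icer) + 500)
  cvf <- ceac(psa_f, wtp_grid = grid)
  pd <- cvf[cvf$strategy == "PD", ]
  expect_equal(pd$prob, c(1, 0))
})

test_that("CEAC crossover interpolates the 0.5 crossing", {
  # constructed draws with a known indifference threshold:
  # delta_cost = 10000 exactly, delta_qaly symmetric around 1 -> the PD/HD
  # preference flips at lambda = 10000 in half the draws structure
  set.seed(10)
  n <- 2000
  dq <- runif(n, 0.5, 1.5)
  psa <- tibble::tibble(
    iteration = 1:n,
    cost_PD = 0, qaly_PD = 0,
    cost_HD = 10000, qaly_HD = dq,
    delta_cost = 10000, delta_qaly = dq)
  class(psa) <- c("psa_result", class(psa))
  cv <- ceac(psa, wtp_grid = seq(5000, 25000, by = 250))
  # P(PD preferred at lambda) = P(lambda * dq < 10000); crosses 0.5 where
  # lambda * median(dq) = 10000
  lam_star <- 10000 / median(dq)
  expect_lt(abs(crossover_wtp(cv) - lam_star), 250)
  # relabelling strategies leaves the crossover unchanged
  swapped <- psa
  swapped[, c("cost_PD", "qaly_PD", "cost_HD", "qaly_HD")] <-
    psa[, c("cost_HD", "qaly_HD", "cost_PD", "qaly_PD")]
  swapped$delta_cost <- -psa$delta_cost
  swapped$delta_qaly <- -psa$delta_qaly
  expect_lt(abs(crossover_wtp(ceac(swapped, seq(5000, 25000, 250))) - lam_star),
            250)
  # no crossing: dominant strategy
  dom <- psa; dom$cost_HD <- -1; dom$delta_cost <- -1
  expect_message(res <- crossover_wtp(ceac(dom, seq(0, 1000, 100))),
                 "do not cross")
  expect_true(is.na(res))
})
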