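#' Discount factor for an annual cycle
#'
#' @param cycle Cycle index (0-based); vectorised.
#' @param rate Annual discount rate, `>= 0`.
#' @return `1 / (1 + rate)^cycle`.
#' @examples
#' discount_factor(0:3, 0.03)
#' @export
discount_factor <- function(cycle, rate) {
  stopifnot(all(cycle >= 0))
  if (any(rate < 0)) rlang::abort("discount rate must be non-negative")
  1 / (1 + rate)^cycle
}

# Per-state engine inputs for one stratum/perspective, resolved once per run.
state_values <- function(params, strategy, perspective) {
  v <- param_values(params)
  keys <- c("PD", "PDCC", "HD", "HDCC")
  ann <- v[paste0("cost_dm_", keys)]
  if (perspective == "societal") {
    ann <- ann + v[paste0("cost_dnm_", keys)] + v[paste0("cost_ind_", keys)]
  } else if (perspective != "government") {
    rlang::abort(paste0("unknown perspective: ", perspective))
  }
  p_acute <- v[paste0("tp_acute_", keys, "_", strategy)]
  addon <- v[c("cost_acute_addon", "cost_acute_chronic_addon",
               "cost_acute_addon", "cost_acute_chronic_addon")]
  list(
    p_switch = unname(v[paste0("tp_switch_", strategy)]),
    p_pd_cc = unname(v[paste0("tp_pd_cc_", strategy)]),
    p_hd_cc = unname(v[paste0("tp_hd_cc_", strategy)]),
    annual_cost = unname(ann),
    acute_cost = unname(p_acute * addon),
    utility = unname(v[paste0("util_", keys)]),
    setup = c(PD = unname(v["cost_setup_PD"]), HD = unname(v["cost_setup_HD"]))
  )
}

split_survivors <- function(p_move) {
  # proportional renormalisation when competing probabilities exceed 1
  tot <- sum(p_move)
  if (tot > 1) {
    rlang::warn(paste0("competing transition probabilities sum to ",
                       signif(tot, 4), " > 1; renormalised"))
    p_move <- p_move / tot
  }
  p_move
}

matrix_from_probs <- function(sv, qd, qd_cc, switch_from_chronic = TRUE) {
  M <- matrix(0, 5, 5, dimnames = list(STATES, STATES))
  # death resolved first; switching/complication applied to survivors
  mv <- split_survivors(c(sw = sv$p_switch, cc = sv$p_pd_cc))
  M["PD", ] <- c((1 - qd) * (1 - sum(mv)), (1 - qd) * mv[["cc"]],
                 (1 - qd) * mv[["sw"]], 0, qd)
  sw_cc <- if (switch_from_chronic) min(sv$p_switch, 1) else 0
  M["PD_CC", ] <- c(0, (1 - qd_cc) * (1 - sw_cc), 0, (1 - qd_cc) * sw_cc, qd_cc)
  mv <- split_survivors(c(sw = sv$p_switch, cc = sv$p_hd_cc))
  M["HD", ] <- c((1 - qd) * mv[["sw"]], 0, (1 - qd) * (1 - sum(mv)),
                 (1 - qd) * mv[["cc"]], qd)
  M["HD_CC", ] <- c(0, (1 - qd_cc) * sw_cc, 0, (1 - qd_cc) * (1 - sw_cc), qd_cc)
  M["DEATH", "DEATH"] <- 1
  M
}

#' Build the annual transition matrix for one cycle
#'
#' Composition within a cycle: death is resolved first from the mortality
#' model (state- and age-dependent), then the modality-switch and
#' chronic-complication probabilities are applied to the surviving fraction,
#' with the remainder staying put. Transitions forbidden by the model
#' structure (chronic back to complication-free of the same modality) are
#' exactly zero, and the death row is absorbing.
#'
#' @param params A `dialysis_params` object.
#' @param mortality A `mortality_model` for the stratum.
#' @param strategy Initial modality stratum, `"PD"` or `"HD"`.
#' @param start_age Age at dialysis initiation (years).
#' @param cycle Cycle index, `>= 0`.
#' @param config Analysis settings; defaults to the parameter set's.
#' @param covariables Covariables passed to the mortality model; defaults to
#'   age at initiation (with its quadratic term) via the package default
#'   profile.
#' @return A 5x5 row-stochastic matrix over (PD, PD_CC, HD, HD_CC, DEATH).
#' @export
build_matrix <- function(params, mortality, strategy = c("PD", "HD"),
                         start_age, cycle, config = params$config,
                         covariables = default_covariables(start_age)) {
  strategy <- match.arg(strategy)
  stopifnot(cycle >= 0)
  sv <- state_values(params, strategy, config$perspective)
  qd <- annual_death_prob(mortality, covariables, cycle, chronic = FALSE)
  qd_cc <- annual_death_prob(mortality, covariables, cycle, chronic = TRUE)
  matrix_from_probs(sv, qd, qd_cc, isTRUE(config$switch_from_chronic))
}

new_cohort_trace <- function(occupancy, strategy, start_age, switches, config) {
  structure(list(occupancy = occupancy, strategy = strategy,
                 start_age = start_age, switches = switches, config = config),
            class = "cohort_trace")
}

#' Run the annual-cycle cohort simulation
#'
#' Propagates the full cohort through the five-state transition structure,
#' starting with all mass in the initial modality's complication-free state,
#' until either the living mass falls below the configured tolerance or the
#' cohort reaches the age cap.
#'
#' @inheritParams build_matrix
#' @param matrix_fn Optional override: a function `(cycle) -> 5x5 matrix`
#'   used instead of the parameter-driven builder (for oracles and tests).
#' @return A `cohort_trace`: occupancy matrix with one row per cycle
#'   boundary (row 1 = model entry), plus the expected modality-switch inflow
#'   mass per cycle used for set-up cost accrual. Use [tidy()] for a long
#'   tibble.
#' @export
run_cohort <- function(params, mortality, strategy = c("PD", "HD"),
                       start_age, config = params$config,
                       covariables = default_covariables(start_age),
                       matrix_fn = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(config$age_cap) && start_age >= config$age_cap) {
    rlang::abort("start_age must be below the age cap")
  }
  tol <- config$mass_tol %||% 1e-8
  max_cycles <- as.integer(ceiling((config$age_cap %||% 100) - start_age))
  if (is.null(matrix_fn)) {
    sv <- state_values(params, strategy, config$perspective)
    qs <- cycle_death_probs(mortality, covariables, max_cycles)
    sfc <- isTRUE(config$switch_from_chronic)
    matrix_fn <- function(cycle) {
      matrix_from_probs(sv, qs$free[cycle + 1], qs$chronic[cycle + 1], sfc)
    }
  }
  occ <- matrix(0, max_cycles + 1, 5, dimnames = list(NULL, STATES))
  occ[1, strategy] <- 1
  switches <- matrix(0, max_cycles, 2, dimnames = list(NULL, c("PD", "HD")))
  t_end <- max_cycles
  for (t in seq_len(max_cycles)) {
    M <- matrix_fn(t - 1)
    x <- occ[t, ]
    occ[t + 1, ] <- x %*% M
    # expected mass switching modality during cycle t-1 (arrives at t)
    switches[t, "HD"] <- x["PD"] * M["PD", "HD"] + x["PD_CC"] * M["PD_CC", "HD_CC"]
    switches[t, "PD"] <- x["HD"] * M["HD", "PD"] + x["HD_CC"] * M["HD_CC", "PD_CC"]
    if (1 - occ[t + 1, "DEATH"] < tol) { t_end <- t; break }
  }
  new_cohort_trace(occ[seq_len(t_end + 1), , drop = FALSE], strategy, start_age,
                   switches[seq_len(t_end), , drop = FALSE], config)
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1
  cat("<cohort_trace>", x$strategy, "-first, start age", x$start_age,
      "|", n, "cycles | dead mass", signif(x$occupancy[n + 1, "DEATH"], 6), "\n")
  invisible(x)
}

#' Tidy a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A tibble with columns `cycle`, `state`, `occupancy`, `strategy`,
#'   `start_age`.
#' @method tidy cohort_trace
#' @export
tidy.cohort_trace <- function(x, ...) {
  occ <- x$occupancy
  tibble::tibble(
    cycle = rep(seq_len(nrow(occ)) - 1L, times = 5L),
    state = factor(rep(STATES, each = nrow(occ)), levels = STATES),
    occupancy = as.vector(occ),
    strategy = x$strategy, start_age = x$start_age)
}

#' Accrue discounted costs, life-years and QALYs over a trace
#'
#' Per cycle `t`, each living state's start-of-cycle occupancy contributes
#' `occupancy * d(t)` person-years, `occupancy * utility * d(t)` QALYs, and
#' `occupancy * (annual state cost + p_acute * acute add-on) * d(t)` cost,
#' with `d(t) = 1/(1 + r)^t`. The government perspective counts direct
#' medical costs only; the societal perspective adds direct non-medical and
#' indirect costs. Set-up cost is charged once at entry and, when
#' `config$setup_on_switch` is `TRUE`, again for the expected mass switching
#' modality (at arrival). With `config$half_cycle = TRUE`, cycle rewards use
#' the average of start- and end-of-cycle occupancy.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param params A `dialysis_params` object.
#' @param config Analysis settings; defaults to the trace's.
#' @return A one-row tibble: `strategy`, `start_age`, `perspective`,
#'   `lifetime_cost`, `life_years`, `qalys` (discounted) and their
#'   undiscounted counterparts.
#' @export
accrue <- function(trace, params, config = trace$config) {
  stopifnot(inherits(trace, "cohort_trace"))
  persp <- config$perspective
  if (!persp %in% c("government", "societal")) {
    rlang::abort(paste0("unknown perspective: ", persp))
  }
  sv <- state_values(params, trace$strategy, persp)
  occ <- trace$occupancy
  n_cyc <- nrow(occ) - 1
  live <- occ[seq_len(n_cyc), 1:4, drop = FALSE]
  if (isTRUE(config$half_cycle)) {
    live <- (live + occ[seq_len(n_cyc) + 1, 1:4, drop = FALSE]) / 2
  }
  d <- discount_factor(seq_len(n_cyc) - 1, config$discount_rate)
  cost_rate <- as.vector(live %*% (sv$annual_cost + sv$acute_cost))
  ly_rate <- rowSums(live)
  qaly_rate <- as.vector(live %*% sv$utility)
  # set-up: once at entry, and on each expected switch at the arrival cycle
  setup0 <- sv$setup[[trace$strategy]]
  setup_d <- setup0
  setup_u <- setup0
  if (isTRUE(config$setup_on_switch) && nrow(trace$switches) > 0) {
    sw <- trace$switches
    d_arr <- discount_factor(seq_len(nrow(sw)), config$discount_rate)
    sw_cost <- sw[, "PD"] * sv$setup[["PD"]] + sw[, "HD"] * sv$setup[["HD"]]
    setup_d <- setup_d + sum(sw_cost * d_arr)
    setup_u <- setup_u + sum(sw_cost)
  }
  tibble::tibble(
    strategy = trace$strategy, start_age = trace$start_age, perspective = persp,
    lifetime_cost = sum(cost_rate * d) + setup_d,
    life_years = sum(ly_rate * d),
    qalys = sum(qaly_rate * d),
    lifetime_cost_undisc = sum(cost_rate) + setup_u,
    life_years_undisc = sum(ly_rate),
    qalys_undisc = sum(qaly_rate))
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n` individual patients through the same per-cycle transition
#' matrices as the cohort engine and accrues the same discounted rewards per
#' individual. Serves as an independent check on the cohort engine's
#' expected outcomes (means should agree within Monte-Carlo error).
#'
#' @inheritParams run_cohort
#' @param n Number of simulated patients.
#' @return A tibble with one row per outcome (`lifetime_cost`, `life_years`,
#'   `qalys`): Monte-Carlo `mean` and standard error `se`.
#' @export
microsimulate <- function(params, mortality, strategy = c("PD", "HD"),
                          start_age, n = 1e5, config = params$config,
                          covariables = default_covariables(start_age)) {
  strategy <- match.arg(strategy)
  sv <- state_values(params, strategy, config$perspective)
  max_cycles <- as.integer(ceiling((config$age_cap %||% 100) - start_age))
  qs <- cycle_death_probs(mortality, covariables, max_cycles)
  sfc <- isTRUE(config$switch_from_chronic)
  state <- rep.int(match(strategy, STATES), n)
  cost <- rep.int(sv$setup[[strategy]], n)
  ly <- numeric(n)
  qaly <- numeric(n)
  per_cost <- sv$annual_cost + sv$acute_cost
  for (t in seq_len(max_cycles) - 1) {
    alive <- state != 5L
    if (!any(alive)) break
    d <- discount_factor(t, config$discount_rate)
    idx_alive <- which(alive)
    s_al <- state[idx_alive]
    ly[idx_alive] <- ly[idx_alive] + d
    qaly[idx_alive] <- qaly[idx_alive] + d * sv$utility[s_al]
    cost[idx_alive] <- cost[idx_alive] + d * per_cost[s_al]
    M <- matrix_from_probs(sv, qs$free[t + 1], qs$chronic[t + 1], sfc)
    new_state <- state
    for (s in 1:4) {
      idx <- which(state == s)
      if (length(idx)) {
        new_state[idx] <- sample.int(5L, length(idx), replace = TRUE, prob = M[s, ])
      }
    }
    if (isTRUE(config$setup_on_switch)) {
      d1 <- discount_factor(t + 1, config$discount_rate)
      sw_pd <- state >= 3L & state <= 4L & new_state <= 2L
      sw_hd <- state <= 2L & (new_state == 3L | new_state == 4L)
      cost[sw_pd] <- cost[sw_pd] + d1 * sv$setup[["PD"]]
      cost[sw_hd] <- cost[sw_hd] + d1 * sv$setup[["HD"]]
    }
    state <- new_state
  }
  out <- list(lifetime_cost = cost, life_years = ly, qalys = qaly)
  tibble::tibble(
    outcome = names(out),
    mean = vapply(out, mean, numeric(1)),
    se = vapply(out, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)))
}
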