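#' Specification for the synthetic patient-level cohort
#'
#' Defines the statistical structure the estimation stages assume: a
#' hospital cohort with covariables, treatment assignment confounded with
#' those covariables through a logit model, Weibull survival with covariable
#' effects and administrative censoring, 30-day-cycle gamma visit costs by
#' complication group, and EQ-5D responses whose tariff-scored means equal
#' known cell utilities in expectation. Defaults follow the modelled study
#' conditions: utilities 0.731/0.599 (PD without/with chronic complications)
#' and 0.811/0.639 (HD), annual modality-switch rates 0.039 (PD-first) and
#' 0.0073 (HD-first), an HD-heavy assignment mix (about 82% HD), and a
#' follow-up window of nine years. Covariable marginals are illustrative
#' package constants (see the methods vignette).
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; all generation is reproducible from it.
#' @param assign_coefs Logit coefficients for P(assigned HD): `intercept`,
#'   `age` (per year, centred at 55), `diabetes`, `cvd`.
#' @param weibull Per-treatment Weibull survival: `shape`, `scale` (years)
#'   and AFT covariable coefficients `age` (per year, centred at 55) and
#'   `diabetes`.
#' @param censor_years Administrative censoring horizon (years).
#' @param switch_rates Annual modality-switch rate per initial modality.
#' @param chronic_rates Probability of chronic-complication status at survey
#'   per treatment.
#' @param p_acute Per-30-day-period acute complication probability.
#' @param cost_means_usd 30-day direct-medical cost means (USD) per
#'   treatment and complication group (`none`, `chronic`, `acute`,
#'   `chronic_acute`); costs are generated in THB via the fx rate.
#' @param cost_cv Coefficient of variation of the gamma visit costs.
#' @param utility_means True potential-outcome mean utilities per
#'   (treatment, chronic status).
#' @param utility_covar_effects Centred covariable effects on individual
#'   utility (`age` per year about 55, `fracture` about its 0.2 prevalence).
#' @param fx THB per USD.
#' @param visit_months 30-day billing periods generated per patient (capped
#'   by survival/censoring).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(
    n_patients = 10000,
    seed = 20220101,
    assign_coefs = c(intercept = 1.2, age = 0.05, diabetes = 0.5, cvd = 0.4),
    weibull = list(
      PD = list(shape = 1.2, scale = 6.5, age = -0.015, diabetes = -0.3),
      HD = list(shape = 1.2, scale = 8.0, age = -0.015, diabetes = -0.3)),
    censor_years = 9,
    switch_rates = c(PD = 0.039, HD = 0.0073),
    chronic_rates = c(PD = 0.35, HD = 0.30),
    p_acute = c(PD = 0.052, HD = 0.154),
    cost_means_usd = list(
      PD = c(none = 663, chronic = 768, acute = 684, chronic_acute = 809),
      HD = c(none = 757, chronic = 1010, acute = 778, chronic_acute = 1051)),
    cost_cv = 0.5,
    utility_means = list(PD = c(no_chronic = 0.731, chronic = 0.599),
                         HD = c(no_chronic = 0.811, chronic = 0.639)),
    utility_covar_effects = c(age = -0.004, fracture = -0.05),
    fx = 33.57,
    visit_months = 24) {
  spec <- as.list(environment())
  stopifnot(n_patients >= 0, censor_years > 0,
            all(unlist(switch_rates) >= 0), all(unlist(chronic_rates) >= 0),
            all(unlist(utility_means) >= 0 & unlist(utility_means) <= 1))
  class(spec) <- "generator_spec"
  spec
}

draw_covariables <- function(n) {
  age <- round(pmin(pmax(stats::rnorm(n, 55, 12), 25), 85))
  tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age,
    sex = stats::rbinom(n, 1, 0.45),
    diabetes = stats::rbinom(n, 1, 0.40),
    hypertension = stats::rbinom(n, 1, 0.70),
    dyslipidaemia = stats::rbinom(n, 1, 0.35),
    cvd = stats::rbinom(n, 1, 0.20),
    fracture = stats::rbinom(n, 1, 0.20),
    education = sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    income = sample(1:3, n, replace = TRUE, prob = c(0.4, 0.4, 0.2)),
    region = sample(1:4, n, replace = TRUE),
    reimbursement = stats::rbinom(n, 1, 0.6))
}

#' Generate the synthetic patient-level cohort
#'
#' Draws the full cohort defined by a [generator_spec()]: covariables,
#' confounded treatment assignment, Weibull event times with administrative
#' censoring, 30-day visit-level billing records (two raw billing labels per
#' period, summing to the period's gamma-distributed cost), and EQ-5D
#' ordinal profiles whose toy-tariff scores have the specified cell means in
#' expectation. Byte-identical output for identical spec and seed.
#'
#' @param spec A `generator_spec`.
#' @param tariff Tariff used to invert utility means into level
#'   probabilities.
#' @return A list of tibbles: `survival` (one row per patient),
#'   `visits` (billing records) and `eq5d` (responses with covariables).
#' @export
generate_cohort <- function(spec = generator_spec(), tariff = read_tariff()) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_patients
  empty <- list(survival = tibble::tibble(), visits = tibble::tibble(),
                eq5d = tibble::tibble())
  if (n == 0) return(empty)
  set.seed(spec$seed)
  cov <- draw_covariables(n)

  ac <- spec$assign_coefs
  lp <- ac[["intercept"]] + ac[["age"]] * (cov$age - 55) +
    ac[["diabetes"]] * cov$diabetes + ac[["cvd"]] * cov$cvd
  treatment <- ifelse(stats::runif(n) < stats::plogis(lp), "HD", "PD")

  event_time <- vapply(seq_len(n), function(i) {
    w <- spec$weibull[[treatment[i]]]
    accel <- exp(-(w$age * (cov$age[i] - 55) + w$diabetes * cov$diabetes[i]))
    stats::rweibull(1, shape = w$shape, scale = w$scale) / accel
  }, numeric(1))
  censor_time <- stats::runif(n, 1, spec$censor_years)
  time <- pmin(event_time, censor_time)
  event <- as.integer(event_time <= censor_time)
  chronic <- stats::rbinom(n, 1, unlist(spec$chronic_rates)[treatment])
  survival <- dplyr::bind_cols(
    cov, tibble::tibble(treatment = treatment, chronic = chronic,
                        time = time, event = event))

  # 30-day billing periods; one visit per period split across two raw labels
  cmap <- default_category_map()
  n_periods <- pmax(pmin(floor(time * 365.25 / 30), spec$visit_months), 1L)
  pid <- rep(seq_len(n), n_periods)
  period <- unlist(lapply(n_periods, seq_len)) - 1L
  m <- length(pid)
  acute_flag <- stats::rbinom(m, 1, unlist(spec$p_acute)[treatment[pid]]) == 1
  chronic_flag <- chronic[pid] == 1
  grp <- dplyr::case_when(acute_flag & chronic_flag ~ "chronic_acute",
                          chronic_flag ~ "chronic",
                          acute_flag ~ "acute",
                          TRUE ~ "none")
  mu_usd <- vapply(seq_len(m), function(k) {
    spec$cost_means_usd[[treatment[pid[k]]]][[grp[k]]]
  }, numeric(1))
  shape <- 1 / spec$cost_cv^2
  total_thb <- stats::rgamma(m, shape = shape, scale = mu_usd * spec$fx / shape)
  frac <- stats::runif(m, 0.3, 0.7)
  labels1 <- sample(cmap$raw_label, m, replace = TRUE)
  labels2 <- sample(cmap$raw_label, m, replace = TRUE)
  base_date <- as.Date("2019-01-01")
  visits <- tibble::tibble(
    patient_id = rep(cov$patient_id[pid], 2),
    date = rep(base_date + period * 30L, 2),
    raw_label = c(labels1, labels2),
    amount_thb = c(total_thb * frac, total_thb * (1 - frac)),
    treatment = rep(treatment[pid], 2),
    acute = rep(acute_flag, 2),
    chronic = rep(chronic_flag, 2)) |>
    dplyr::arrange(.data$patient_id, .data$date)

  eq5d <- dplyr::bind_cols(
    cov,
    tibble::tibble(treatment = treatment, chronic = chronic)) |>
    dplyr::bind_cols(draw_eq5d_profiles(
      treatment, chronic, cov, spec, tariff))

  list(survival = survival, visits = visits, eq5d = eq5d)
}

# Invert the additive tariff: choose per-dimension level probabilities so
# the expected tariff score equals each individual's target utility.
draw_eq5d_profiles <- function(treatment, chronic, cov, spec, tariff) {
  n <- length(treatment)
  eff <- spec$utility_covar_effects
  cell <- vapply(seq_len(n), function(i) {
    spec$utility_means[[treatment[i]]][[if (chronic[i] == 1) "chronic" else "no_chronic"]]
  }, numeric(1))
  target <- cell + eff[["age"]] * (cov$age - 55) +
    eff[["fracture"]] * (cov$fracture - 0.2)
  target <- pmin(pmax(target, 0.3), 1)
  delta <- (1 - target) / 5  # expected decrement per dimension
  out <- list()
  for (dim in EQ5D_DIMS) {
    sub <- tariff[tariff$dimension == dim, ]
    d2 <- sub$decrement[sub$level == 2]
    d3 <- sub$decrement[sub$level == 3]
    if (any(delta > d3 + 1e-12)) {
      rlang::abort("utility mean unreachable under tariff")
    }
    # split the target decrement across levels 2 and 3; tilt towards level 3
    # exactly as much as feasibility (p2 + p3 <= 1) requires
    w_feas <- (1 / d2 - 1 / pmax(delta, 1e-12)) / (1 / d2 - 1 / d3)
    w <- pmin(pmax(0.3, w_feas), 1)
    p3 <- w * delta / d3
    p2 <- (1 - w) * delta / d2
    u <- stats::runif(n)
    out[[dim]] <- ifelse(u < p3, 3L, ifelse(u < p3 + p2, 2L, 1L))
  }
  tibble::as_tibble(out)
}

#' Ground-truth parameter table for a generator specification
#'
#' Machine-readable table of every true value the generator used, consumed
#' by the estimator-recovery tests; includes the implied annual death
#' probabilities per treatment from the generating Weibull model (at the
#' centred covariable profile) for cross-checking [annual_death_prob()].
#'
#' @param spec A `generator_spec`.
#' @param years Cycles for which implied death probabilities are reported.
#' @return A tibble with columns `parameter`, `value`.
#' @export
truth_report <- function(spec = generator_spec(), years = 0:4) {
  rows <- list(
    tibble::tibble(parameter = "n_patients", value = spec$n_patients),
    tibble::tibble(parameter = "seed", value = spec$seed),
    tibble::tibble(parameter = paste0("assign_", names(spec$assign_coefs)),
                   value = unname(spec$assign_coefs)))
  for (tr in c("PD", "HD")) {
    w <- spec$weibull[[tr]]
    rows <- c(rows, list(
      tibble::tibble(
        parameter = paste0("weibull_", tr, "_", c("shape", "scale", "age", "diabetes")),
        value = c(w$shape, w$scale, w$age, w$diabetes)),
      tibble::tibble(parameter = paste0("switch_rate_", tr),
                     value = spec$switch_rates[[tr]]),
      tibble::tibble(parameter = paste0("chronic_rate_", tr),
                     value = spec$chronic_rates[[tr]]),
      tibble::tibble(
        parameter = paste0("utility_", tr, "_", names(spec$utility_means[[tr]])),
        value = unname(spec$utility_means[[tr]])),
      tibble::tibble(
        parameter = paste0("cost30d_usd_", tr, "_", names(spec$cost_means_usd[[tr]])),
        value = unname(spec$cost_means_usd[[tr]])),
      tibble::tibble(
        parameter = paste0("annual_death_prob_", tr, "_year", years),
        value = {
          m <- mortality_model(shape = w$shape, scale = w$scale)
          annual_death_prob(m, list(), years)
        })))
  }
  dplyr::bind_rows(rows)
}

#' Write the synthetic cohort to CSV files
#'
#' Emits the exact CSV schemas the estimation functions consume.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(survival = file.path(dir, "survival.csv"),
             visits = file.path(dir, "visits.csv"),
             eq5d = file.path(dir, "eq5d.csv"))
  for (nm in names(paths)) {
    utils::write.csv(cohort[[nm]], paths[[nm]], row.names = FALSE)
  }
  invisible(paths)
}
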