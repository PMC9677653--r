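#' Aggregate direct medical costs from visit-level billing records
#'
#' Implements the six-step aggregation used for direct medical costs:
#' (1) re-categorise the raw billing labels into eight cost groups (lab,
#' medical supply, medicine, operation, room, service, X-ray, other) and sum
#' within a visit; (2) aggregate each patient's visits into non-overlapping
#' 30-day observations anchored at the patient's first visit; (3) pool
#' patients into one cohort; (4) inflate each observation to 2021 THB using
#' the supplied inflation index; (5) classify observations into the eight
#' (treatment x complication) outcome groups -- none, chronic, acute, chronic
#' plus acute; (6) summarise per group and convert to USD.
#'
#' @param visits A data frame with columns `patient_id`, `date`
#'   (`Date` or coercible), `raw_label`, `amount_thb` (`>= 0`), `treatment`
#'   (`"PD"`/`"HD"`), `acute`, `chronic` (logical complication flags for the
#'   visit).
#' @param category_map Data frame with `raw_label`, `group` covering every
#'   raw label; defaults to the mapping shipped with the package.
#' @param inflation Data frame with `year` and `index` (price index; the
#'   inflation factor for year `y` is `index[2021] / index[y]`). Must cover
#'   every observation year and 2021.
#' @param fx THB per USD.
#' @param window `"anchor"` (30-day windows from each patient's first visit,
#'   default) or `"month"` (calendar months).
#' @return A `cost_summary` tibble: per (treatment, complication group) the
#'   observation count and mean, sd, median, IQR of 30-day cost in 2021 USD.
#'   Attributes: `observations` (the windowed observations) and
#'   `total_thb_2021` / `total_usd` for money-conservation checks.
#' @export
aggregate_direct_medical <- function(visits, category_map = default_category_map(),
                                     inflation, fx = 33.57,
                                     window = c("anchor", "month")) {
  window <- match.arg(window)
  visits <- tibble::as_tibble(visits)
  need <- c("patient_id", "date", "raw_label", "amount_thb", "treatment",
            "acute", "chronic")
  stopifnot(all(need %in% names(visits)), fx > 0)
  if (any(visits$amount_thb < 0)) rlang::abort("negative billing amount")
  unmapped <- setdiff(unique(visits$raw_label), category_map$raw_label)
  if (length(unmapped)) {
    rlang::abort(paste0("unmapped raw cost categories: ",
                        paste(unmapped, collapse = ", ")))
  }
  visits$date <- as.Date(visits$date)
  visits$group8 <- category_map$group[match(visits$raw_label, category_map$raw_label)]
  obs <- visits |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(window_id = if (window == "anchor") {
      as.integer(floor(as.numeric(.data$date - min(.data$date)) / 30))
    } else {
      as.integer(factor(format(.data$date, "%Y-%m")))
    }) |>
    dplyr::group_by(.data$patient_id, .data$window_id) |>
    dplyr::summarise(
      amount_thb = sum(.data$amount_thb),
      year = as.integer(format(min(.data$date), "%Y")),
      treatment = .data$treatment[1],
      acute = any(.data$acute), chronic = any(.data$chronic),
      .groups = "drop")
  missing_years <- setdiff(c(unique(obs$year), 2021L), inflation$year)
  if (length(missing_years)) {
    rlang::abort(paste0("inflation index missing for year(s): ",
                        paste(missing_years, collapse = ", ")))
  }
  idx <- stats::setNames(inflation$index, inflation$year)
  obs$amount_thb_2021 <- obs$amount_thb * idx[["2021"]] /
    unname(idx[as.character(obs$year)])
  obs$amount_usd <- obs$amount_thb_2021 / fx
  obs$complication <- dplyr::case_when(
    obs$acute & obs$chronic ~ "chronic_acute",
    obs$chronic ~ "chronic",
    obs$acute ~ "acute",
    TRUE ~ "none")
  summ <- obs |>
    dplyr::group_by(.data$treatment, .data$complication) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$amount_usd), sd = stats::sd(.data$amount_usd),
      median = stats::median(.data$amount_usd),
      q25 = stats::quantile(.data$amount_usd, 0.25),
      q75 = stats::quantile(.data$amount_usd, 0.75),
      .groups = "drop")
  class(summ) <- c("cost_summary", class(summ))
  attr(summ, "observations") <- obs
  attr(summ, "total_thb_2021") <- sum(obs$amount_thb_2021)
  attr(summ, "total_usd") <- sum(obs$amount_usd)
  summ
}

#' @rdname aggregate_direct_medical
#' @export
default_category_map <- function() {
  path <- system.file("extdata", "cost_categories.csv", package = "dialysisCEA",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Unit costs per visit for direct non-medical and indirect costs
#'
#' The per-visit unit cost is summarised by median and interquartile range;
#' totals multiply the median unit cost by the number of follow-up visits
#' (or hospitalisation days for admissions).
#'
#' @param cost_per_visit Numeric vector of per-visit (or per-day) costs from
#'   the survey.
#' @param n_visits Number of follow-up visits or hospital days to scale to.
#' @return A one-row tibble: `n`, `median`, `q25`, `q75`, `total`.
#' @examples
#' unit_cost_nonmedical(c(1, 2, 3, 4, 5), n_visits = 10)
#' @export
unit_cost_nonmedical <- function(cost_per_visit, n_visits = NA_real_) {
  stopifnot(length(cost_per_visit) >= 1)
  tibble::tibble(
    n = length(cost_per_visit),
    median = stats::median(cost_per_visit),
    q25 = unname(stats::quantile(cost_per_visit, 0.25)),
    q75 = unname(stats::quantile(cost_per_visit, 0.75)),
    total = stats::median(cost_per_visit) * n_visits)
}

EQ5D_DIMS <- c("mobility", "selfcare", "activities", "pain", "anxiety")

#' Read an EQ-5D tariff (value set) table
#'
#' A tariff is an additive decrement table: `utility = constant - sum of
#' per-dimension decrements`. The official national value set is not
#' redistributed; a synthetic "toy" additive tariff ships with the package
#' for tests and examples.
#'
#' @param path CSV with columns `dimension`, `level`, `decrement`; defaults
#'   to the shipped toy tariff.
#' @param constant Tariff constant (utility of the full-health profile with
#'   all level-1 decrements zero).
#' @return A `eq5d_tariff` tibble.
#' @export
read_tariff <- function(path = NULL, constant = 1) {
  path <- path %||% system.file("extdata", "toy_tariff.csv",
                                package = "dialysisCEA", mustWork = TRUE)
  t <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("dimension", "level", "decrement") %in% names(t)))
  if (!setequal(unique(t$dimension), EQ5D_DIMS)) {
    rlang::abort("tariff must define all five EQ-5D dimensions")
  }
  if (any(t$decrement[t$level == 1] != 0)) {
    rlang::abort("level-1 decrements must be zero (full health scores 1)")
  }
  attr(t, "constant") <- constant
  class(t) <- c("eq5d_tariff", class(t))
  t
}

#' Score EQ-5D responses with an additive tariff
#'
#' @param responses Data frame with one column per EQ-5D dimension
#'   (`mobility`, `selfcare`, `activities`, `pain`, `anxiety`) holding
#'   ordinal levels.
#' @param tariff A tariff from [read_tariff()].
#' @return Numeric utility per response row; the all-level-1 profile scores
#'   the tariff constant (1 by default).
#' @export
score_eq5d <- function(responses, tariff = read_tariff()) {
  stopifnot(all(EQ5D_DIMS %in% names(responses)))
  util <- rep(attr(tariff, "constant") %||% 1, nrow(responses))
  for (dim in EQ5D_DIMS) {
    sub <- tariff[tariff$dimension == dim, ]
    i <- match(responses[[dim]], sub$level)
    if (anyNA(i)) {
      rlang::abort(paste0("level outside tariff range in dimension ", dim))
    }
    util <- util - sub$decrement[i]
  }
  util
}

#' Utility estimation by inverse-probability-weighted regression adjustment
#'
#' Three-step IPWRA estimator of the potential-outcome mean utility under
#' each treatment: (i) a logit propensity model of treatment assignment on
#' the propensity covariables; (ii) a linear outcome model per treatment,
#' weighted by the inverse probability of the received treatment; (iii)
#' potential-outcome means as the average of each treatment model's
#' predictions over the full sample, overall and within complication
#' status. Propensities outside `(trunc, 1 - trunc)` are truncated with a
#' warning. Standard errors come from the weighted outcome model's
#' heteroscedasticity-robust covariance at the mean covariable profile
#' (propensity-estimation uncertainty is not propagated; see the methods
#' vignette).
#'
#' @param responses Data frame of EQ-5D responses with the five dimension
#'   columns, `treatment` (`"PD"`/`"HD"`), a `chronic` complication
#'   indicator, and the covariable columns.
#' @param tariff A tariff from [read_tariff()].
#' @param propensity_covars Covariables for the assignment model.
#' @param outcome_covars Covariables for the outcome model (the `chronic`
#'   indicator is always included).
#' @param trunc Propensity truncation bound.
#' @return An `ipwra_result` tibble: `treatment`, `group` (`overall`,
#'   `no_chronic`, `chronic`), `estimate`, `se`, plus `naive` (unadjusted
#'   group-mean utilities) for comparison. Attributes carry the propensity
#'   model, overlap diagnostics and truncation count.
#' @export
ipwra_utility <- function(responses,
                          tariff = read_tariff(),
                          propensity_covars = c("age", "education", "income",
                                                "region", "reimbursement",
                                                "fracture", "diabetes",
                                                "hypertension", "dyslipidaemia",
                                                "cvd"),
                          outcome_covars = c("age", "sex", "income", "region",
                                             "fracture"),
                          trunc = 0.01) {
  responses <- as.data.frame(responses)
  stopifnot("treatment" %in% names(responses), "chronic" %in% names(responses))
  if (length(unique(responses$treatment)) < 2) {
    rlang::abort("both treatments must be present")
  }
  propensity_covars <- intersect(propensity_covars, names(responses))
  outcome_covars <- intersect(outcome_covars, names(responses))
  responses$utility <- score_eq5d(responses, tariff)
  responses$is_hd <- as.integer(responses$treatment == "HD")

  pfit <- stats::glm(
    stats::reformulate(propensity_covars, "is_hd"),
    data = responses, family = stats::binomial())
  ps <- stats::fitted(pfit)
  if (any(ps < 1e-10 | ps > 1 - 1e-10)) {
    rlang::abort("perfect separation in the propensity model")
  }
  n_trunc <- sum(ps < trunc | ps > 1 - trunc)
  if (n_trunc > 0) {
    rlang::warn(paste0(n_trunc, " propensity value(s) truncated at [",
                       trunc, ", ", 1 - trunc, "]"))
    ps <- pmin(pmax(ps, trunc), 1 - trunc)
  }
  responses$p_received <- ifelse(responses$is_hd == 1, ps, 1 - ps)
  responses$ipw <- 1 / responses$p_received

  out_fml <- stats::reformulate(c(outcome_covars, "chronic"), "utility")
  pom <- function(treat) {
    dat <- responses[responses$treatment == treat, ]
    fit <- stats::lm(out_fml, data = dat, weights = ipw)
    X <- stats::model.matrix(out_fml, data = responses)
    pred <- as.vector(X %*% stats::coef(fit))
    V <- robust_vcov(fit)
    cell <- function(rows) {
      xbar <- colMeans(X[rows, , drop = FALSE])
      tibble::tibble(estimate = mean(pred[rows]),
                     se = sqrt(drop(t(xbar) %*% V %*% xbar)))
    }
    dplyr::bind_rows(
      dplyr::mutate(cell(seq_len(nrow(X))), group = "overall"),
      dplyr::mutate(cell(which(responses$chronic == 0)), group = "no_chronic"),
      dplyr::mutate(cell(which(responses$chronic == 1)), group = "chronic")) |>
      dplyr::mutate(treatment = treat, .before = 1)
  }
  est <- dplyr::bind_rows(pom("PD"), pom("HD"))
  naive <- responses |>
    dplyr::group_by(.data$treatment, .data$chronic) |>
    dplyr::summarise(naive_mean = mean(.data$utility), .groups = "drop")
  est <- dplyr::left_join(
    est,
    dplyr::mutate(naive,
                  group = ifelse(.data$chronic == 1, "chronic", "no_chronic")) |>
      dplyr::select("treatment", "group", naive = "naive_mean"),
    by = c("treatment", "group"))
  class(est) <- c("ipwra_result", class(est))
  attr(est, "propensity_fit") <- pfit
  attr(est, "overlap") <- range(ps)
  attr(est, "n_truncated") <- n_trunc
  attr(est, "weights") <- responses$ipw
  est
}

# HC1-robust covariance for a (weighted) lm fit.
robust_vcov <- function(fit) {
  X <- stats::model.matrix(fit)
  w <- stats::weights(fit)
  if (is.null(w)) w <- rep(1, nrow(X))
  r <- stats::residuals(fit)
  bread <- solve(crossprod(X * sqrt(w)))
  meat <- crossprod(X * (w * r))
  n <- nrow(X); k <- ncol(X)
  (n / (n - k)) * bread %*% meat %*% bread
}

#' Convert estimated utilities to a parameter-file fragment
#'
#' Maps an [ipwra_utility()] result onto the utility block of the parameter
#' schema so estimated values can feed the Markov engine directly.
#'
#' @param est An `ipwra_result`.
#' @return A named list matching the `utilities:` block of the parameter
#'   YAML (normal-approximation 95% intervals, beta PSA distribution).
#' @export
utilities_to_params <- function(est) {
  cell <- function(treat, grp) {
    r <- est[est$treatment == treat & est$group == grp, ]
    list(mean = r$estimate, low = max(r$estimate - 1.96 * r$se, 0),
         high = min(r$estimate + 1.96 * r$se, 1), dist = "beta")
  }
  list(PD = cell("PD", "no_chronic"), PD_CC = cell("PD", "chronic"),
       HD = cell("HD", "no_chronic"), HD_CC = cell("HD", "chronic"))
}
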