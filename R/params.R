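#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# State labels, in transition-matrix order. DEATH is absorbing; the chronic
# states (PD_CC, HD_CC) cannot return to the complication-free state of the
# same modality.
STATES <- c("PD", "PD_CC", "HD", "HD_CC", "DEATH")
LIVING_STATES <- STATES[1:4]
STRATA <- c("PD", "HD")

#' Convert a mean and 95% interval to beta distribution parameters
#'
#' Uses the symmetric normal approximation: the target standard deviation is
#' `(high - low) / (2 * 1.96)` and the beta shape parameters are recovered by
#' the method of moments so that the analytic mean equals `mean` exactly.
#'
#' @param mean Point estimate, in (0, 1).
#' @param low,high Lower and upper 95% interval bounds.
#' @return A list with elements `alpha` and `beta`, or a list with
#'   `fixed = TRUE` when the interval is degenerate (`low == high`).
#' @examples
#' beta_from_interval(0.039, 0.035, 0.044)
#' @export
beta_from_interval <- function(mean, low, high) {
  stopifnot(is.finite(mean), is.finite(low), is.finite(high))
  if (low > high) abort("interval bounds out of order (low > high)")
  if (low == high) return(list(fixed = TRUE, value = mean))
  if (mean <= 0 || mean >= 1) abort("beta distribution requires mean in (0, 1)")
  if (low > mean || high < mean) abort("interval must contain the mean")
  s <- (high - low) / (2 * 1.96)
  v <- s^2
  if (v >= mean * (1 - mean)) {
    abort("implied variance is infeasible for a beta distribution")
  }
  nu <- mean * (1 - mean) / v - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Convert a mean and 95% interval to gamma distribution parameters
#'
#' Same method-of-moments convention as [beta_from_interval()]: the standard
#' deviation is `(high - low) / 3.92` and `shape * scale` equals `mean`.
#'
#' @inheritParams beta_from_interval
#' @return A list with `shape` and `scale`, or a fixed point mass when the
#'   interval is degenerate.
#' @export
gamma_from_interval <- function(mean, low, high) {
  stopifnot(is.finite(mean), is.finite(low), is.finite(high))
  if (low > high) abort("interval bounds out of order (low > high)")
  if (low == high) return(list(fixed = TRUE, value = mean))
  if (mean <= 0) abort("gamma distribution requires a positive mean")
  s <- (high - low) / (2 * 1.96)
  list(shape = (mean / s)^2, scale = s^2 / mean)
}

est_row <- function(id, label, block, stratum, target, x,
                    kind = c("probability", "cost", "utility")) {
  kind <- match.arg(kind)
  if (!is.null(x$pct)) {
    low <- x$mean * (1 - x$pct)
    high <- x$mean * (1 + x$pct)
  } else {
    low <- x$low
    high <- x$high
  }
  tibble(
    id = id, label = label, block = block,
    stratum = stratum %||% NA_character_, target = target %||% NA_character_,
    kind = kind, mean = x$mean, low = low, high = high, dist = x$dist
  )
}

params_from_config <- function(cfg) {
  rows <- list()
  for (st in STRATA) {
    tr <- cfg$transitions[[paste0("start_with_", st)]]
    if (is.null(tr)) abort(paste0("missing transitions block for start_with_", st))
    who <- paste0("start with ", st)
    rows <- c(rows, list(
      est_row(paste0("tp_switch_", st), paste("Modality switch probability,", who),
              "transition", st, NA, tr$switch),
      est_row(paste0("tp_pd_cc_", st), paste("PD to PD chronic complications,", who),
              "transition", st, NA, tr$pd_to_pd_cc),
      est_row(paste0("tp_hd_cc_", st), paste("HD to HD chronic complications,", who),
              "transition", st, NA, tr$hd_to_hd_cc)
    ))
    for (s in LIVING_STATES) {
      rows <- c(rows, list(
        est_row(paste0("tp_acute_", sub("_", "", s), "_", st),
                paste0("Acute complication probability, ", s, ", ", who),
                "transition", st, s, tr$acute[[s]])
      ))
    }
  }
  for (m in c("PD", "HD")) {
    rows <- c(rows, list(
      est_row(paste0("cost_setup_", m), paste("Set-up cost,", m),
              "cost", NA, m, cfg$costs$setup[[m]], kind = "cost")
    ))
  }
  nice <- c(PD = "PD", PD_CC = "PD with chronic complications",
            HD = "HD", HD_CC = "HD with chronic complications")
  for (s in LIVING_STATES) {
    key <- sub("_", "", s)
    rows <- c(rows, list(
      est_row(paste0("cost_dm_", key), paste("Direct medical cost,", nice[[s]]),
              "cost", NA, s, cfg$costs$direct_medical[[s]], kind = "cost"),
      est_row(paste0("cost_dnm_", key), paste("Direct non-medical cost,", nice[[s]]),
              "cost", NA, s, cfg$costs$direct_nonmedical[[s]], kind = "cost"),
      est_row(paste0("cost_ind_", key), paste("Indirect cost,", nice[[s]]),
              "cost", NA, s, cfg$costs$indirect[[s]], kind = "cost"),
      est_row(paste0("util_", key), paste("Utility,", nice[[s]]),
              "utility", NA, s, cfg$utilities[[s]], kind = "utility")
    ))
  }
  rows <- c(rows, list(
    est_row("cost_acute_addon", "Acute complication cost add-on",
            "cost", NA, NA, cfg$costs$acute_addon, kind = "cost"),
    est_row("cost_acute_chronic_addon", "Acute plus chronic complication cost add-on",
            "cost", NA, NA, cfg$costs$acute_chronic_addon, kind = "cost")
  ))
  dplyr::bind_rows(rows)
}

default_config <- function() {
  list(discount_rate = 0.03, fx_rate = 33.57, wtp = 4766,
       psa_iterations = 5000, age_cap = 100, perspective = "societal",
       half_cycle = FALSE, setup_on_switch = TRUE, switch_from_chronic = TRUE,
       mass_tol = 1e-8)
}

validate_params_tbl <- function(tbl) {
  bad <- function(cond, msg, ids) {
    if (any(cond)) abort(paste0(msg, ": ", paste(ids[cond], collapse = ", ")))
  }
  bad(!tbl$dist %in% c("beta", "gamma", "exponential", "uniform", "fixed"),
      "unknown distribution family", tbl$id)
  bad(!is.finite(tbl$mean) | !is.finite(tbl$low) | !is.finite(tbl$high),
      "non-finite estimate", tbl$id)
  ok_int <- tbl$low <= tbl$mean + 1e-12 & tbl$mean <= tbl$high + 1e-12
  bad(!ok_int, "interval does not bracket the mean", tbl$id)
  p <- tbl$kind == "probability"
  bad(p & (tbl$mean < 0 | tbl$mean > 1 | tbl$low < 0 | tbl$high > 1),
      "probability outside [0, 1]", tbl$id)
  u <- tbl$kind == "utility"
  bad(u & (tbl$mean < 0 | tbl$mean > 1), "utility outside [0, 1]", tbl$id)
  bad(tbl$kind == "cost" & tbl$mean < 0, "negative cost", tbl$id)
  # chronic utility must not exceed the complication-free utility
  um <- stats::setNames(tbl$mean, tbl$id)
  if (um[["util_PDCC"]] > um[["util_PD"]] || um[["util_HDCC"]] > um[["util_HD"]]) {
    abort("chronic-state utility exceeds the complication-free utility")
  }
  invisible(tbl)
}

new_dialysis_params <- function(tbl, config) {
  validate_params_tbl(tbl)
  structure(list(params = tbl, config = config), class = "dialysis_params")
}

#' Load model parameters from a YAML file
#'
#' Reads a structured parameter file (annual transition probabilities by
#' initial-modality stratum, costs by state and perspective component, and
#' utility scores, each with a point estimate, 95% interval and PSA
#' distribution family) together with analysis settings, validating every
#' type invariant at load time.
#'
#' @param path Path to a YAML parameter file; defaults to the canonical
#'   parameter set shipped with the package.
#' @return A `dialysis_params` object: a list with a `params` tibble (one row
#'   per estimate) and a `config` list of analysis settings.
#' @examples
#' p <- load_params()
#' dplyr::filter(tidy(p), id == "tp_switch_PD")
#' @export
load_params <- function(path = default_params_path()) {
  if (!file.exists(path)) abort(paste0("parameter file not found: ", path))
  cfg <- yaml::read_yaml(path)
  config <- utils::modifyList(default_config(), cfg$settings %||% list())
  if (config$discount_rate < 0) abort("settings.discount_rate must be >= 0")
  if (!config$perspective %in% c("government", "societal")) {
    abort("settings.perspective must be 'government' or 'societal'")
  }
  tbl <- params_from_config(cfg)
  new_dialysis_params(tbl, config)
}

#' @rdname load_params
#' @export
default_params <- function() load_params()

default_params_path <- function() {
  system.file("extdata", "table1.yaml", package = "dialysisCEA", mustWork = TRUE)
}

#' Write model parameters back to YAML
#'
#' Inverse of [load_params()]; `load_params(write_params(p, f))` is lossless.
#'
#' @param x A `dialysis_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(x, path) {
  stopifnot(inherits(x, "dialysis_params"))
  tbl <- x$params
  g <- function(id) {
    r <- tbl[tbl$id == id, ]
    list(mean = r$mean, low = r$low, high = r$high, dist = r$dist)
  }
  gs <- function(id) {  # setup costs round-trip through the pct form
    r <- tbl[tbl$id == id, ]
    list(mean = r$mean, pct = (r$high - r$mean) / r$mean, dist = r$dist)
  }
  tr <- function(st) list(
    switch = g(paste0("tp_switch_", st)),
    pd_to_pd_cc = g(paste0("tp_pd_cc_", st)),
    hd_to_hd_cc = g(paste0("tp_hd_cc_", st)),
    acute = stats::setNames(
      lapply(LIVING_STATES, function(s) g(paste0("tp_acute_", sub("_", "", s), "_", st))),
      LIVING_STATES)
  )
  by_state <- function(prefix) stats::setNames(
    lapply(LIVING_STATES, function(s) g(paste0(prefix, sub("_", "", s)))),
    LIVING_STATES)
  out <- list(
    settings = x$config,
    transitions = list(start_with_PD = tr("PD"), start_with_HD = tr("HD")),
    costs = list(
      setup = list(PD = gs("cost_setup_PD"), HD = gs("cost_setup_HD")),
      direct_medical = by_state("cost_dm_"),
      acute_addon = g("cost_acute_addon"),
      acute_chronic_addon = g("cost_acute_chronic_addon"),
      direct_nonmedical = by_state("cost_dnm_"),
      indirect = by_state("cost_ind_")
    ),
    utilities = by_state("util_")
  )
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' @export
print.dialysis_params <- function(x, ...) {
  cat("<dialysis_params>", nrow(x$params), "estimates;",
      "discount", x$config$discount_rate, "| perspective", x$config$perspective, "\n")
  print(x$params, n = 8)
  invisible(x)
}

#' Tidy a parameter set
#'
#' @param x A `dialysis_params` object.
#' @param ... Unused.
#' @return The parameter tibble (one row per estimate: id, label, block,
#'   stratum, target, kind, mean, low, high, dist).
#' @method tidy dialysis_params
#' @export
tidy.dialysis_params <- function(x, ...) x$params

# Fast lookup of point estimates as a named vector.
param_values <- function(x) stats::setNames(x$params$mean, x$params$id)

#' Modify point estimates of a parameter set
#'
#' Used by the tornado analysis and in tests; returns a copy with the named
#' estimates replaced.
#'
#' @param x A `dialysis_params` object.
#' @param values Named numeric vector of replacement point estimates.
#' @export
set_param_values <- function(x, values) {
  stopifnot(inherits(x, "dialysis_params"), !is.null(names(values)))
  i <- match(names(values), x$params$id)
  if (anyNA(i)) abort(paste0("unknown parameter id: ",
                             paste(names(values)[is.na(i)], collapse = ", ")))
  x$params$mean[i] <- unname(values)
  # widen intervals so the modified object still validates (tornado bounds)
  x$params$low[i] <- pmin(x$params$low[i], x$params$mean[i])
  x$params$high[i] <- pmax(x$params$high[i], x$params$mean[i])
  x
}

draw_estimate <- function(mean, low, high, dist) {
  if (dist == "fixed" || low == high) return(mean)
  switch(dist,
    beta = {
      b <- beta_from_interval(mean, low, high)
      stats::rbeta(1, b$alpha, b$beta)
    },
    gamma = {
      g <- gamma_from_interval(mean, low, high)
      stats::rgamma(1, shape = g$shape, scale = g$scale)
    },
    # one-parameter family: parameterised by the point estimate as its mean;
    # the printed interval is recorded but cannot also be matched
    exponential = stats::rexp(1, rate = 1 / mean),
    uniform = stats::runif(1, low, high),
    abort(paste0("unknown distribution: ", dist))
  )
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Each estimate is sampled independently from its declared distribution:
#' beta and gamma via the interval method of moments
#' ([beta_from_interval()], [gamma_from_interval()]), exponential with the
#' point estimate as the distribution mean, and uniform over the stated
#' range (set-up costs). Degenerate intervals are point masses. Draws use
#' the current RNG state, so a fixed seed gives identical draws.
#'
#' @param x A `dialysis_params` object.
#' @return A `dialysis_params` object whose `mean` column holds the draw.
#' @export
sample_parameters <- function(x) {
  stopifnot(inherits(x, "dialysis_params"))
  tbl <- x$params
  draw <- purrr::pmap_dbl(
    list(tbl$mean, tbl$low, tbl$high, tbl$dist),
    draw_estimate
  )
  tbl$mean <- draw
  tbl$low <- pmin(tbl$low, draw)
  tbl$high <- pmax(tbl$high, draw)
  out <- x
  out$params <- tbl
  out
}
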