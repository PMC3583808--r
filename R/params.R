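#' Model health states
#'
#' The eight live states plus absorbing death. Q1-Q4 are one-quarter tunnel
#' states covering the first transplant year; IRON_CHELATION covers transplant
#' years 2-3; POST_HSCT all later years after a successful transplant;
#' BTICT_NO_CARDIAC / BTICT_CARDIAC are the transfusion-dependent states
#' (entered at model start in the comparator arm, or after graft failure in
#' the transplant arm).
#'
#' @format character vector of state names, DEATH last.
#' @export
health_states <- c("Q1", "Q2", "Q3", "Q4", "IRON_CHELATION", "POST_HSCT",
                   "BTICT_NO_CARDIAC", "BTICT_CARDIAC", "DEATH")

# states whose occupants are alive
.alive_states <- setdiff(health_states, "DEATH")

.cost_components <- c("direct_medical", "direct_non_medical", "indirect")

#' Base-case model parameters
#'
#' Returns the full parameter set of the cost-utility comparison as a list of
#' class \code{thal_params}. Defaults are the base-case inputs of the
#' underlying evaluation: per-state cost triples (direct medical, direct
#' non-medical, indirect; 2011 USD) with standard errors, per-state utilities
#' with standard errors, transition inputs (per-quarter graft-failure
#' probabilities 0.00003 and 0.0003 for quarters 1 and 2, annual cardiac
#' complication probability 0.0114, relative risk of death 3.9 for
#' transfusion-dependent patients), 3\% annual discounting, cost-to-charge
#' ratio 1.37, 30.50 THB per USD, and willingness-to-pay thresholds of 4,210
#' and 12,263 USD/QALY (one and three times per-capita GDP).
#'
#' The cardiac-state utility is derived, not free: the no-complication
#' utility 0.61 minus a heart-failure disutility of 0.15.
#'
#' @param ... named overrides for any top-level element.
#' @return a \code{thal_params} list. Key elements:
#' \describe{
#'   \item{start_age}{cohort entry age, 13.7 years.}
#'   \item{horizon_years}{time horizon, 99 years (capped by the life table).}
#'   \item{disc_cost, disc_qaly}{annual discount rates, both 0.03.}
#'   \item{q_fail_q1, q_fail_q2}{per-quarter graft-failure probabilities.}
#'   \item{lambda_death_cohort}{cohort transplant-related death rate per day,
#'     blended with background mortality during quarters 1-2.}
#'   \item{rr_btict_death}{relative risk of death under transfusion therapy.}
#'   \item{p_cardiac_annual}{annual probability of cardiac complication.}
#'   \item{cardiac_death_rate}{cardiac-cause death rate per year for the
#'     cardiac sub-state: a single constant or a data frame
#'     \code{(age, rate)}.}
#'   \item{costs}{data frame of per-state per-period cost means and SEs with
#'     their pricing period and source (hospital charges scale with the
#'     cost-to-charge ratio; survey and literature costs do not).}
#'   \item{utilities}{data frame of per-state utility means and SEs.}
#'   \item{ccr, ccr_base}{cost-to-charge ratio and the ratio at which the
#'     hospital cost inputs were converted (both 1.37 at base case).}
#'   \item{wtp}{willingness-to-pay thresholds, USD/QALY.}
#' }
#' @examples
#' p <- thal_params(disc_cost = 0, disc_qaly = 0)
#' p$wtp
#' @export
thal_params <- function(...) {
  costs <- data.frame(
    state = rep(c("PRE_BMT", "Q1", "Q2", "Q3", "Q4", "IRON_CHELATION",
                  "POST_HSCT", "BTICT_NO_CARDIAC", "BTICT_CARDIAC"), each = 3L),
    component = rep(.cost_components, times = 9L),
    mean = c(1330, 75, 175,          # pre-transplant work-up, once
             1226, 458, 945,         # Q1 (per quarter)
             1710, 335, 691,         # Q2
             1628, 259, 535,         # Q3
             878, 253, 522,          # Q4
             1120, 539, 1111,        # iron chelation (per year)
             1548, 299, 617,         # post-transplant (per year)
             1187, 1240, 636,        # transfusion, no cardiac (per year)
             1187, 1240, 636),       # transfusion, cardiac (per year)
    se = c(438, 21, 42,
           169, 51, 105,
           381, 41, 85,
           538, 30, 62,
           282, 32, 66,
           238, 112, 230,
           411, 146, 301,
           137, 232, 221,
           137, 232, 221),
    period = c(rep("once", 3L), rep("quarter", 12L), rep("year", 12L)),
    source = c("hospital", "survey", "survey",
               rep(c("hospital", "survey", "survey"), 4L),
               "hospital", "survey", "survey",
               "hospital", "survey", "survey",
               rep("literature", 6L)),
    stringsAsFactors = FALSE
  )

  u_no_cardiac <- 0.61
  hf_disutility <- 0.15
  utilities <- data.frame(
    state = c("Q1", "Q2", "Q3", "Q4", "IRON_CHELATION", "POST_HSCT",
              "BTICT_NO_CARDIAC", "BTICT_CARDIAC"),
    mean = c(0.59, 0.59, 0.59, 0.59, 0.88, 0.90,
             u_no_cardiac, u_no_cardiac - hf_disutility),
    se = c(0.30, 0.30, 0.30, 0.30, 0.06, 0.05, 0.03, 0.02),
    stringsAsFactors = FALSE
  )

  p <- list(
    start_age = 13.7,
    horizon_years = 99,
    disc_cost = 0.03,
    disc_qaly = 0.03,
    q_fail_q1 = 0.00003,
    q_fail_q2 = 0.0003,
    failure_source = "table",          # "table" or "fitted"
    lambda_death_cohort = 7.8e-5,      # per day; ~1 death/18 over 2y follow-up
    lambda_fail_cohort = NA_real_,     # filled when failure_source = "fitted"
    se_log_lambda_death = 1,           # asymptotic 1/sqrt(events), 1 event
    rr_btict_death = 3.9,
    p_cardiac_annual = 0.0114,
    cardiac_death_rate = 0.05,         # per year; see methods vignette
    hf_disutility = hf_disutility,
    costs = costs,
    utilities = utilities,
    ccr = 1.37,
    ccr_base = 1.37,
    thb_per_usd = 30.50,
    wtp = c(gdp1 = 4210, gdp3 = 12263)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_params(structure(p, class = "thal_params"))
}

validate_params <- function(p) {
  stopifnot(inherits(p, "thal_params"))
  probs <- c(p$q_fail_q1, p$q_fail_q2, p$p_cardiac_annual)
  if (any(probs < 0 | probs >= 1)) stop("transition probabilities must lie in [0, 1)")
  if (p$rr_btict_death <= 0) stop("relative risk must be positive")
  if (any(p$costs$mean < 0) || any(p$costs$se < 0)) stop("costs and SEs must be non-negative")
  if (any(p$utilities$mean < 0 | p$utilities$mean > 1)) stop("utilities must lie in [0, 1]")
  if (p$disc_cost < 0 || p$disc_qaly < 0) stop("discount rates must be non-negative")
  if (p$horizon_years < 1) stop("horizon must be at least one year")
  if (p$ccr <= 0 || p$ccr_base <= 0) stop("cost-to-charge ratios must be positive")
  p
}

#' @export
print.thal_params <- function(x, ...) {
  cat("Cost-utility model parameters\n")
  cat(sprintf("  start age %.1f y, horizon %d y, discounting %g%% costs / %g%% QALYs\n",
              x$start_age, x$horizon_years, 100 * x$disc_cost, 100 * x$disc_qaly))
  cat(sprintf("  graft failure q1/q2: %g / %g; RR death (BT-ICT): %g; cardiac: %g/yr\n",
              x$q_fail_q1, x$q_fail_q2, x$rr_btict_death, x$p_cardiac_annual))
  cat(sprintf("  CCR %g, %g THB/USD, WTP %s USD/QALY\n", x$ccr, x$thb_per_usd,
              paste(format(x$wtp, big.mark = ","), collapse = " / ")))
  invisible(x)
}

# cost mean lookup (state x component), with charge repricing for
# hospital-database items when ccr differs from the conversion base
state_cost <- function(params, state, component) {
  rows <- params$costs$state == state & params$costs$component == component
  if (!any(rows)) stop("no cost entry for ", state, "/", component)
  m <- params$costs$mean[rows]
  if (params$costs$source[rows] == "hospital") m <- m * params$ccr / params$ccr_base
  m
}

state_utility <- function(params, state) {
  i <- match(state, params$utilities$state)
  if (is.na(i)) stop("no utility entry for ", state)
  params$utilities$mean[i]
}

# cardiac-cause death rate per year at a given age (constant or age schedule)
cardiac_rate_at <- function(params, age) {
  s <- params$cardiac_death_rate
  if (is.data.frame(s)) {
    i <- findInterval(floor(age), s$age)
    if (i < 1L) i <- 1L
    s$rate[i]
  } else {
    s
  }
}
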