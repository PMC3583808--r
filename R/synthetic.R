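#' Generate a Gompertz-Makeham life table
#'
#' Deterministic synthetic life table with hazard
#' \eqn{\mu(x) = A + B c^x}: a constant background component (Makeham) plus
#' exponentially rising senescent mortality (Gompertz). The annual death
#' probability is the closed-form integral
#' \deqn{q_x = 1 - \exp\{-(A + B (c^{x+1} - c^x)/\log c)\},}
#' with the terminal-age entry forced to 1. Stands in for a national
#' age-specific mortality schedule when none is supplied.
#'
#' @param A Makeham background rate per year, non-negative.
#' @param B Gompertz level rate per year, positive.
#' @param c Gompertz slope (per-year multiplier), above 1.
#' @param terminal_age last tabulated age (default 100).
#' @return a \code{lifetable}.
#' @examples
#' lt <- generate_life_table()
#' life_expectancy(lt)
#' @export
generate_life_table <- function(A = 5e-4, B = 3e-5, c = 1.09,
                                terminal_age = 100) {
  stopifnot(A >= 0, B > 0, c > 1, terminal_age >= 99)
  x <- 0:(terminal_age - 1L)
  cumhaz <- A + B * (c^(x + 1) - c^x) / log(c)
  qx <- 1 - exp(-cumhaz)
  if (any(qx[x < 60] >= 1 - 1e-12)) {
    warning("implausible table: qx reaches 1 before age 60")
  }
  life_table(c(x, terminal_age), c(qx, 1))
}

#' Period life expectancy at birth from a life table
#'
#' Survivorship-product life expectancy: \eqn{l_{x+1} = l_x (1 - q_x)} with
#' \eqn{l_0 = 1}, and person-years per age approximated by the trapezoid
#' \eqn{(l_x + l_{x+1})/2}.
#'
#' @param table a \code{lifetable}.
#' @return life expectancy at birth in years.
#' @export
life_expectancy <- function(table) {
  stopifnot(inherits(table, "lifetable"))
  l <- cumprod(c(1, 1 - table$qx))
  sum((l[-length(l)] + l[-1L]) / 2)
}

#' Calibrate the Gompertz level to a target life expectancy
#'
#' Bisects on \code{B} (holding \code{A} and \code{c} fixed) until the
#' generated table's period life expectancy at birth matches \code{target_e0}
#' within \code{tol} years.
#'
#' @param target_e0 target life expectancy at birth, years.
#' @param A,c,terminal_age passed to \code{\link{generate_life_table}}.
#' @param tol convergence tolerance in years (default 0.01).
#' @return the calibrated \code{lifetable}, with the fitted \code{B} attached
#'   as attribute \code{"B"}.
#' @export
calibrate_life_table <- function(target_e0 = 74, A = 5e-4, c = 1.09,
                                 terminal_age = 100, tol = 0.01) {
  f <- function(B) life_expectancy(generate_life_table(A, B, c, terminal_age)) - target_e0
  lo <- 1e-9; hi <- 1e-2
  if (f(lo) < 0) stop("target life expectancy unattainable even at minimal B")
  if (f(hi) > 0) stop("target life expectancy unattainable even at maximal B")
  repeat {
    mid <- sqrt(lo * hi)            # bisect on the log scale: B spans decades
    d <- f(mid)
    if (abs(d) < tol) break
    if (d > 0) lo <- mid else hi <- mid
  }
  tab <- generate_life_table(A, mid, c, terminal_age)
  attr(tab, "B") <- mid
  tab
}

#' Generate a synthetic transplant cohort
#'
#' Emulates the 18-patient transplant cohort: per patient, exponential death
#' and graft-failure times are drawn, graft failure is only possible within
#' \code{cutoff_days} of transplant, administrative censoring occurs at a
#' uniformly drawn follow-up time, and the earliest of the three wins.
#' Defaults reproduce the cohort's observed frequencies: about 11\% graft
#' failure within 180 days and about 5.6\% death over a mean two-year
#' follow-up ranging one to eight years.
#'
#' @param n number of patients (default 18).
#' @param lambda_death exponential death rate per day (default 7.8e-5).
#' @param lambda_fail exponential graft-failure rate per day (default
#'   6.54e-4, giving \eqn{1 - e^{-180\lambda} \approx 0.11}).
#' @param cutoff_days graft-failure cutoff (default 180).
#' @param followup_range administrative censoring window in days (default
#'   365 to 2920, i.e. 1 to 8 years).
#' @param seed integer seed.
#' @return a \code{survival_records} data frame.
#' @export
generate_cohort <- function(n = 18, lambda_death = 7.8e-5,
                            lambda_fail = 6.54e-4, cutoff_days = 180,
                            followup_range = c(365, 2920), seed = 1) {
  stopifnot(n >= 1, lambda_death >= 0, lambda_fail >= 0,
            length(followup_range) == 2L, all(followup_range > 0),
            followup_range[2L] >= followup_range[1L])
  set.seed(seed)
  rexp_safe <- function(n, rate) if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
  t_death <- rexp_safe(n, lambda_death)
  t_fail <- rexp_safe(n, lambda_fail)
  t_fail[t_fail > cutoff_days] <- Inf
  t_cens <- stats::runif(n, followup_range[1L], followup_range[2L])
  t_obs <- pmin(t_death, t_fail, t_cens)
  event <- ifelse(t_obs == t_fail, "graft_failure",
                  ifelse(t_obs == t_death, "death", "censored"))
  survival_records(seq_len(n), t_obs, event)
}

#' Generate a synthetic cost survey
#'
#' Emulates questionnaire cost collection: per-respondent costs are drawn
#' from a gamma distribution moment-matched to the reported mean and a
#' per-respondent standard deviation of \code{se * sqrt(n_source)} (the
#' reported SE times the square root of the original sample size), so the
#' sample mean and its standard error are recoverable from the replicate.
#'
#' @param mean reported mean cost, positive.
#' @param se reported standard error of the mean.
#' @param n number of respondents to draw.
#' @param n_source sample size behind the reported SE (default 18).
#' @param seed integer seed.
#' @return numeric vector of per-respondent costs.
#' @export
generate_cost_survey <- function(mean, se, n, n_source = 18, seed = 1) {
  stopifnot(mean > 0, se >= 0, n >= 1, n_source >= 1)
  set.seed(seed)
  sd_i <- se * sqrt(n_source)
  if (sd_i == 0) return(rep(mean, n))
  stats::rgamma(n, shape = mean^2 / sd_i^2, scale = sd_i^2 / mean)
}
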