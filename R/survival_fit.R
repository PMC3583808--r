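#' Patient-level time-to-event records
#'
#' Builds the cohort record table used to fit the parametric survival model:
#' one row per patient with follow-up time in days and the terminating event,
#' one of \code{"death"}, \code{"graft_failure"} or \code{"censored"}.
#'
#' @param patient_id identifier vector.
#' @param time_days positive follow-up time in days.
#' @param event character vector over
#'   \code{c("death", "graft_failure", "censored")}.
#' @return a data frame of class \code{survival_records}.
#' @export
survival_records <- function(patient_id, time_days, event) {
  event <- match.arg(event, c("death", "graft_failure", "censored"),
                     several.ok = TRUE)
  if (any(time_days <= 0) || anyNA(time_days)) stop("time_days must be positive")
  if (length(unique(c(length(patient_id), length(time_days), length(event)))) != 1L) {
    stop("patient_id, time_days and event must have equal length")
  }
  structure(data.frame(patient_id = patient_id,
                       time_days = as.numeric(time_days),
                       event = event,
                       stringsAsFactors = FALSE),
            class = c("survival_records", "data.frame"))
}

#' Read a cohort CSV
#'
#' Expects columns \code{patient_id,time_days,event} with event labels
#' \code{death}, \code{graft_failure} or \code{censored}.
#'
#' @param path file path.
#' @return a \code{survival_records} data frame.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_days", "event")
  if (!all(need %in% names(d))) stop("cohort CSV needs columns patient_id,time_days,event")
  survival_records(d$patient_id, d$time_days, d$event)
}

#' Fit the parametric survival model H(t) = lambda * t^gamma
#'
#' Fits, by maximum likelihood, the cumulative-hazard model
#' \deqn{H(t) = \lambda t^{\gamma}}
#' to one endpoint (death or graft failure), treating the competing event as
#' censoring for that endpoint. With the shape fixed at \eqn{\gamma = 1}
#' (exponential regression, the base case) the MLE has the closed form
#' \eqn{\hat\lambda =} events / person-days at risk. With \eqn{\gamma} free
#' the Weibull-form MLE of \eqn{(\lambda, \gamma)} is obtained by Newton-type
#' optimisation of the log-likelihood on the log-parameter scale.
#'
#' @param records a \code{survival_records} data frame.
#' @param event_type endpoint to model: \code{"death"} or
#'   \code{"graft_failure"}.
#' @param shape_fixed fix \eqn{\gamma} at this value (default 1, the
#'   exponential base case); \code{NULL} frees the shape.
#' @return an object of class \code{parametric_survival}: a list with
#'   \code{lam} (per day^gamma), \code{gam}, \code{event_type},
#'   \code{n_events}, \code{person_days} and a \code{zero_events} flag.
#' @examples
#' rec <- survival_records(1:3, c(100, 200, 300),
#'                         c("death", "censored", "censored"))
#' fit_parametric(rec, "death")$lam  # 1/600
#' @export
fit_parametric <- function(records, event_type = c("death", "graft_failure"),
                           shape_fixed = 1) {
  stopifnot(inherits(records, "survival_records"), nrow(records) >= 1L)
  event_type <- match.arg(event_type)
  t <- records$time_days
  d <- as.integer(records$event == event_type)
  person_days <- sum(t)
  if (person_days <= 0) stop("zero person-time: cannot fit")
  n_events <- sum(d)

  if (n_events == 0L) {
    warning("no '", event_type, "' events: lambda set to 0, probabilities are 0")
    return(structure(list(lam = 0, gam = if (is.null(shape_fixed)) 1 else shape_fixed,
                          event_type = event_type, n_events = 0L,
                          person_days = person_days, zero_events = TRUE),
                     class = "parametric_survival"))
  }

  if (!is.null(shape_fixed)) {
    gam <- shape_fixed
    if (gam <= 0) stop("shape must be positive")
    # MLE with fixed shape: lambda = events / sum(t^gamma)
    lam <- n_events / sum(t^gam)
  } else {
    # Weibull log-likelihood: sum d*(log lam + log gam + (gam-1) log t) - lam t^gam
    nll <- function(par) {
      lam <- exp(par[1L]); gam <- exp(par[2L])
      -(sum(d * (log(lam) + log(gam) + (gam - 1) * log(t))) - lam * sum(t^gam))
    }
    start <- c(log(n_events / person_days), 0)
    opt <- stats::optim(start, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    lam <- exp(opt$par[1L]); gam <- exp(opt$par[2L])
  }
  structure(list(lam = lam, gam = gam, event_type = event_type,
                 n_events = n_events, person_days = person_days,
                 zero_events = FALSE),
            class = "parametric_survival")
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat("Parametric survival model (", x$event_type, ")\n", sep = "")
  cat(sprintf("  lambda = %.6g per day^gamma, gamma = %.4g\n", x$lam, x$gam))
  cat(sprintf("  %d events over %.0f person-days\n", x$n_events, x$person_days))
  invisible(x)
}

#' Cumulative hazard, survival and per-cycle transition probability
#'
#' \code{cumulative_hazard} evaluates \eqn{H(t) = \lambda t^\gamma};
#' \code{survival_at} evaluates \eqn{S(t) = \exp(-H(t))};
#' \code{cycle_transition_probability} converts the fitted model into the
#' probability of the event during a cycle of length \code{u} days ending at
#' day \code{t}:
#' \deqn{P = 1 - S(t) / S(t - u).}
#' For the exponential case (\eqn{\gamma = 1}) this is
#' \eqn{1 - e^{-\lambda u}}, independent of \code{t} (memorylessness).
#'
#' @param model a \code{parametric_survival} fit.
#' @param t time in days (non-negative; for the cycle probability,
#'   \code{t >= u}).
#' @param u cycle length in days, positive.
#' @return hazard (non-negative), survival probability in \code{(0, 1]}, or a
#'   transition probability in \code{[0, 1)}.
#' @export
cumulative_hazard <- function(model, t) {
  stopifnot(inherits(model, "parametric_survival"))
  if (any(t < 0)) stop("time must be non-negative")
  model$lam * t^model$gam
}

#' @rdname cumulative_hazard
#' @export
survival_at <- function(model, t) {
  exp(-cumulative_hazard(model, t))
}

#' @rdname cumulative_hazard
#' @export
cycle_transition_probability <- function(model, t, u) {
  if (any(u <= 0)) stop("cycle length must be positive")
  if (any(t < u)) stop("t must be at least the cycle length u")
  1 - survival_at(model, t) / survival_at(model, t - u)
}

#' Per-cycle graft-failure probabilities with a post-engraftment cutoff
#'
#' In the transplant cohort both graft failures occurred within the first six
#' months (days 50 and 131) and none later, so the model applies zero failure
#' probability to any cycle that starts at or after \code{cutoff_days}
#' (default 180). Earlier cycles get \code{cycle_transition_probability}
#' evaluated at the cycle end.
#'
#' @param model_fail a \code{parametric_survival} fit for graft failure.
#' @param cycle_grid data frame with columns \code{start_day,end_day} covering
#'   the first model year in 90-day cycles.
#' @param cutoff_days failure cutoff in days (default 180).
#' @return numeric vector of per-cycle failure probabilities, one per grid
#'   row, each in \code{[0, 1)} and exactly 0 from the cutoff on.
#' @export
failure_schedule <- function(model_fail, cycle_grid, cutoff_days = 180) {
  stopifnot(is.data.frame(cycle_grid),
            all(c("start_day", "end_day") %in% names(cycle_grid)))
  vapply(seq_len(nrow(cycle_grid)), function(i) {
    s <- cycle_grid$start_day[i]; e <- cycle_grid$end_day[i]
    if (s >= cutoff_days) return(0)
    cycle_transition_probability(model_fail, e, e - s)
  }, numeric(1L))
}

#' Blend cohort and background mortality on the rate scale
#'
#' The transplant cohort is too small for its death probability to stand
#' alone, so the per-cycle cohort probability is converted to a rate, the
#' age-specific background mortality rate (rescaled to the cycle span) is
#' added, and the sum is converted back to a probability.
#'
#' @param p_cohort_cycle cohort-derived death probability over the cycle.
#' @param table a \code{lifetable}.
#' @param age age in years at the cycle start.
#' @param span cycle length in years.
#' @return blended death probability over the cycle.
#' @export
blended_death_probability <- function(p_cohort_cycle, table, age, span) {
  q_annual <- annual_death_probability(table, age)
  if (q_annual >= 1) return(1)
  combine_rates_additive(p_cohort_cycle, rescale_probability(q_annual, span), span)
}
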