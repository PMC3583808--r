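#' One-way parameter specification
#'
#' Describes one uncertain input: its base value, a plausible low/high range
#' for one-way analysis, and the distribution family used in probabilistic
#' sensitivity analysis. Probabilities and utilities (bounded in \code{[0,1]})
#' take beta distributions, costs (positive, right-skewed) take gamma
#' distributions, survival-rate parameters take log-normal distributions;
#' \code{"fixed"} excludes the parameter from sampling.
#'
#' @param name parameter name (a \code{setter} function of
#'   \code{(params, value)} may be attached for engine-side application).
#' @param base base-case value.
#' @param low,high one-way range, \code{low <= base <= high}.
#' @param family one of \code{"beta"}, \code{"gamma"}, \code{"lognormal"},
#'   \code{"fixed"}.
#' @param mean,se distribution mean and standard error (default the base
#'   value and \code{NA}).
#' @param setter function applying a value to a \code{thal_params} list.
#' @return a \code{param_spec} list.
#' @export
param_spec <- function(name, base, low = base, high = base,
                       family = c("fixed", "beta", "gamma", "lognormal"),
                       mean = base, se = NA_real_, setter = NULL) {
  family <- match.arg(family)
  if (!(low <= base && base <= high)) stop("need low <= base <= high for ", name)
  if (family == "beta") {
    if (mean <= 0 || mean >= 1) stop("beta mean must lie in (0,1): ", name)
    if (!is.na(se) && se^2 >= mean * (1 - mean)) {
      stop("infeasible beta dispersion for ", name,
           ": se^2 must be below mean*(1-mean)")
    }
  }
  if (family %in% c("gamma", "lognormal") && mean <= 0) {
    stop(family, " mean must be positive: ", name)
  }
  structure(list(name = name, base = base, low = low, high = high,
                 family = family, mean = mean, se = se, setter = setter),
            class = "param_spec")
}

#' Moment-match a distribution to a mean and standard error
#'
#' Solves the family's parameters so the distribution's analytic mean and
#' standard deviation equal \code{(mean, se)}:
#' beta \eqn{\alpha = m(m(1-m)/s^2 - 1)}, \eqn{\beta = (1-m)(m(1-m)/s^2 - 1)};
#' gamma shape \eqn{m^2/s^2}, scale \eqn{s^2/m}; log-normal
#' \eqn{\sigma^2 = \log(1 + s^2/m^2)}, \eqn{\mu = \log m - \sigma^2/2}.
#'
#' @param spec a \code{param_spec} (family \code{"fixed"} is rejected).
#' @return named list of distribution parameters.
#' @export
moment_match <- function(spec) {
  stopifnot(inherits(spec, "param_spec"))
  m <- spec$mean; s <- spec$se
  if (is.na(s)) stop("no standard error available for ", spec$name)
  switch(spec$family,
    beta = {
      if (s^2 >= m * (1 - m)) {
        stop("infeasible beta dispersion for ", spec$name)
      }
      k <- m * (1 - m) / s^2 - 1
      list(alpha = m * k, beta = (1 - m) * k)
    },
    gamma = list(shape = m^2 / s^2, scale = s^2 / m),
    lognormal = {
      sig2 <- log(1 + s^2 / m^2)
      list(meanlog = log(m) - sig2 / 2, sdlog = sqrt(sig2))
    },
    stop("no distribution for family '", spec$family, "'")
  )
}

sample_spec <- function(spec, n) {
  if (spec$family == "fixed") return(rep(spec$base, n))
  mm <- moment_match(spec)
  switch(spec$family,
    beta = stats::rbeta(n, mm$alpha, mm$beta),
    gamma = stats::rgamma(n, shape = mm$shape, scale = mm$scale),
    lognormal = stats::rlnorm(n, mm$meanlog, mm$sdlog))
}

# ---- engine-side setters --------------------------------------------------

set_cost <- function(state, component) {
  force(state); force(component)
  function(params, value) {
    i <- params$costs$state == state & params$costs$component == component
    params$costs$mean[i] <- value
    params
  }
}

set_utility <- function(state) {
  force(state)
  function(params, value) {
    params$utilities$mean[params$utilities$state == state] <- value
    params
  }
}

set_scalar <- function(field) {
  force(field)
  function(params, value) { params[[field]] <- value; params }
}

set_discount <- function(params, value) {
  params$disc_cost <- value; params$disc_qaly <- value; params
}

#' Default uncertain-parameter specifications
#'
#' Builds the full list of \code{param_spec}s for the base-case model:
#' utilities and transition probabilities as beta, every cost component as
#' gamma, the cohort death rate as log-normal (log-scale SE
#' \eqn{1/\sqrt{events}}), plus the deterministic one-way-only entries
#' (discount rate 0-6\%, cost-to-charge ratio 0.8-1.5, no-cardiac utility
#' 0.3-0.9). Parameters without a reported SE get one-way ranges of
#' \eqn{\pm 1.96} SE around the mean with SE taken as half the mean, and are
#' sampled with that dispersion.
#'
#' @param params a \code{thal_params} list.
#' @return named list of \code{param_spec}s.
#' @export
default_param_specs <- function(params) {
  specs <- list()
  clamp01 <- function(x) pmin(pmax(x, 0), 1 - 1e-9)

  # utilities: beta with reported SEs; the no-cardiac transfusion utility
  # carries the wide published one-way range 0.3-0.9
  for (i in seq_len(nrow(params$utilities))) {
    s <- params$utilities$state[i]
    m <- params$utilities$mean[i]; se <- params$utilities$se[i]
    rng <- clamp01(m + c(-1, 1) * 1.96 * se)
    if (s == "BTICT_NO_CARDIAC") rng <- c(0.3, 0.9)
    specs[[paste0("utility_", tolower(s))]] <- param_spec(
      paste0("utility_", tolower(s)), base = m, low = rng[1L], high = rng[2L],
      family = "beta", mean = m, se = se, setter = set_utility(s))
  }

  # costs: gamma with reported SEs
  for (i in seq_len(nrow(params$costs))) {
    s <- params$costs$state[i]; cc <- params$costs$component[i]
    m <- params$costs$mean[i]; se <- params$costs$se[i]
    nm <- paste0("cost_", tolower(s), "_", cc)
    specs[[nm]] <- param_spec(nm, base = m,
                              low = max(0, m - 1.96 * se), high = m + 1.96 * se,
                              family = "gamma", mean = m, se = se,
                              setter = set_cost(s, cc))
  }

  # transition probabilities: beta; no SEs were reported, so dispersion is
  # taken as half the mean (documented in the methods vignette)
  for (fld in c("q_fail_q1", "q_fail_q2", "p_cardiac_annual")) {
    m <- params[[fld]]; se <- m / 2
    specs[[fld]] <- param_spec(fld, base = m,
                               low = clamp01(m - 1.96 * se),
                               high = clamp01(m + 1.96 * se),
                               family = "beta", mean = m, se = se,
                               setter = set_scalar(fld))
  }

  # cohort death rate: log-normal, asymptotic log-scale SE 1/sqrt(events)
  m <- params$lambda_death_cohort
  sdlog <- params$se_log_lambda_death
  se_nat <- m * sqrt(exp(sdlog^2) - 1)
  specs$lambda_death_cohort <- param_spec(
    "lambda_death_cohort", base = m,
    low = m * exp(-1.96 * sdlog), high = m * exp(1.96 * sdlog),
    family = "lognormal", mean = m * exp(sdlog^2 / 2), se = se_nat,
    setter = set_scalar("lambda_death_cohort"))

  # deterministic one-way-only entries
  specs$discount_rate <- param_spec("discount_rate", base = params$disc_cost,
                                    low = 0, high = 0.06, family = "fixed",
                                    setter = set_discount)
  specs$ccr <- param_spec("ccr", base = params$ccr, low = 0.8, high = 1.5,
                          family = "fixed", setter = set_scalar("ccr"))
  specs
}

apply_spec <- function(params, spec, value) {
  if (is.null(spec$setter)) stop("no setter attached to ", spec$name)
  validate_params(spec$setter(params, value))
}

#' One-way sensitivity analysis for a single parameter
#'
#' Reruns the full two-arm comparison with the parameter at its low and at
#' its high value, all else at base, and returns both cost-effectiveness
#' ratios. Unlike \code{\link{icer}}, the ratio here is signed
#' (\eqn{\Delta Cost / \Delta QALY}), so a dominant extreme (cheaper and more
#' effective) shows as a negative value and orders below any positive ICER in
#' the tornado.
#'
#' @param params base \code{thal_params}.
#' @param spec a \code{param_spec} with a setter.
#' @param table a \code{lifetable}.
#' @return list with \code{name}, \code{icer_low}, \code{icer_high},
#'   \code{range} (absolute ICER spread).
#' @export
one_way <- function(params, spec, table) {
  res <- lapply(c(spec$low, spec$high), function(v) {
    p <- tryCatch(apply_spec(params, spec, v),
                  error = function(e) stop("one-way failure for ", spec$name,
                                           " at value ", v, ": ",
                                           conditionMessage(e)))
    cua <- run_cua(p, table)$cua
    if (cua$delta_qalys == 0) NA_real_ else cua$delta_cost / cua$delta_qalys
  })
  list(name = spec$name, icer_low = res[[1L]], icer_high = res[[2L]],
       range = abs(res[[2L]] - res[[1L]]))
}

#' Tornado ordering of one-way results
#'
#' Sorts one-way entries by descending absolute ICER spread
#' (\code{|icer_high - icer_low|}); ties break alphabetically by name.
#'
#' @param entries list of \code{one_way} results.
#' @return data frame \code{parameter, icer_low, icer_high, range}, widest
#'   first.
#' @export
tornado <- function(entries) {
  stopifnot(length(entries) >= 1L)
  d <- data.frame(parameter = vapply(entries, `[[`, character(1L), "name"),
                  icer_low = vapply(entries, `[[`, numeric(1L), "icer_low"),
                  icer_high = vapply(entries, `[[`, numeric(1L), "icer_high"),
                  stringsAsFactors = FALSE)
  d$range <- abs(d$icer_high - d$icer_low)
  d[order(-d$range, d$parameter), , drop = FALSE]
}

#' Probabilistic sensitivity analysis
#'
#' Samples every uncertain parameter independently from its assigned
#' distribution, reruns both arms per draw, and records the incremental cost
#' and QALYs. Draws whose sampled values violate model constraints (e.g.
#' probabilities reaching 1) are resampled with a count kept; a resample rate
#' above 1\% aborts. Fully reproducible under a fixed seed.
#'
#' @param params base \code{thal_params}.
#' @param table a \code{lifetable}.
#' @param specs list of \code{param_spec}s (default
#'   \code{\link{default_param_specs}}).
#' @param n_draws number of Monte-Carlo draws (default 1000).
#' @param seed integer seed.
#' @return a \code{psa_result}: data frame \code{draws} with columns
#'   \code{draw, delta_cost_usd, delta_qaly}, the resample count and seed.
#' @export
run_psa <- function(params, table, specs = default_param_specs(params),
                    n_draws = 1000, seed = 1) {
  set.seed(seed)
  active <- Filter(function(s) s$family != "fixed", specs)
  dc <- numeric(n_draws); dq <- numeric(n_draws)
  resamples <- 0L
  for (i in seq_len(n_draws)) {
    repeat {
      p <- params
      ok <- tryCatch({
        for (s in active) p <- apply_spec(p, s, sample_spec(s, 1L))
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      resamples <- resamples + 1L
      if (resamples > max(10L, 0.01 * n_draws)) {
        stop("PSA resample rate exceeded 1%: check parameter specifications")
      }
    }
    r <- run_cua(p, table)$cua
    dc[i] <- r$delta_cost; dq[i] <- r$delta_qalys
  }
  if (any(!is.finite(dc)) || any(!is.finite(dq))) stop("non-finite PSA draws")
  structure(list(draws = data.frame(draw = seq_len(n_draws),
                                    delta_cost_usd = dc, delta_qaly = dq),
                 n_draws = n_draws, seed = seed, resamples = resamples),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value \eqn{\lambda}, the probability of being
#' cost-effective is the fraction of PSA draws with positive net monetary
#' benefit \eqn{\lambda \Delta QALY - \Delta Cost > 0}.
#'
#' @param psa a \code{psa_result}.
#' @param wtp_grid willingness-to-pay grid, USD/QALY.
#' @return a \code{ceac_curve} data frame:
#'   \code{wtp_usd_per_qaly, prob_cost_effective}.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$draws) > 0)
  pr <- vapply(wtp_grid, function(l)
    mean(l * psa$draws$delta_qaly - psa$draws$delta_cost_usd > 0), numeric(1L))
  structure(data.frame(wtp_usd_per_qaly = wtp_grid, prob_cost_effective = pr),
            class = c("ceac_curve", "data.frame"))
}

#' Write sensitivity outputs as CSV
#'
#' @param x a \code{psa_result}, \code{ceac_curve}, or tornado data frame.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_psa <- function(x, path) {
  stopifnot(inherits(x, "psa_result"))
  utils::write.csv(x$draws, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psa
#' @export
write_ceac <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
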