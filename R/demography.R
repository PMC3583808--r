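#' Construct a life table
#'
#' A life table is a data frame of annual probabilities of death \code{qx}
#' indexed by completed age in years. It is the demographic backbone of the
#' model: background mortality for the transplant arm and the baseline onto
#' which the transfusion arm's relative risk is applied.
#'
#' @param age integer vector of ages, contiguous from 0 to a terminal age
#'   of at least 99.
#' @param qx annual probability of death at each age, in \code{[0, 1]}; the
#'   terminal-age entry must be 1 so residual cohort mass is absorbed.
#' @return An object of class \code{lifetable} (a data frame with columns
#'   \code{age} and \code{qx}).
#' @examples
#' lt <- life_table(0:99, c(rep(0.005, 99), 1))
#' annual_death_probability(lt, 13.7)
#' @export
life_table <- function(age, qx) {
  age <- as.integer(age)
  if (length(age) != length(qx)) stop("age and qx must have equal length")
  if (age[1L] != 0L || any(diff(age) != 1L)) {
    stop("ages must be contiguous integers starting at 0")
  }
  if (max(age) < 99L) stop("terminal age must be at least 99")
  if (any(qx < 0 | qx > 1) || anyNA(qx)) stop("every qx must lie in [0, 1]")
  if (qx[length(qx)] != 1) stop("terminal-age qx must equal 1")
  structure(data.frame(age = age, qx = as.numeric(qx)),
            class = c("lifetable", "data.frame"))
}

#' Read or write a life table as CSV
#'
#' The on-disk dialect is a plain CSV with header \code{age,qx}, one row per
#' integer age from 0 to the terminal age.
#'
#' @param path file path.
#' @param table a \code{lifetable}.
#' @return \code{read_life_table} returns a \code{lifetable};
#'   \code{write_life_table} returns \code{path} invisibly.
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(d))) stop("life table CSV needs columns age,qx")
  life_table(d$age, d$qx)
}

#' @rdname read_life_table
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "lifetable"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Annual death probability at a (possibly fractional) age
#'
#' Looks up the annual \code{qx} of the row whose age equals
#' \code{floor(age)}; annual life tables carry no sub-annual structure, so no
#' interpolation is attempted. The cohort enters the model at mean age 13.7,
#' so its first cycles read \code{q13}.
#'
#' @param table a \code{lifetable}.
#' @param age age in years, within the table's range.
#' @return the annual probability of death, in \code{[0, 1]}.
#' @export
annual_death_probability <- function(table, age) {
  stopifnot(inherits(table, "lifetable"))
  a <- floor(age)
  if (any(a < table$age[1L]) || any(a > table$age[nrow(table)])) {
    stop("age outside the life-table range [", table$age[1L], ", ",
         table$age[nrow(table)], "]")
  }
  table$qx[match(a, table$age)]
}

#' Probability/rate conversions over an explicit time span
#'
#' Under a constant hazard, a probability \code{p} of an event over
#' \code{span} years corresponds to the instantaneous rate
#' \code{-log(1 - p) / span} per year, and a rate \code{r} over \code{span}
#' years back to the probability \code{1 - exp(-r * span)}. All rate algebra
#' in the model (relative risks, additive cause-specific mortality, quarterly
#' versus annual cycles) runs through these two functions so every code path
#' shares one span convention.
#'
#' @param p event probability in \code{[0, 1)}.
#' @param r non-negative instantaneous rate per year.
#' @param span time span in years, strictly positive.
#' @return \code{prob_to_rate}: a rate per year; \code{rate_to_prob}: a
#'   probability in \code{[0, 1)}.
#' @examples
#' rate_to_prob(prob_to_rate(0.05, 1), 1) # 0.05
#' @export
prob_to_rate <- function(p, span = 1) {
  if (any(span <= 0)) stop("span must be positive")
  if (any(p < 0 | p > 1) || anyNA(p)) stop("probability outside [0, 1]")
  if (any(p == 1)) stop("probability of 1 implies an infinite rate")
  -log(1 - p) / span
}

#' @rdname prob_to_rate
#' @export
rate_to_prob <- function(r, span = 1) {
  if (any(span <= 0)) stop("span must be positive")
  if (any(r < 0) || anyNA(r)) stop("rate must be non-negative")
  1 - exp(-r * span)
}

#' Apply a relative risk on the hazard scale
#'
#' Converts the background probability to a rate, multiplies the rate by
#' \code{rr}, and converts back — never multiplying probabilities directly.
#' For span-matched conversion this equals \code{1 - (1 - p)^rr}. Used for the
#' transfusion arm's mortality, where thalassemia carries a relative risk of
#' death of 3.9 over the age-matched general population.
#'
#' @param p_background background probability over \code{span}, in
#'   \code{[0, 1)}.
#' @param rr relative risk (hazard ratio), strictly positive.
#' @param span span in years over which \code{p_background} applies.
#' @return risk-adjusted probability over the same span.
#' @export
apply_relative_risk <- function(p_background, rr, span = 1) {
  if (any(rr <= 0)) stop("relative risk must be positive")
  rate_to_prob(prob_to_rate(p_background, span) * rr, span)
}

#' Combine two event probabilities by adding their rates
#'
#' Converts both probabilities (over a common span) to rates, adds the rates,
#' and converts back. This is the cause-addition used for the cardiac
#' sub-state: all-cause thalassemia mortality plus cardiac-related mortality.
#' Algebraically the result is \code{1 - (1 - p_a) * (1 - p_b)}.
#'
#' @param p_a,p_b probabilities over \code{span}, each in \code{[0, 1)}.
#' @param span common span in years.
#' @return combined probability, at least \code{max(p_a, p_b)} and below 1.
#' @export
combine_rates_additive <- function(p_a, p_b, span = 1) {
  rate_to_prob(prob_to_rate(p_a, span) + prob_to_rate(p_b, span), span)
}

#' Rescale an annual probability to a different cycle length
#'
#' Constant-hazard rescaling: the annual probability is converted to a rate
#' and re-expressed over \code{span} years. Quarterly transplant cycles use
#' \code{span = 0.25}.
#'
#' @param q_annual annual probability in \code{[0, 1)}.
#' @param span target span in years.
#' @return probability over \code{span}.
#' @export
rescale_probability <- function(q_annual, span) {
  rate_to_prob(prob_to_rate(q_annual, 1), span)
}
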