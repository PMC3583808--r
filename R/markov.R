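#' Build the cycle schedule for one treatment arm
#'
#' The transplant arm runs four quarterly tunnel cycles (Q1-Q4) in the first
#' year, two annual iron-chelation cycles (years 2-3), then annual
#' post-transplant cycles; the transfusion arm cycles annually throughout.
#' Cycles stop when the horizon is reached or the cohort age passes the life
#' table's terminal age, whichever comes first; the terminal row's
#' \code{qx = 1} absorbs any residual alive mass.
#'
#' @param params a \code{thal_params} list.
#' @param arm \code{"hsct"} or \code{"btict"}.
#' @param terminal_age terminal age of the life table in use (default 100).
#' @return data frame of class \code{cycle_schedule} with columns
#'   \code{index}, \code{start_age}, \code{length_years}, \code{phase}
#'   (state occupied during the cycle) and \code{from_state} (state occupied
#'   at the cycle start).
#' @export
build_cycle_schedule <- function(params, arm = c("hsct", "btict"),
                                 terminal_age = 100) {
  arm <- match.arg(arm)
  if (params$horizon_years < 1) stop("horizon shorter than 1 year")
  start_age <- numeric(0); len <- numeric(0); phase <- character(0)
  age <- params$start_age; elapsed <- 0; i <- 0L
  repeat {
    if (elapsed >= params$horizon_years || floor(age) > terminal_age) break
    i <- i + 1L
    l <- if (arm == "hsct" && i <= 4L) 0.25 else 1
    ph <- if (arm == "btict") "BTICT_NO_CARDIAC"
          else if (i <= 4L) paste0("Q", i)
          else if (i <= 6L) "IRON_CHELATION"
          else "POST_HSCT"
    start_age <- c(start_age, age); len <- c(len, l); phase <- c(phase, ph)
    age <- age + l; elapsed <- elapsed + l
  }
  from_state <- c(if (arm == "hsct") "Q1" else "BTICT_NO_CARDIAC",
                  phase[-length(phase)])
  structure(data.frame(index = seq_along(len), start_age = start_age,
                       length_years = len, phase = phase,
                       from_state = from_state, stringsAsFactors = FALSE),
            class = c("cycle_schedule", "data.frame"))
}

# annual probability rescaled to a span, tolerating the terminal qx = 1
scale_q <- function(q_annual, span) {
  if (q_annual >= 1) 1 else rescale_probability(q_annual, span)
}

# fill a matrix row with competing exits decomposed on the rate scale:
# each exit probability is converted to a rate over the span, total exit
# mass is 1 - exp(-sum of rates), allocated proportionally to rates, and the
# residual goes to `stay`. Certain exits (p = 1) short-circuit.
competing_row <- function(row, exits, stay, span) {
  p <- unlist(exits)
  if (any(p >= 1)) {
    row[] <- 0
    row[names(exits)[which(p >= 1)[1L]]] <- 1
    return(row)
  }
  if (sum(p) > 1) {
    stop("competing exit probabilities sum to ", signif(sum(p), 6),
         " > 1 for targets ", paste(names(exits), collapse = ", "))
  }
  r <- vapply(p, prob_to_rate, numeric(1L), span = span)
  rt <- sum(r)
  if (rt == 0) { row[stay] <- row[stay] + 1; return(row) }
  p_exit <- 1 - exp(-rt * span)
  for (k in seq_along(r)) row[names(exits)[k]] <- row[names(exits)[k]] + p_exit * r[k] / rt
  row[stay] <- row[stay] + 1 - p_exit
  row
}

#' Per-cycle transition matrix
#'
#' Assembles the time-varying transition matrix for one cycle of one arm.
#' Transplant-path states exit to death (cohort mortality blended with
#' background in quarters 1-2, background-only thereafter) and to graft
#' failure (quarters 1-2 only); survivors advance along the tunnel.
#' Transfusion states are always active (they absorb graft failures in the
#' transplant arm): no-cardiac exits to the cardiac sub-state at 0.0114/yr
#' and to death at the relative-risk-adjusted background rate; the cardiac
#' sub-state adds the cardiac-cause death rate on the rate scale. Death is
#' absorbing. Competing exits within a row are decomposed as independent
#' rates, so every row is stochastic by construction, never renormalised by
#' scaling event probabilities.
#'
#' @param params a \code{thal_params} list.
#' @param cycle one row of a \code{cycle_schedule}.
#' @param table a \code{lifetable}.
#' @param arm \code{"hsct"} or \code{"btict"}.
#' @return a 9 x 9 row-stochastic matrix over \code{\link{health_states}}.
#' @export
build_transition_matrix <- function(params, cycle, table,
                                    arm = c("hsct", "btict")) {
  arm <- match.arg(arm)
  q_bg <- annual_death_probability(table, cycle$start_age)
  .trans_matrix(params, span = cycle$length_years, age = cycle$start_age,
                q_bg = q_bg, phase = cycle$phase, from = cycle$from_state,
                arm = arm)
}

# scalar-argument matrix builder; q_bg is the pre-looked-up annual background
# probability at floor(age). Exit mass within a row is decomposed as
# independent constant rates over the cycle, so rows stay stochastic without
# scaling event probabilities.
.trans_matrix <- function(params, span, age, q_bg, phase, from, arm) {
  ns <- length(health_states)
  M <- matrix(0, ns, ns, dimnames = list(health_states, health_states))
  diag(M) <- 1
  i_nc <- 7L; i_card <- 8L; i_death <- 9L  # BTICT_NO_CARDIAC/CARDIAC/DEATH

  # competing two-exit row on the rate scale
  two_exit <- function(p1, p2, i1, i2, i_from, i_stay) {
    out <- numeric(ns)
    if (p1 >= 1) { out[i1] <- 1 }
    else if (p2 >= 1) { out[i2] <- 1 }
    else if (p1 + p2 > 1) {
      stop("competing exit probabilities sum to ", signif(p1 + p2, 6), " > 1")
    } else if (p1 == 0 && p2 == 0) { out[i_stay] <- 1 }
    else {
      r1 <- -log(1 - p1) / span; r2 <- -log(1 - p2) / span
      rt <- r1 + r2
      p_exit <- 1 - exp(-rt * span)
      out[i1] <- p_exit * r1 / rt
      out[i2] <- p_exit * r2 / rt
      out[i_stay] <- 1 - p_exit
    }
    M[i_from, ] <<- out
  }

  # transfusion-dependent rows (active in both arms)
  p_death_nc <- if (q_bg >= 1) 1 else
    1 - exp(-(-log(1 - q_bg)) * params$rr_btict_death * span)
  p_card <- if (params$p_cardiac_annual >= 1) 1 else
    1 - exp(log(1 - params$p_cardiac_annual) * span)
  two_exit(p_death_nc, p_card, i_death, i_card, i_nc, i_nc)
  p_death_card <- if (p_death_nc >= 1) 1 else
    1 - (1 - p_death_nc) * exp(-cardiac_rate_at(params, age) * span)
  M[i_card, ] <- 0
  M[i_card, i_death] <- p_death_card
  M[i_card, i_card] <- 1 - p_death_card

  if (arm == "hsct") {
    i_from <- match(from, health_states)
    i_stay <- match(phase, health_states)
    if (phase == "Q1" || phase == "Q2") {
      p_cohort <- 1 - exp(-params$lambda_death_cohort * 90) # 90-day quarter
      p_death <- if (q_bg >= 1) 1 else
        1 - (1 - p_cohort) * exp(log(1 - q_bg) * span)
      p_fail <- if (phase == "Q1") params$q_fail_q1 else params$q_fail_q2
    } else {
      p_death <- if (q_bg >= 1) 1 else 1 - exp(log(1 - q_bg) * span)
      p_fail <- 0
    }
    two_exit(p_death, p_fail, i_death, i_nc, i_from, i_stay)
  }
  M[i_death, ] <- 0
  M[i_death, i_death] <- 1
  M
}

#' Run the cohort through the model
#'
#' Propagates state occupancy through the arm's cycle schedule: the cohort
#' starts fully in Q1 (transplant arm) or in the no-cardiac transfusion state
#' (comparator arm), and each trace row is the previous row multiplied by
#' that cycle's transition matrix.
#'
#' @param arm \code{"hsct"} or \code{"btict"}.
#' @param params a \code{thal_params} list.
#' @param table a \code{lifetable}.
#' @param models optional named list of \code{parametric_survival} fits
#'   (\code{death}, \code{failure}); when supplied with
#'   \code{params$failure_source = "fitted"}, the quarterly failure
#'   probabilities and the cohort death rate are taken from the fits instead
#'   of the tabulated base-case values.
#' @return a \code{cohort_trace}: numeric matrix with one row per cycle plus
#'   an initial row, one column per \code{\link{health_states}} entry, with
#'   the schedule attached as attribute \code{"schedule"}.
#' @export
run_cohort <- function(arm = c("hsct", "btict"), params, table, models = NULL) {
  arm <- match.arg(arm)
  if (!is.null(models) && identical(params$failure_source, "fitted")) {
    if (!is.null(models$failure)) {
      grid <- data.frame(start_day = c(0, 90), end_day = c(90, 180))
      qf <- failure_schedule(models$failure, grid)
      params$q_fail_q1 <- qf[1L]; params$q_fail_q2 <- qf[2L]
    }
    if (!is.null(models$death)) {
      if (models$death$gam != 1) stop("cohort death rate requires an exponential fit")
      params$lambda_death_cohort <- models$death$lam
    }
  }
  sched <- build_cycle_schedule(params, arm,
                                terminal_age = table$age[nrow(table)])
  ns <- length(health_states)
  trace <- matrix(0, nrow = nrow(sched) + 1L, ncol = ns,
                  dimnames = list(NULL, health_states))
  trace[1L, if (arm == "hsct") "Q1" else "BTICT_NO_CARDIAC"] <- 1
  q_bg <- annual_death_probability(table, sched$start_age)
  for (i in seq_len(nrow(sched))) {
    M <- .trans_matrix(params, span = sched$length_years[i],
                       age = sched$start_age[i], q_bg = q_bg[i],
                       phase = sched$phase[i], from = sched$from_state[i],
                       arm = arm)
    trace[i + 1L, ] <- trace[i, , drop = FALSE] %*% M
  }
  structure(trace, schedule = sched, arm = arm, class = "cohort_trace")
}

#' Write a cohort trace as CSV
#'
#' Columns: \code{cycle}, \code{start_age}, \code{length_years}, one column
#' per live state, then \code{death}. The initial row carries cycle 0 with
#' zero length.
#'
#' @param trace a \code{cohort_trace}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  sched <- attr(trace, "schedule")
  d <- data.frame(cycle = c(0L, sched$index),
                  start_age = c(sched$start_age[1L], sched$start_age),
                  length_years = c(0, sched$length_years))
  m <- as.data.frame(unclass(trace)[, , drop = FALSE])
  names(m) <- tolower(names(m))
  utils::write.csv(cbind(d, m), path, row.names = FALSE)
  invisible(path)
}
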