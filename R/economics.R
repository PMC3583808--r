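#' Discount factor
#'
#' Annual compound discounting: \code{(1 + rate)^(-t)}. Quarterly cycles use
#' fractional exponents on the same formula.
#'
#' @param rate annual discount rate (base case 0.03).
#' @param t time in years.
#' @return scalar discount factor in \code{(0, 1]}.
#' @export
discount_factor <- function(rate, t) {
  stopifnot(rate >= 0, all(t >= 0))
  (1 + rate)^(-t)
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' For each cycle, every cost component and the utility-weighted cycle length
#' accrue on the end-of-cycle occupancy of each alive state and are
#' discounted to the cycle's end time (no half-cycle correction). Quarterly
#' states carry per-quarter cost amounts; annually priced states are scaled
#' by the cycle length. The transplant arm additionally charges the
#' pre-transplant work-up cost triple once, undiscounted, at time zero.
#'
#' @param trace a \code{cohort_trace} from \code{\link{run_cohort}}.
#' @param params a \code{thal_params} list.
#' @param arm \code{"hsct"} or \code{"btict"}; defaults to the trace's arm.
#' @return an \code{arm_result}: list with discounted and undiscounted
#'   component costs (\code{direct_medical}, \code{direct_non_medical},
#'   \code{indirect}), \code{total}, and \code{qalys}.
#' @export
accumulate <- function(trace, params, arm = attr(trace, "arm")) {
  stopifnot(inherits(trace, "cohort_trace"))
  sched <- attr(trace, "schedule")
  len <- sched$length_years
  t_end <- cumsum(len)
  df_c <- discount_factor(params$disc_cost, t_end)
  df_q <- discount_factor(params$disc_qaly, t_end)

  # per-state cost matrix (natural pricing period) and utility vector
  cost_mat <- vapply(.cost_components, function(cc)
    vapply(.alive_states, state_cost, numeric(1L), params = params,
           component = cc), numeric(length(.alive_states)))
  util <- vapply(.alive_states, state_utility, numeric(1L), params = params)
  quarterly <- vapply(.alive_states, function(s)
    params$costs$period[params$costs$state == s][1L] == "quarter", logical(1L))

  occ <- unclass(trace)[-1L, .alive_states, drop = FALSE]
  # cost scale: cycle length over the state's pricing period
  scale <- outer(len, ifelse(quarterly, 0.25, 1), "/")
  undisc <- (occ * scale) %*% cost_mat
  comp_u <- colSums(undisc)
  comp <- colSums(undisc * df_c)
  qaly_u <- sum((occ * len) %*% util)
  qaly <- sum(((occ * len) %*% util) * df_q)
  if (arm == "hsct") {
    for (cc in .cost_components) {
      amt <- state_cost(params, "PRE_BMT", cc)
      comp[cc] <- comp[cc] + amt
      comp_u[cc] <- comp_u[cc] + amt
    }
  }
  structure(list(arm = arm,
                 direct_medical = comp[["direct_medical"]],
                 direct_non_medical = comp[["direct_non_medical"]],
                 indirect = comp[["indirect"]],
                 total = sum(comp),
                 qalys = qaly,
                 undiscounted = list(direct_medical = comp_u[["direct_medical"]],
                                     direct_non_medical = comp_u[["direct_non_medical"]],
                                     indirect = comp_u[["indirect"]],
                                     total = sum(comp_u),
                                     qalys = qaly_u)),
            class = "arm_result")
}

#' Construct an arm result from known component totals
#'
#' Utility constructor for working with externally reported results (e.g.
#' published base-case tables): takes the three discounted cost components
#' and QALYs and fills in the total.
#'
#' @param direct_medical,direct_non_medical,indirect component costs (USD).
#' @param qalys discounted QALYs.
#' @param arm arm label.
#' @return an \code{arm_result}.
#' @export
arm_result <- function(direct_medical, direct_non_medical, indirect, qalys,
                       arm = "hsct") {
  structure(list(arm = arm, direct_medical = direct_medical,
                 direct_non_medical = direct_non_medical, indirect = indirect,
                 total = direct_medical + direct_non_medical + indirect,
                 qalys = qalys, undiscounted = NULL),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("Arm %s (discounted):\n", x$arm))
  cat(sprintf("  direct medical     %12.2f\n", x$direct_medical))
  cat(sprintf("  direct non-medical %12.2f\n", x$direct_non_medical))
  cat(sprintf("  indirect           %12.2f\n", x$indirect))
  cat(sprintf("  total              %12.2f\n", x$total))
  cat(sprintf("  QALYs              %12.2f\n", x$qalys))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' Computes incremental costs (per component and total), incremental QALYs
#' and their ratio for the transplant arm against the transfusion arm:
#' \deqn{ICER = (Cost_{RI-HSCT} - Cost_{BT-ICT}) /
#'   (QALY_{RI-HSCT} - QALY_{BT-ICT}).}
#' Dominance (cheaper and more effective) is flagged rather than reported as
#' a negative ratio, and a zero QALY difference leaves the ratio undefined.
#'
#' @param hsct,btict \code{arm_result}s computed under the same parameters
#'   and life table.
#' @return a \code{cua_result}: incremental components, \code{delta_cost},
#'   \code{delta_qalys}, \code{icer}, and a \code{dominant} flag.
#' @export
icer <- function(hsct, btict) {
  stopifnot(inherits(hsct, "arm_result"), inherits(btict, "arm_result"))
  dc <- hsct$total - btict$total
  dq <- hsct$qalys - btict$qalys
  dominant <- dc < 0 && dq > 0
  ratio <- if (dq == 0) NA_real_ else if (dominant) NA_real_ else dc / dq
  structure(list(delta_direct_medical = hsct$direct_medical - btict$direct_medical,
                 delta_direct_non_medical = hsct$direct_non_medical - btict$direct_non_medical,
                 delta_indirect = hsct$indirect - btict$indirect,
                 delta_cost = dc, delta_qalys = dq,
                 icer = ratio, dominant = dominant),
            class = "cua_result")
}

#' @export
print.cua_result <- function(x, ...) {
  cat(sprintf("Incremental cost  %12.2f USD\n", x$delta_cost))
  cat(sprintf("Incremental QALYs %12.2f\n", x$delta_qalys))
  if (x$dominant) cat("Dominant: cheaper and more effective\n")
  else if (is.na(x$icer)) cat("ICER undefined (zero QALY difference)\n")
  else cat(sprintf("ICER              %12.2f USD/QALY\n", x$icer))
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' \code{NMB = WTP * dQALYs - dCost}; positive exactly when the ICER falls
#' below the willingness-to-pay threshold (for a positive QALY gain).
#'
#' @param cua a \code{cua_result}.
#' @param wtp willingness to pay, USD per QALY (vectorised).
#' @return net monetary benefit in USD, one value per threshold.
#' @export
nmb <- function(cua, wtp) {
  stopifnot(inherits(cua, "cua_result"), all(wtp >= 0))
  wtp * cua$delta_qalys - cua$delta_cost
}

#' Charge and currency conversions
#'
#' \code{charge_to_cost} converts hospital charges to economic costs by a
#' cost-to-charge ratio (base case 1.37); \code{thb_to_usd} converts Thai
#' baht to 2011 US dollars at 30.50 THB per USD.
#'
#' @param charge hospital charge (non-negative).
#' @param ccr cost-to-charge ratio, positive.
#' @param amount_thb amount in Thai baht.
#' @param thb_per_usd exchange rate (default 30.50).
#' @return converted amount.
#' @export
charge_to_cost <- function(charge, ccr = 1.37) {
  stopifnot(all(charge >= 0), ccr > 0)
  charge * ccr
}

#' @rdname charge_to_cost
#' @export
thb_to_usd <- function(amount_thb, thb_per_usd = 30.50) {
  stopifnot(all(amount_thb >= 0))
  amount_thb / thb_per_usd
}

#' Run the full two-arm comparison
#'
#' Convenience wrapper: runs both arms through the Markov engine under one
#' parameter set and life table, accumulates costs and QALYs, and returns
#' the incremental comparison.
#'
#' @param params a \code{thal_params} list.
#' @param table a \code{lifetable}.
#' @param models optional survival fits, see \code{\link{run_cohort}}.
#' @return list with \code{hsct}, \code{btict} (\code{arm_result}s) and
#'   \code{cua} (\code{cua_result}).
#' @export
run_cua <- function(params, table, models = NULL) {
  tr_h <- run_cohort("hsct", params, table, models)
  tr_b <- run_cohort("btict", params, table, models)
  h <- accumulate(tr_h, params)
  b <- accumulate(tr_b, params)
  list(hsct = h, btict = b, cua = icer(h, b))
}

#' Write base-case results as CSV
#'
#' Mirrors the conventional results layout: one row per cost component plus
#' total and QALYs, columns for each arm and the increment.
#'
#' @param res result list from \code{\link{run_cua}}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_cua <- function(res, path) {
  h <- res$hsct; b <- res$btict; d <- res$cua
  out <- data.frame(
    outcome = c("direct_medical", "direct_non_medical", "indirect", "total",
                "qalys", "icer"),
    hsct = c(h$direct_medical, h$direct_non_medical, h$indirect, h$total,
             h$qalys, NA),
    btict = c(b$direct_medical, b$direct_non_medical, b$indirect, b$total,
              b$qalys, NA),
    incremental = c(d$delta_direct_medical, d$delta_direct_non_medical,
                    d$delta_indirect, d$delta_cost, d$delta_qalys, d$icer))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
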