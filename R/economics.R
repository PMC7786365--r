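#' Run one treatment arm through the Markov model
#'
#' Builds the transition schedule from the arm's DFS and OS laws, runs
#' the cohort trace, lays out the per-cycle cost vectors, and accrues
#' discounted costs, life-years and QALYs, decomposed by health state.
#'
#' @param spec An [npc_model_spec()].
#' @param arm `"GP"` or `"TPF"`.
#' @param wastage Drug pricing policy, `"vial_based"` or `"exact_dose"`.
#' @param keep_trace Attach the cohort trace to the result.
#' @return A list of class `arm_result` with `total_cost`, `total_ly`,
#'   `total_qaly` and a `by_state` data frame (rows `dfs`, `pd`).
#' @export
run_arm <- function(spec, arm, wastage = c("vial_based", "exact_dose"),
                    keep_trace = FALSE) {
  wastage <- match.arg(wastage)
  config <- spec$config
  if (!identical(config$annual_discount, spec$shared$discount$mean))
    config$annual_discount <- spec$shared$discount$mean
  K <- n_cycles(config)
  schedule <- build_transition_schedule(arm_survival(spec, arm, "dfs"),
                                        arm_survival(spec, arm, "os"), config)
  trace <- run_cohort(schedule, config)
  costs <- build_cycle_costs(spec, arm, wastage)
  cyc_years <- config$cycle_length_days / 365.25
  ly_rewards <- list(dfs = rep(cyc_years, K), pd = rep(cyc_years, K))
  u <- spec$shared$utilities
  qaly_rewards <- list(dfs = rep(u$dfs$mean * cyc_years, K),
                       pd = rep(u$pd$mean * cyc_years, K))
  cost <- discounted_accrual(trace, costs, config)
  ly <- discounted_accrual(trace, ly_rewards, config)
  qaly <- discounted_accrual(trace, qaly_rewards, config)
  out <- list(arm = arm,
              total_cost = cost$total, total_ly = ly$total, total_qaly = qaly$total,
              by_state = data.frame(state = c("dfs", "pd"),
                                    cost = c(cost$dfs, cost$pd),
                                    ly = c(ly$dfs, ly$pd),
                                    qaly = c(qaly$dfs, qaly$pd)))
  if (keep_trace) out$trace <- trace
  class(out) <- "arm_result"
  out
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s: cost $%.2f, %.3f LY, %.3f QALY\n",
              x$arm, x$total_cost, x$total_ly, x$total_qaly))
  invisible(x)
}

#' Incremental cost-effectiveness comparison of two arms
#'
#' Computes the incremental cost and effect of the intervention over the
#' comparator and classifies the result: an ICER in the trade-off
#' quadrants, `"dominant"` when the intervention is at least as cheap and
#' more effective (or cheaper and at least as effective), `"dominated"`
#' in the mirror case, and `"equivalent"` at an exact tie.  Ties on one
#' axis are resolved in favour of the cheaper / more effective arm and
#' flagged `weak = TRUE`; no division by a zero effect ever occurs.
#'
#' @param intervention,comparator `arm_result` objects (or lists with
#'   `total_cost` and the chosen effect).
#' @param effect `"qaly"` or `"ly"`.
#' @param wtp Willingness-to-pay per effect unit, carried into the result.
#' @return A list of class `ce_comparison` with `delta_cost`,
#'   `delta_effect`, `verdict`, `icer`, `weak`, `wtp`.
#' @export
compare_arms <- function(intervention, comparator, effect = c("qaly", "ly"),
                         wtp = 31008.16) {
  effect <- match.arg(effect)
  eff_of <- function(x) if (effect == "qaly") x$total_qaly else x$total_ly
  dc <- intervention$total_cost - comparator$total_cost
  de <- eff_of(intervention) - eff_of(comparator)
  weak <- FALSE
  if (dc == 0 && de == 0) {
    verdict <- "equivalent"; icer <- NA_real_
  } else if (de > 0 && dc <= 0) {
    verdict <- "dominant"; icer <- NA_real_
  } else if (de >= 0 && dc < 0) {
    verdict <- "dominant"; icer <- NA_real_; weak <- de == 0
  } else if (de < 0 && dc >= 0) {
    verdict <- "dominated"; icer <- NA_real_
  } else if (de <= 0 && dc > 0) {
    verdict <- "dominated"; icer <- NA_real_; weak <- de == 0
  } else {
    verdict <- "icer"; icer <- dc / de
  }
  structure(list(delta_cost = dc, delta_effect = de, effect_unit = effect,
                 verdict = verdict, icer = icer, weak = weak, wtp = wtp),
            class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("<ce_comparison> dCost $%.2f, dEffect %.4f %s -> %s",
              x$delta_cost, x$delta_effect, toupper(x$effect_unit), x$verdict))
  if (x$verdict == "icer") cat(sprintf(" ($%.2f per %s)", x$icer, toupper(x$effect_unit)))
  if (x$weak) cat(" [weak]")
  cat("\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `wtp * QALYs - cost`, the linearised decision rule: the incremental
#' NMB is positive exactly when the ICER lies below the willingness to
#' pay (in the trade-off quadrant).
#'
#' @param result An `arm_result` (or list with `total_cost`, `total_qaly`).
#' @param wtp Non-negative willingness-to-pay per QALY.
#' @return Money.
#' @export
net_monetary_benefit <- function(result, wtp) {
  if (wtp < 0) stop("`wtp` must be non-negative")
  wtp * result$total_qaly - result$total_cost
}

#' Full base-case evaluation of a two-arm specification
#'
#' @param spec An [npc_model_spec()].
#' @param wastage Drug pricing policy.
#' @param wtp Willingness-to-pay for the comparison verdict.
#' @return A list with `arm_results` (named list of `arm_result`),
#'   `comparison` (per QALY) and `comparison_ly` (per LY); the first
#'   named arm is treated as the intervention.
#' @export
evaluate_model <- function(spec, wastage = c("vial_based", "exact_dose"),
                           wtp = NULL) {
  wastage <- match.arg(wastage)
  if (is.null(wtp)) wtp <- unname(spec$wtp[length(spec$wtp)])
  arms <- names(spec$arms)
  res <- lapply(arms, function(a) run_arm(spec, a, wastage))
  names(res) <- arms
  list(arm_results = res,
       comparison = compare_arms(res[[1]], res[[2]], "qaly", wtp),
       comparison_ly = compare_arms(res[[1]], res[[2]], "ly", wtp))
}

#' Results table in the total / DFS-state / PD-state layout
#'
#' @param eval_result Result of [evaluate_model()].
#' @return A data frame with one row per (scope, arm): total and
#'   per-state discounted cost, LY and QALY, incremental values and
#'   ICERs per LY and per QALY for the first arm over the second.
#' @export
results_table <- function(eval_result) {
  res <- eval_result$arm_results
  a1 <- res[[1]]; a2 <- res[[2]]
  scope_row <- function(scope, x) {
    if (scope == "total")
      data.frame(scope = scope, arm = x$arm, cost = x$total_cost,
                 ly = x$total_ly, qaly = x$total_qaly)
    else {
      s <- x$by_state[x$by_state$state == scope, ]
      data.frame(scope = scope, arm = x$arm, cost = s$cost, ly = s$ly, qaly = s$qaly)
    }
  }
  out <- do.call(rbind, lapply(c("total", "dfs", "pd"), function(sc)
    rbind(scope_row(sc, a1), scope_row(sc, a2))))
  inc <- function(col) {
    v <- rep(NA_real_, nrow(out))
    for (sc in unique(out$scope)) {
      i <- which(out$scope == sc)
      v[i[1]] <- out[[col]][i[1]] - out[[col]][i[2]]
    }
    v
  }
  out$inc_cost <- inc("cost"); out$inc_ly <- inc("ly"); out$inc_qaly <- inc("qaly")
  out$icer_per_ly <- ifelse(!is.na(out$inc_ly) & out$inc_ly != 0,
                            out$inc_cost / out$inc_ly, NA_real_)
  out$icer_per_qaly <- ifelse(!is.na(out$inc_qaly) & out$inc_qaly != 0,
                              out$inc_cost / out$inc_qaly, NA_real_)
  out
}
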