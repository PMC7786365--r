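#' Simulate censored time-to-event data from a parametric law
#'
#' Event times are drawn by inverse-transform sampling,
#' `t = (-log U / lambda)^(1/gamma)`; censoring is then applied: none,
#' uniform on `(0, cens_time)`, or administrative at `cens_time`.
#'
#' @param model A [parametric_survival()] generating law.
#' @param n Number of subjects.
#' @param censoring `"none"`, `"uniform"` or `"administrative"`.
#' @param cens_time Censoring horizon (model time units); required unless
#'   `censoring == "none"`.
#' @param seed Integer RNG seed.
#' @return A [pseudo_ipd()].
#' @export
simulate_ipd <- function(model, n, censoring = c("none", "uniform", "administrative"),
                         cens_time = NULL, seed = 1) {
  censoring <- match.arg(censoring)
  stopifnot(inherits(model, "parametric_survival"), n >= 1)
  if (censoring != "none" && is.null(cens_time))
    stop("`cens_time` is required for censored designs")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  u <- stats::runif(n)
  t_event <- (-log(u) / model$scale)^(1 / model$shape)
  if (censoring == "none") {
    return(pseudo_ipd(t_event, rep(1L, n)))
  }
  t_cens <- if (censoring == "uniform") stats::runif(n, 0, cens_time)
            else rep(cens_time, n)
  event <- as.integer(t_event <= t_cens)
  pseudo_ipd(pmin(t_event, t_cens), event)
}

#' Kaplan-Meier estimate as a digitized curve
#'
#' Product-limit estimate of the survivor function with numbers at risk
#' reported at requested times, in the same container a digitizer would
#' produce — the input of [reconstruct_pseudo_ipd()], enabling full
#' round-trip tests of the reconstruction workflow.
#'
#' @param ipd A [pseudo_ipd()].
#' @param at_risk_times Times at which to report numbers at risk
#'   (defaults to 8 equally spaced times over the observed range,
#'   starting at 0).
#' @param label Curve label.
#' @return A [digitized_curve()] with an `at_risk` table.
#' @export
km_estimate <- function(ipd, at_risk_times = NULL, label = "") {
  stopifnot(inherits(ipd, "pseudo_ipd"))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  if (is.null(at_risk_times))
    at_risk_times <- seq(0, max(ipd$time), length.out = 8)
  at_risk_times <- sort(unique(at_risk_times))
  sm <- summary(fit, times = at_risk_times, extend = TRUE)
  at_risk <- data.frame(time = sm$time, n_at_risk = sm$n.risk)
  keep <- fit$n.event > 0
  if (!any(keep)) {
    return(digitized_curve(max(ipd$time), 1, at_risk = at_risk, label = label))
  }
  digitized_curve(fit$time[keep], fit$surv[keep], at_risk = at_risk, label = label)
}
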