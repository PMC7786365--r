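#' Digitized survival curve
#'
#' Container for points read off a published Kaplan-Meier curve, with an
#' optional numbers-at-risk table.  Times must be strictly increasing and
#' the survival ordinates non-increasing.
#'
#' @param time Non-negative, strictly increasing times.
#' @param survival Survival probabilities in `[0, 1]`, non-increasing.
#' @param at_risk Optional data frame with columns `time` and `n_at_risk`.
#' @param label Optional curve label.
#' @return An object of class `digitized_curve`.
#' @export
digitized_curve <- function(time, survival, at_risk = NULL, label = "") {
  stopifnot(is.numeric(time), is.numeric(survival),
            length(time) == length(survival))
  if (any(time < 0)) stop("times must be non-negative")
  if (is.unsorted(time, strictly = TRUE)) stop("times must be strictly increasing")
  if (any(survival < 0 | survival > 1)) stop("survival must lie in [0, 1]")
  if (any(diff(survival) > 1e-12)) stop("survival must be non-increasing")
  if (!is.null(at_risk)) {
    stopifnot(is.data.frame(at_risk), all(c("time", "n_at_risk") %in% names(at_risk)))
    if (any(at_risk$n_at_risk < 0)) stop("at-risk counts must be non-negative")
  }
  structure(list(label = label,
                 points = data.frame(time = time, survival = survival),
                 at_risk = at_risk),
            class = "digitized_curve")
}

#' Pseudo individual-patient data
#'
#' @param time Non-negative event or censoring times.
#' @param event 1 for an event, 0 for censoring.
#' @return An object of class `pseudo_ipd` (a data frame).
#' @export
pseudo_ipd <- function(time, event) {
  stopifnot(is.numeric(time), length(time) == length(event))
  if (length(time) == 0L) stop("at least one record is required")
  if (any(time < 0)) stop("times must be non-negative")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)")
  structure(data.frame(time = as.numeric(time), event = as.integer(event)),
            class = c("pseudo_ipd", "data.frame"))
}

# survival value of a step curve at arbitrary times (right-continuous step)
.curve_survival_at <- function(curve, t) {
  pts <- curve$points
  f <- stats::stepfun(pts$time, c(1, pts$survival), right = FALSE)
  f(t)
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Within each interval between consecutive at-risk report times, the
#' number of events is solved from the survival ratio and the change in
#' numbers at risk under the usual assumption that censoring is spread
#' evenly through the interval: with `n`, `n'` at risk at the interval
#' ends and survival ratio `R = S'/S`, the implied events are
#' `d = (n + n') (1 - R) / (1 + R)` and censorings `c = n - n' - d`.
#' Fractional solutions are rounded by largest remainder so that
#' `d + c = n - n'` exactly.  Event times are spread evenly inside the
#' interval, interleaved with censoring times.  Patients still at risk at
#' the final boundary are censored there.
#'
#' @param curve A [digitized_curve()] with an `at_risk` table.
#' @param interval_boundaries Increasing times at which at-risk counts and
#'   survival are available; defaults to the curve's at-risk times.
#' @return A [pseudo_ipd()].
#' @export
reconstruct_pseudo_ipd <- function(curve, interval_boundaries = NULL) {
  stopifnot(inherits(curve, "digitized_curve"))
  if (is.null(curve$at_risk)) stop("curve has no at-risk table; reconstruction needs one")
  if (is.null(interval_boundaries)) interval_boundaries <- curve$at_risk$time
  b <- sort(unique(as.numeric(interval_boundaries)))
  if (length(b) < 2L) stop("need at least two interval boundaries")
  idx <- match(b, curve$at_risk$time)
  if (anyNA(idx)) stop("at-risk counts missing at boundaries: ",
                       paste(b[is.na(idx)], collapse = ", "))
  n <- curve$at_risk$n_at_risk[idx]
  S <- .curve_survival_at(curve, b)
  if (any(S <= 0)) stop("survival must be positive at every boundary")

  times <- numeric(0); events <- integer(0)
  for (j in seq_len(length(b) - 1L)) {
    n0 <- n[j]; n1 <- n[j + 1L]
    lost <- n0 - n1
    if (lost < 0) stop(sprintf("interval [%g, %g): at-risk count increases", b[j], b[j + 1L]))
    if (lost == 0L) next
    R <- S[j + 1L] / S[j]
    if (R > 1 + 1e-9)
      stop(sprintf("interval [%g, %g): survival increases", b[j], b[j + 1L]))
    d_star <- (n0 + n1) * (1 - R) / (1 + R)
    if (d_star < -1e-9 || d_star > lost + 1e-9)
      stop(sprintf("interval [%g, %g): implied events (%.2f) outside [0, %d]",
                   b[j], b[j + 1L], d_star, lost))
    # largest-remainder rounding of (d*, c*) with fixed integer sum
    d <- floor(d_star); c_ <- floor(lost - d_star)
    if (d + c_ < lost) {
      if ((d_star - d) >= (lost - d_star - c_)) d <- d + 1L else c_ <- c_ + 1L
    }
    d <- max(0L, min(lost, d)); c_ <- lost - d
    width <- b[j + 1L] - b[j]
    if (d > 0) {
      times <- c(times, b[j] + width * (seq_len(d) - 0.5) / d)
      events <- c(events, rep(1L, d))
    }
    if (c_ > 0) {
      times <- c(times, b[j] + width * (seq_len(c_) - 0.5) / c_)
      events <- c(events, rep(0L, c_))
    }
  }
  n_end <- n[length(n)]
  if (n_end > 0) {
    times <- c(times, rep(b[length(b)], n_end))
    events <- c(events, rep(0L, n_end))
  }
  if (length(times) == 0L) stop("reconstruction produced no records")
  ord <- order(times, -events)
  pseudo_ipd(times[ord], events[ord])
}

#' Fit a parametric survival law to pseudo individual-patient data
#'
#' Maximum-likelihood fit of the Weibull (proportional-hazards
#' parameterisation) or exponential law, with observed-information
#' standard errors, via [flexsurv::flexsurvreg()].  As a goodness-of-fit
#' diagnostic, the adjusted R-squared and correlation coefficient of the
#' linear regression of `log(-log S_KM)` on `log t` over the Kaplan-Meier
#' support are also reported.
#'
#' @param data A [pseudo_ipd()].
#' @param family `"weibull"` or `"exponential"`.
#' @param time_unit Time unit the data are recorded in.
#' @return A list of class `fit_result` with elements `model`
#'   (a [parametric_survival()]), `scale_se`, `shape_se`, `adjusted_r2`,
#'   `correlation`, `loglik`, `n_events`.
#' @export
fit_parametric <- function(data, family = c("weibull", "exponential"),
                           time_unit = "months") {
  family <- match.arg(family)
  stopifnot(inherits(data, "pseudo_ipd"))
  d_events <- sum(data$event == 1L)
  if (d_events == 0L) stop("all records are censored; cannot fit")
  if (family == "weibull" &&
      length(unique(data$time[data$event == 1L])) < 2L)
    stop("weibull shape is unidentifiable with fewer than 2 distinct event times")

  dist <- if (family == "weibull") "weibullPH" else "exp"
  fs <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = data, dist = dist),
    error = function(e) stop("parametric fit did not converge: ", conditionMessage(e)))

  if (family == "weibull") {
    scale <- unname(fs$res["scale", "est"]); scale_se <- unname(fs$res["scale", "se"])
    shape <- unname(fs$res["shape", "est"]); shape_se <- unname(fs$res["shape", "se"])
  } else {
    scale <- unname(fs$res["rate", "est"]); scale_se <- unname(fs$res["rate", "se"])
    shape <- 1; shape_se <- NA_real_
  }

  km <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  keep <- km$surv > 0 & km$surv < 1 & km$n.event > 0 & km$time > 0
  adj_r2 <- NA_real_; corr <- NA_real_
  if (sum(keep) >= 3L) {
    x <- log(km$time[keep]); y <- log(-log(km$surv[keep]))
    fit_lm <- stats::lm(y ~ x)
    adj_r2 <- summary(fit_lm)$adj.r.squared
    corr <- -abs(stats::cor(x, y)) # survival vs time correlation is negative
  }

  structure(list(model = parametric_survival(family, scale, shape, time_unit),
                 scale_se = scale_se, shape_se = shape_se,
                 adjusted_r2 = adj_r2, correlation = corr,
                 loglik = fs$loglik, n_events = d_events),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s fit: scale %.5g (SE %.3g), shape %.5g%s\n",
              x$model$family, x$model$scale, x$scale_se, x$model$shape,
              if (is.na(x$shape_se)) "" else sprintf(" (SE %.3g)", x$shape_se)))
  cat(sprintf("  events %d, loglik %.2f, adj R^2 %.4f\n",
              x$n_events, x$loglik, x$adjusted_r2))
  invisible(x)
}

#' Read/write pseudo-IPD and digitized curves as CSV
#'
#' `write_pseudo_ipd`/`read_pseudo_ipd` use columns `time,event`;
#' `write_digitized_curve`/`read_digitized_curve` use `time,survival`
#' with an optional companion file `<path>_at_risk.csv` holding
#' `time,n_at_risk`.
#'
#' @param x Object to write.
#' @param path CSV path.
#' @return The object read, or (invisibly) the path written.
#' @name ipd_io
NULL

#' @rdname ipd_io
#' @export
write_pseudo_ipd <- function(x, path) {
  stopifnot(inherits(x, "pseudo_ipd"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ipd_io
#' @export
read_pseudo_ipd <- function(path) {
  d <- utils::read.csv(path)
  pseudo_ipd(d$time, d$event)
}

#' @rdname ipd_io
#' @export
write_digitized_curve <- function(x, path) {
  stopifnot(inherits(x, "digitized_curve"))
  utils::write.csv(x$points, path, row.names = FALSE)
  if (!is.null(x$at_risk))
    utils::write.csv(x$at_risk, sub("\\.csv$", "_at_risk.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname ipd_io
#' @export
read_digitized_curve <- function(path) {
  pts <- utils::read.csv(path)
  ar_path <- sub("\\.csv$", "_at_risk.csv", path)
  ar <- if (file.exists(ar_path)) utils::read.csv(ar_path) else NULL
  digitized_curve(pts$time, pts$survival, at_risk = ar)
}
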