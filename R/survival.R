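#' Parametric survival law
#'
#' Construct a Weibull or exponential survival law in the proportional-hazards
#' parameterisation \eqn{S(t) = \exp(-\lambda t^\gamma)}, where \eqn{\lambda}
#' is the scale and \eqn{\gamma} the shape.  The exponential law is the
#' special case \eqn{\gamma = 1}.  Time is measured in an explicit unit so
#' that cycle lengths given in days can be converted unambiguously.
#'
#' @param family `"weibull"` or `"exponential"`.
#' @param scale Positive scale \eqn{\lambda} (units `time_unit^-shape`).
#' @param shape Positive shape \eqn{\gamma}; must be 1 for the exponential.
#' @param time_unit One of `"days"`, `"weeks"`, `"months"`, `"years"`, or
#'   `"cycles"` (21-day treatment cycles, the natural unit of parameters
#'   fitted on a three-weekly schedule).
#'
#' @return An object of class `parametric_survival`.
#' @export
#' @examples
#' m <- parametric_survival("weibull", scale = 0.00059, shape = 1.48831)
#' survival_at(m, 36)
parametric_survival <- function(family = c("weibull", "exponential"),
                                scale, shape = 1,
                                time_unit = c("months", "days", "weeks", "years", "cycles")) {
  family <- match.arg(family)
  time_unit <- match.arg(time_unit)
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (scale <= 0) stop("`scale` must be > 0")
  if (shape <= 0) stop("`shape` must be > 0")
  if (family == "exponential" && shape != 1)
    stop("exponential law requires shape == 1")
  structure(list(family = family, scale = scale, shape = shape,
                 time_unit = time_unit),
            class = "parametric_survival")
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat(sprintf("<parametric_survival> %s: S(t) = exp(-%g * t^%g), t in %s\n",
              x$family, x$scale, x$shape, x$time_unit))
  invisible(x)
}

# days per unit of a model's time scale (365.25-day year convention)
.unit_days <- function(unit) {
  switch(unit,
         days = 1, weeks = 7, months = 365.25 / 12, years = 365.25, cycles = 21,
         stop("unknown time unit: ", unit))
}

#' Survivor function of a parametric law
#'
#' @param model A [parametric_survival()] object.
#' @param t Non-negative time(s) in the model's `time_unit`.
#' @return `exp(-scale * t^shape)`, vectorised over `t`.
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "parametric_survival"), is.numeric(t))
  if (any(t < 0)) stop("`t` must be non-negative")
  exp(-model$scale * t^model$shape)
}

#' Per-cycle transition probability out of a survival curve
#'
#' Conditional probability of the event occurring during cycle `k` given
#' survival to its start: `tp(k) = 1 - S(k*u) / S((k-1)*u)` for cycle
#' length `u` in the model's time unit.  For the exponential law this is
#' constant in `k`; for a Weibull with shape > 1 it is non-decreasing.
#'
#' @param model A [parametric_survival()] object.
#' @param cycle_index Positive integer cycle index (vectorised).
#' @param cycle_length Positive cycle length in the model's `time_unit`.
#' @return Probability in `[0, 1)`, one per `cycle_index`.
#' @export
cycle_transition_prob <- function(model, cycle_index, cycle_length) {
  stopifnot(inherits(model, "parametric_survival"),
            is.numeric(cycle_index), is.numeric(cycle_length),
            length(cycle_length) == 1L)
  if (cycle_length <= 0) stop("`cycle_length` must be > 0")
  if (any(cycle_index < 1) || any(cycle_index != floor(cycle_index)))
    stop("`cycle_index` must be a positive integer")
  k <- cycle_index
  u <- cycle_length
  if (model$family == "exponential") {
    rep_len(1 - exp(-model$scale * u), length(k))
  } else {
    1 - survival_at(model, k * u) / survival_at(model, (k - 1) * u)
  }
}

#' Model-implied survival landmarks
#'
#' Reports the survival probabilities a fitted law implies at landmark
#' times, so that the assumed time unit of published scale/shape
#' parameters can be checked against published Kaplan-Meier landmark
#' values (e.g. 3-year DFS/OS) instead of being taken on faith.
#'
#' @param model A [parametric_survival()] object.
#' @param times_years Landmark times in years.
#' @return A data frame with columns `years` and `survival`.
#' @export
implied_survival_summary <- function(model, times_years = c(1, 3, 5, 10)) {
  t_model <- times_years * 365.25 / .unit_days(model$time_unit)
  data.frame(years = times_years, survival = survival_at(model, t_model))
}
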