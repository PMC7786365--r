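# --- distribution builders ----------------------------------------------

#' Gamma distribution from a mean and a published range
#'
#' Method-of-moments gamma for cost parameters: the range is read as a
#' 95% interval, `se = (high - low) / 3.92`, then
#' `shape = mean^2 / se^2`, `rate = mean / se^2`.  The resulting
#' distribution has exactly the requested mean.
#'
#' @param mean Positive mean.
#' @param low,high Range bounds, `high > low`.
#' @return Named vector `c(shape, rate)`.
#' @export
gamma_from_mean_bounds <- function(mean, low, high) {
  if (mean <= 0) stop("`mean` must be positive")
  se <- (high - low) / 3.92
  if (!is.finite(se) || se <= 0) stop("range implies a non-positive SE")
  c(shape = mean^2 / se^2, rate = mean / se^2)
}

#' Beta distribution from a mean and a published range
#'
#' Method-of-moments beta for probabilities and utilities, with
#' `se = (high - low) / 3.92`.  If the implied variance is infeasible
#' (`se^2 >= mean (1 - mean)`) it is truncated to 95% of the feasible
#' maximum.
#'
#' @param mean Mean in (0, 1).
#' @param low,high Range bounds, `high > low`.
#' @return Named vector `c(alpha, beta)`; `alpha/(alpha+beta) == mean`.
#' @export
beta_from_mean_bounds <- function(mean, low, high) {
  if (mean <= 0 || mean >= 1) stop("`mean` must lie strictly in (0, 1)")
  se <- (high - low) / 3.92
  if (!is.finite(se) || se <= 0) stop("range implies a non-positive SE")
  v_max <- mean * (1 - mean)
  v <- min(se^2, 0.95 * v_max)
  nu <- v_max / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

# one random draw per parameter row; lognormal is centred on the log of
# the estimate with the delta-method log-scale SE (median-preserving)
.draw_param <- function(p) {
  switch(p$dist,
         gamma = {
           if (p$mean <= 0) return(p$mean)
           g <- gamma_from_mean_bounds(p$mean, p$low, p$high)
           stats::rgamma(1, shape = g["shape"], rate = g["rate"])
         },
         beta = {
           b <- beta_from_mean_bounds(p$mean, p$low, p$high)
           stats::rbeta(1, b["alpha"], b["beta"])
         },
         lognormal = {
           sdlog <- p$se / p$mean
           p$mean * exp(stats::rnorm(1, 0, sdlog))
         },
         fixed = p$mean,
         stop("unknown distribution: ", p$dist))
}

# --- one-way sensitivity analysis ---------------------------------------

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the full base case with each uncertain parameter set to
#' its lower and upper bound in turn (all others at base), recording the
#' incremental cost-effectiveness ratio at each bound.  No linear
#' approximation is used.  Entries are sorted by descending ICER spread.
#'
#' @param spec An [npc_model_spec()].
#' @param parameters Character vector of dotted parameter paths; defaults
#'   to every parameter with a non-degenerate range.
#' @param wastage Drug pricing policy.
#' @return A data frame of class `owsa_result` with columns `name`,
#'   `low`, `high`, `icer_at_low`, `icer_at_high`, `spread`, plus the
#'   base-case ICER in attribute `base_icer`.
#' @export
owsa <- function(spec, parameters = NULL,
                 wastage = c("vial_based", "exact_dose")) {
  wastage <- match.arg(wastage)
  pt <- param_table(spec)
  if (is.null(parameters)) {
    pt <- pt[!is.na(pt$low) & !is.na(pt$high) & pt$high > pt$low, ]
    parameters <- pt$name
  } else {
    missing <- setdiff(parameters, pt$name)
    if (length(missing))
      stop("parameter(s) not found: ", paste(missing, collapse = ", "))
    pt <- pt[match(parameters, pt$name), ]
  }
  icer_of <- function(s) {
    cmp <- evaluate_model(s, wastage)$comparison
    if (cmp$verdict == "icer") cmp$icer else cmp$delta_cost / cmp$delta_effect
  }
  base_icer <- icer_of(spec)
  res <- lapply(seq_len(nrow(pt)), function(i) {
    nm <- pt$name[i]
    lo <- if (is.na(pt$low[i])) pt$mean[i] else pt$low[i]
    hi <- if (is.na(pt$high[i])) pt$mean[i] else pt$high[i]
    data.frame(name = nm, low = lo, high = hi,
               icer_at_low = icer_of(set_param(spec, nm, lo)),
               icer_at_high = icer_of(set_param(spec, nm, hi)))
  })
  out <- do.call(rbind, res)
  out$spread <- abs(out$icer_at_high - out$icer_at_low)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  class(out) <- c("owsa_result", "data.frame")
  attr(out, "base_icer") <- base_icer
  out
}

# --- probabilistic sensitivity analysis ---------------------------------

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Each replicate draws every uncertain parameter from its distribution
#' (gamma for costs, beta for probabilities and utilities, log-normal
#' for survival scale/shape), rebuilds and reruns both arms, and records
#' the incremental cost and QALYs of the first arm over the second.
#' The scale and shape of each Weibull law are drawn jointly on the log
#' scale with their reported estimation correlation (the
#' `scale_shape_corr` field of the arm's survival entry, when present):
#' scale/shape estimates from survival fits are strongly negatively
#' correlated, and ignoring this grossly overstates uncertainty in the
#' extrapolated tail.  Fully reproducible given `seed`; replicates with
#' a non-finite result are kept and flagged, never dropped silently.
#'
#' @param spec An [npc_model_spec()].
#' @param n_samples Number of Monte Carlo replicates (default 10000).
#' @param seed Integer RNG seed.
#' @param wastage Drug pricing policy.
#' @return A data frame of class `psa_result` with columns `sample_id`,
#'   `delta_cost`, `delta_qaly`; attribute `n_nonfinite` counts degenerate
#'   replicates.
#' @export
run_psa <- function(spec, n_samples = 10000, seed = 1,
                    wastage = c("vial_based", "exact_dose")) {
  wastage <- match.arg(wastage)
  stopifnot(n_samples >= 1)
  pt <- param_table(spec)
  # survival scale/shape pairs are drawn jointly; everything else singly
  surv_paths <- pt$name[pt$dist == "lognormal"]
  generic <- pt$name[!(pt$dist %in% c("fixed", "lognormal"))]
  samplers <- lapply(generic, function(nm) {
    p <- .get_param(spec, nm)
    if (p$dist == "gamma") {
      if (p$mean <= 0) return(function() p$mean)
      g <- gamma_from_mean_bounds(p$mean, p$low, p$high)
      function() stats::rgamma(1, shape = g[["shape"]], rate = g[["rate"]])
    } else {
      b <- beta_from_mean_bounds(p$mean, p$low, p$high)
      function() stats::rbeta(1, b[["alpha"]], b[["beta"]])
    }
  })
  names(samplers) <- generic

  surv_blocks <- list()
  for (arm in names(spec$arms)) {
    for (ep in names(spec$arms[[arm]]$survival)) {
      sv <- spec$arms[[arm]]$survival[[ep]]
      if (!inherits(sv$scale, "cea_param") || sv$scale$dist != "lognormal") next
      surv_blocks[[paste(arm, ep, sep = ".")]] <- list(
        arm = arm, endpoint = ep,
        scale = sv$scale$mean, sd_log_scale = sv$scale$se / sv$scale$mean,
        shape = sv$shape$mean,
        sd_log_shape = if (inherits(sv$shape, "cea_param") &&
                           sv$shape$dist == "lognormal")
          sv$shape$se / sv$shape$mean else 0,
        corr = if (!is.null(sv$scale_shape_corr)) sv$scale_shape_corr else 0)
    }
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  dc <- numeric(n_samples); dq <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    s <- spec
    for (b in surv_blocks) {
      z1 <- stats::rnorm(1)
      sv <- s$arms[[b$arm]]$survival[[b$endpoint]]
      sv$scale$mean <- b$scale * exp(b$sd_log_scale * z1)
      if (b$sd_log_shape > 0) {
        z2 <- b$corr * z1 + sqrt(1 - b$corr^2) * stats::rnorm(1)
        sv$shape$mean <- b$shape * exp(b$sd_log_shape * z2)
      }
      s$arms[[b$arm]]$survival[[b$endpoint]] <- sv
    }
    for (nm in generic) s <- set_param(s, nm, samplers[[nm]]())
    arms <- names(s$arms)
    r1 <- run_arm(s, arms[1], wastage)
    r2 <- run_arm(s, arms[2], wastage)
    dc[i] <- r1$total_cost - r2$total_cost
    dq[i] <- r1$total_qaly - r2$total_qaly
  }
  out <- data.frame(sample_id = seq_len(n_samples), delta_cost = dc, delta_qaly = dq)
  class(out) <- c("psa_result", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "n_nonfinite") <- sum(!is.finite(dc) | !is.finite(dq))
  if (attr(out, "n_nonfinite") > 0)
    warning(attr(out, "n_nonfinite"), " replicate(s) produced non-finite results")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA replicates
#' with positive incremental net monetary benefit,
#' `wtp * dQALY - dCost > 0`.
#'
#' @param samples A `psa_result` (or data frame with `delta_cost`,
#'   `delta_qaly`).
#' @param wtp_grid Increasing willingness-to-pay values.
#' @return A data frame with columns `wtp` and `probability`.
#' @export
ceac <- function(samples, wtp_grid) {
  stopifnot(nrow(samples) > 0, length(wtp_grid) > 0)
  data.frame(wtp = wtp_grid,
             probability = vapply(wtp_grid, function(w)
               mean(w * samples$delta_qaly - samples$delta_cost > 0), numeric(1)))
}

#' Probability of cost-effectiveness at one threshold
#'
#' @param samples A `psa_result`.
#' @param wtp Willingness-to-pay per QALY.
#' @return Fraction of replicates with positive incremental net monetary
#'   benefit.
#' @export
prob_cost_effective <- function(samples, wtp) {
  ceac(samples, wtp)$probability
}
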