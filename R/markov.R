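#' Markov model configuration
#'
#' Cycle length, horizon and discounting for the three-state cohort model.
#' The cycle count is the number of complete cycles inside the horizon,
#' `floor(horizon_years * 365.25 / cycle_length_days)`; with the defaults
#' (21-day cycles, 10-year horizon) that is 173 cycles.  The per-cycle
#' discount factor is `(1 + annual_discount)^(-cycle_length_days/365.25)`.
#'
#' @param cycle_length_days Positive cycle length in days (default 21).
#' @param horizon_years Positive model horizon in years (default 10).
#' @param annual_discount Annual discount rate in `[0, 1)` (default 0.03).
#' @param half_cycle_correction Average start- and end-of-cycle occupancy
#'   when accruing rewards (default `FALSE`).
#' @return An object of class `model_config`.
#' @export
model_config <- function(cycle_length_days = 21, horizon_years = 10,
                         annual_discount = 0.03, half_cycle_correction = FALSE) {
  stopifnot(cycle_length_days > 0, horizon_years > 0,
            annual_discount >= 0, annual_discount < 1,
            is.logical(half_cycle_correction))
  cfg <- structure(list(cycle_length_days = cycle_length_days,
                        horizon_years = horizon_years,
                        annual_discount = annual_discount,
                        half_cycle_correction = half_cycle_correction),
                   class = "model_config")
  if (n_cycles(cfg) < 1L) stop("horizon shorter than one cycle")
  cfg
}

#' @rdname model_config
#' @param config A `model_config`.
#' @export
n_cycles <- function(config) {
  as.integer(floor(config$horizon_years * 365.25 / config$cycle_length_days))
}

# discount factors for cycles 1..K (end-of-cycle convention)
.discount_factors <- function(config, K = n_cycles(config)) {
  (1 + config$annual_discount)^(-(seq_len(K)) * config$cycle_length_days / 365.25)
}

#' Build the per-cycle three-state transition schedule
#'
#' Transition probabilities between DFS (disease-free survival), PD
#' (progressed disease) and Death are derived from the fitted DFS and OS
#' laws.  Two decompositions are available:
#'
#' * `"independent"` (default): every alive state shares the OS-curve
#'   per-cycle death probability, and DFS additionally loses the
#'   DFS-curve per-cycle transition probability to PD.  The alive
#'   fraction then equals `S_os(k u)` exactly, so cumulative deaths track
#'   the overall-survival curve by construction.  This is the
#'   conventional partitioned structure of cohort models built directly
#'   from published DFS and OS curves.
#' * `"hazard_partition"`: the probability of leaving DFS is the
#'   DFS-curve transition probability, of which the part routed directly
#'   to Death is capped by the OS-curve transition probability; the
#'   PD-to-Death probability is then calibrated per cycle so cumulative
#'   deaths track `1 - S_os(k u)`.  Under this scheme DFS occupancy
#'   equals `S_dfs(k u)` exactly and identical DFS/OS curves route no
#'   one to PD.
#'
#' Either way, probabilities that would leave `[0, 1]` are clamped;
#' affected cycles are recorded in the `clamped_cycles` attribute, and a
#' warning is raised only if the death-tracking deficit persists to the
#' end of the horizon.
#'
#' @param dfs,os [parametric_survival()] laws for disease-free and overall
#'   survival, sharing a time unit.
#' @param config A [model_config()].
#' @param method `"independent"` or `"hazard_partition"` (see above).
#' @return A data frame of class `transition_schedule` with columns
#'   `cycle`, `dfs_dfs`, `dfs_pd`, `dfs_death`, `pd_pd`, `pd_death`.
#' @export
build_transition_schedule <- function(dfs, os, config,
                                      method = c("independent", "hazard_partition")) {
  method <- match.arg(method)
  stopifnot(inherits(dfs, "parametric_survival"),
            inherits(os, "parametric_survival"),
            inherits(config, "model_config"))
  if (dfs$time_unit != os$time_unit)
    stop("DFS and OS laws must share a time unit")
  K <- n_cycles(config)
  u <- config$cycle_length_days / .unit_days(dfs$time_unit)
  S_dfs <- survival_at(dfs, (0:K) * u)
  S_os  <- survival_at(os,  (0:K) * u)
  p_leave <- 1 - S_dfs[-1] / S_dfs[-(K + 1)]
  p_os    <- 1 - S_os[-1] / S_os[-(K + 1)]

  if (method == "independent") {
    p_dfs_death <- p_os
    p_dfs_pd <- pmin(p_leave, 1 - p_os)
    clamped <- p_leave > 1 - p_os
    out <- data.frame(cycle = seq_len(K),
                      dfs_dfs = 1 - p_dfs_pd - p_dfs_death,
                      dfs_pd = p_dfs_pd,
                      dfs_death = p_dfs_death,
                      pd_pd = 1 - p_os,
                      pd_death = p_os)
    class(out) <- c("transition_schedule", "data.frame")
    attr(out, "clamped_cycles") <- which(clamped)
    return(out)
  }

  p_dfs_death <- pmin(p_leave, p_os)
  p_dfs_pd <- p_leave - p_dfs_death

  p_pd_death <- numeric(K)
  clamped <- logical(K)
  dfs_occ <- 1; pd_occ <- 0; dead_occ <- 0
  for (k in seq_len(K)) {
    deaths_from_dfs <- dfs_occ * p_dfs_death[k]
    needed <- (1 - S_os[k + 1]) - dead_occ - deaths_from_dfs
    if (pd_occ > 0) {
      p <- needed / pd_occ
      if (p < 0 || p > 1) clamped[k] <- TRUE
      p_pd_death[k] <- min(max(p, 0), 1)
    } else {
      p_pd_death[k] <- 0
      if (needed > 1e-12) clamped[k] <- TRUE
    }
    deaths_from_pd <- pd_occ * p_pd_death[k]
    new_pd <- dfs_occ * p_dfs_pd[k]
    dfs_occ <- dfs_occ * (1 - p_leave[k])
    pd_occ <- pd_occ + new_pd - deaths_from_pd
    dead_occ <- dead_occ + deaths_from_dfs + deaths_from_pd
  }
  final_deficit <- abs(dead_occ - (1 - S_os[K + 1]))
  if (final_deficit > 1e-8)
    warning(sprintf(paste0("PD->Death calibration clamped and did not recover: ",
                           "final death deficit %.3g (cycles %s)"),
                    final_deficit,
                    paste(utils::head(which(clamped), 10), collapse = ",")),
            call. = FALSE)

  out <- data.frame(cycle = seq_len(K),
                    dfs_dfs = 1 - p_leave,
                    dfs_pd = p_dfs_pd,
                    dfs_death = p_dfs_death,
                    pd_pd = 1 - p_pd_death,
                    pd_death = p_pd_death)
  class(out) <- c("transition_schedule", "data.frame")
  attr(out, "clamped_cycles") <- which(clamped)
  out
}

#' Per-cycle transition matrices of a schedule
#'
#' @param schedule A `transition_schedule`.
#' @return A list of 3x3 row-stochastic matrices (states DFS, PD, Death;
#'   the Death row is exactly absorbing).
#' @export
schedule_matrices <- function(schedule) {
  stopifnot(inherits(schedule, "transition_schedule"))
  lapply(seq_len(nrow(schedule)), function(k) {
    r <- schedule[k, ]
    matrix(c(r$dfs_dfs, r$dfs_pd, r$dfs_death,
             0,         r$pd_pd,  r$pd_death,
             0,         0,        1),
           nrow = 3, byrow = TRUE,
           dimnames = list(c("dfs", "pd", "dead"), c("dfs", "pd", "dead")))
  })
}

#' Run the cohort trace
#'
#' Propagates a cohort through the per-cycle transition matrices:
#' `occupancy_k = occupancy_{k-1} %*% M_k`.  Row 1 of the result is the
#' starting distribution (cycle 0).
#'
#' @param schedule A `transition_schedule` (or a list of 3x3 matrices).
#' @param config A [model_config()]; the schedule must cover its horizon.
#' @param start Starting state distribution over (DFS, PD, Death);
#'   defaults to the whole cohort in DFS.
#' @return A data frame of class `cohort_trace` with columns `cycle`,
#'   `dfs`, `pd`, `dead`.
#' @export
run_cohort <- function(schedule, config, start = c(1, 0, 0)) {
  K <- n_cycles(config)
  stopifnot(length(start) == 3L, all(start >= 0),
            abs(sum(start) - 1) < 1e-9)
  if (inherits(schedule, "transition_schedule")) {
    if (nrow(schedule) < K) stop("schedule covers ", nrow(schedule),
                                 " cycles but the horizon needs ", K)
    # scalar recursion; the Death state is absorbing so it is the remainder
    dfs <- numeric(K + 1L); pd <- numeric(K + 1L); dead <- numeric(K + 1L)
    dfs[1L] <- start[1]; pd[1L] <- start[2]; dead[1L] <- start[3]
    p_stay <- schedule$dfs_dfs; p_pd <- schedule$dfs_pd
    p_dd <- schedule$dfs_death; p_pp <- schedule$pd_pd; p_pdd <- schedule$pd_death
    for (k in seq_len(K)) {
      dfs[k + 1L] <- dfs[k] * p_stay[k]
      pd[k + 1L] <- dfs[k] * p_pd[k] + pd[k] * p_pp[k]
      dead[k + 1L] <- dead[k] + dfs[k] * p_dd[k] + pd[k] * p_pdd[k]
    }
    out <- data.frame(cycle = 0:K, dfs = dfs, pd = pd, dead = dead)
    class(out) <- c("cohort_trace", "data.frame")
    return(out)
  }
  mats <- schedule
  if (length(mats) < K) stop("schedule covers ", length(mats),
                             " cycles but the horizon needs ", K)
  occ <- matrix(0, nrow = K + 1L, ncol = 3L)
  occ[1L, ] <- start
  v <- start
  for (k in seq_len(K)) {
    v <- as.numeric(v %*% mats[[k]])
    occ[k + 1L, ] <- v
  }
  out <- data.frame(cycle = 0:K, dfs = occ[, 1], pd = occ[, 2], dead = occ[, 3])
  class(out) <- c("cohort_trace", "data.frame")
  out
}

#' Discounted reward accrual over a cohort trace
#'
#' Sums `v^k * occupancy * reward` over cycles, where the per-cycle
#' discount factor is `(1+r)^(-cycle_days/365.25)`.  Rewards are given
#' per state and cycle; occupancy is taken at the end of each cycle
#' (or as the start/end average under half-cycle correction).  Death
#' accrues nothing.
#'
#' @param trace A `cohort_trace`.
#' @param rewards A list with numeric vectors `dfs` and `pd`, one value
#'   per cycle (length `n_cycles(config)`), in reward units per cycle.
#' @param config A [model_config()].
#' @return A list with `total` and the per-state decomposition
#'   `dfs`, `pd`.
#' @export
discounted_accrual <- function(trace, rewards, config) {
  stopifnot(inherits(trace, "cohort_trace"), is.list(rewards),
            all(c("dfs", "pd") %in% names(rewards)))
  K <- n_cycles(config)
  if (nrow(trace) < K + 1L) stop("trace shorter than the configured horizon")
  if (length(rewards$dfs) != K || length(rewards$pd) != K)
    stop("rewards must have one value per cycle (", K, ")")
  v <- .discount_factors(config, K)
  occ_dfs <- trace$dfs[2:(K + 1L)]
  occ_pd <- trace$pd[2:(K + 1L)]
  if (config$half_cycle_correction) {
    occ_dfs <- (trace$dfs[1:K] + occ_dfs) / 2
    occ_pd <- (trace$pd[1:K] + occ_pd) / 2
  }
  dfs_total <- sum(v * occ_dfs * rewards$dfs)
  pd_total <- sum(v * occ_pd * rewards$pd)
  list(total = dfs_total + pd_total, dfs = dfs_total, pd = pd_total)
}

#' Export a cohort trace as CSV
#'
#' Columns: `cycle`, `dfs`, `pd`, `dead`, `discount_factor`.
#'
#' @param trace A `cohort_trace`.
#' @param config The [model_config()] the trace was run under.
#' @param path Output CSV path.
#' @export
write_cohort_trace <- function(trace, config, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  K <- nrow(trace) - 1L
  df <- as.data.frame(trace)
  df$discount_factor <- c(1, .discount_factors(config, K))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
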