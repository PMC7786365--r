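# --- drug acquisition and the single-use-vial wastage policy ------------

# cheapest whole-vial covering of a dose when every vial of a drug has the
# same per-mg price: minimise total billed milligrams over vial combinations
.min_billed_mg <- function(dose_mg, vial_sizes_mg) {
  if (dose_mg <= 0) return(0)
  sizes <- sort(vial_sizes_mg, decreasing = TRUE)
  best <- Inf
  recurse <- function(i, rem, billed) {
    if (billed >= best) return()
    if (rem <= 0) { best <<- billed; return() }
    if (i == length(sizes)) {
      total <- billed + ceiling(rem / sizes[i]) * sizes[i]
      if (total < best) best <<- total
      return()
    }
    for (n in ceiling(rem / sizes[i]):0)
      recurse(i + 1L, rem - n * sizes[i], billed + n * sizes[i])
  }
  recurse(1L, dose_mg, 0)
  best
}

#' Chemotherapy drug cost per cycle under a wastage policy
#'
#' `vial_based` pricing rounds every administration up to the cheapest
#' combination of whole single-use vials; `exact_dose` pricing charges
#' only the administered milligrams.  Vial-based cost is never below
#' exact-dose cost.
#'
#' @param dose_rules Named list, one entry per drug, each with
#'   `mg_per_m2` and `n_admin` (administrations per cycle).
#' @param catalogue Named list, one entry per drug, each with
#'   `vial_sizes_mg` and `price_per_mg`.
#' @param bsa_m2 Body surface area in square metres.
#' @param mode `"vial_based"` or `"exact_dose"`.
#' @return Named vector of per-cycle costs, one per drug.
#' @export
drug_cost_per_cycle <- function(dose_rules, catalogue, bsa_m2 = 1.72,
                                mode = c("vial_based", "exact_dose")) {
  mode <- match.arg(mode)
  vapply(names(dose_rules), function(drug) {
    rule <- dose_rules[[drug]]
    cat_d <- catalogue[[drug]]
    if (is.null(cat_d) || length(cat_d$vial_sizes_mg) == 0L)
      stop("no vials in catalogue for drug: ", drug)
    dose <- rule$mg_per_m2 * bsa_m2
    mg <- if (mode == "vial_based") .min_billed_mg(dose, cat_d$vial_sizes_mg)
          else dose
    rule$n_admin * mg * cat_d$price_per_mg
  }, numeric(1))
}

# per-drug multiplier taking a vial-based acquisition cost to its
# exact-dose counterpart (<= 1 by construction)
.wastage_ratios <- function(dose_rules, catalogue, bsa_m2) {
  exact <- drug_cost_per_cycle(dose_rules, catalogue, bsa_m2, "exact_dose")
  vial <- drug_cost_per_cycle(dose_rules, catalogue, bsa_m2, "vial_based")
  ifelse(vial > 0, exact / vial, 1)
}

# --- adverse events -----------------------------------------------------

#' Expected adverse-event management cost
#'
#' Sum over adverse-event classes of probability times unit management
#' cost; the total is charged once, in the first model cycle.
#'
#' @param ae A list with parameters `g12_cost`, `g34_cost`, `p_g12`,
#'   `p_leucopenia_g34`, `p_neutropenia_g34` (each a [cea_param()] or a
#'   number).
#' @return Expected cost (money).
#' @export
expected_ae_cost <- function(ae) {
  val <- function(p) if (inherits(p, "cea_param")) p$mean else p
  val(ae$p_g12) * val(ae$g12_cost) +
    (val(ae$p_leucopenia_g34) + val(ae$p_neutropenia_g34)) * val(ae$g34_cost)
}

# --- cost accrual schedule ----------------------------------------------

#' Convert a periodic cost to a per-cycle cost
#'
#' @param amount Cost accrued per period.
#' @param period_days Period length in days (>= cycle length).
#' @param cycle_days Cycle length in days.
#' @return `amount * cycle_days / period_days`.
#' @export
period_to_cycle_cost <- function(amount, period_days, cycle_days) {
  if (period_days <= 0 || cycle_days <= 0) stop("periods must be positive")
  if (period_days < cycle_days) stop("period must be at least one cycle")
  amount * cycle_days / period_days
}

#' Per-cycle cost vectors for one treatment arm
#'
#' Lays the arm's cost items onto the cycle grid: induction cycles 1-3
#' carry drug acquisition, supportive care, hospitalization and
#' laboratory costs; the PICC line and the expected adverse-event cost
#' are charged in cycle 1; concurrent chemoradiotherapy cycles 4-6 carry
#' radiotherapy and concurrent cisplatin, with radiotherapy preparation
#' and pre-treatment imaging charged once at cycle 4; disease-free cycles
#' thereafter carry the time-banded follow-up cost (years 0-2 / 3-5 /
#' 6-10, banded by end-of-cycle time); every progressed-disease cycle
#' carries the mix of subsequent treatment and best supportive care.
#' Under the `exact_dose` wastage policy the drug acquisition items are
#' deflated by the catalogue's administered-to-billed milligram ratio.
#'
#' @param spec An [npc_model_spec()].
#' @param arm `"GP"` or `"TPF"`.
#' @param wastage `"vial_based"` (base case) or `"exact_dose"`.
#' @return A list with per-cycle vectors `dfs` and `pd` (length
#'   `n_cycles(spec$config)`).
#' @export
build_cycle_costs <- function(spec, arm,
                              wastage = c("vial_based", "exact_dose")) {
  wastage <- match.arg(wastage)
  a <- spec$arms[[arm]]
  if (is.null(a)) stop("unknown arm: ", arm)
  sh <- spec$shared
  config <- spec$config
  K <- n_cycles(config)
  cl <- config$cycle_length_days

  drug_items <- intersect(names(a$induction), names(spec$doses[[arm]]))
  for (item in c("hydration", "antiemetic", "hospitalization", "laboratory"))
    if (is.null(a$induction[[item]]))
      stop("arm ", arm, " is missing mandatory cost item: ", item)

  ratios <- rep(1, length(drug_items)); names(ratios) <- drug_items
  ccrt_cis_ratio <- 1
  if (wastage == "exact_dose") {
    ratios <- .wastage_ratios(spec$doses[[arm]][drug_items],
                              spec$vial_catalogue, spec$bsa_m2)
    ccrt_cis_ratio <- .wastage_ratios(spec$doses$ccrt, spec$vial_catalogue,
                                      spec$bsa_m2)[["cisplatin"]]
  }

  induction_per_cycle <- 0
  for (item in names(a$induction)) {
    r <- if (item %in% drug_items) ratios[[item]] else 1
    induction_per_cycle <- induction_per_cycle + r * a$induction[[item]]$mean
  }

  dfs <- numeric(K)
  dfs[seq_len(min(3L, K))] <- induction_per_cycle
  dfs[1L] <- dfs[1L] + a$picc$cost$mean * a$picc$rate$mean + expected_ae_cost(a$ae)
  ccrt_cycles <- intersect(4:6, seq_len(K))
  dfs[ccrt_cycles] <- dfs[ccrt_cycles] + sh$ccrt$radiotherapy$mean +
    ccrt_cis_ratio * sh$ccrt$cisplatin$mean
  if (K >= 4L) dfs[4L] <- dfs[4L] + sh$ccrt$preparation$mean + sh$ccrt$imaging$mean
  if (K >= 7L) {
    k <- 7:K
    end_day <- k * cl
    band <- ifelse(end_day <= 2 * 365.25, sh$follow_up$band1$mean,
                   ifelse(end_day <= 5 * 365.25, sh$follow_up$band2$mean,
                          sh$follow_up$band3$mean))
    dfs[k] <- dfs[k] + band
  }

  p_sub <- a$pd$p_subsequent$mean
  pd_cost <- p_sub * a$pd$subsequent$mean + (1 - p_sub) * sh$bsc$mean
  list(dfs = dfs, pd = rep(pd_cost, K))
}

#' Export per-cycle cost vectors as CSV
#'
#' @param costs Result of [build_cycle_costs()].
#' @param path Output CSV path (columns `cycle`, `dfs_cost`, `pd_cost`).
#' @export
write_cycle_costs <- function(costs, path) {
  utils::write.csv(data.frame(cycle = seq_along(costs$dfs),
                              dfs_cost = costs$dfs, pd_cost = costs$pd),
                   path, row.names = FALSE)
  invisible(path)
}
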