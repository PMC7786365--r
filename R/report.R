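# write a run manifest listing every file a reporting run produced
.write_manifest <- function(out_dir, subcommand, seed, files) {
  manifest <- list(subcommand = subcommand,
                   seed = seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   package_version = as.character(utils::packageVersion("npccea")),
                   output_directory = out_dir,
                   files = files)
  path <- file.path(out_dir, paste0(subcommand, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run and report the base-case analysis
#'
#' Evaluates both arms, assembles the results table (total and per-state
#' rows with incremental values and ICERs per LY and per QALY), and, if
#' `out_dir` is given, writes `base_case_results.csv`, per-arm cohort
#' traces and cost vectors, a `base_case_summary.json`, and a manifest.
#' Re-running with the same inputs overwrites with identical content.
#'
#' @param spec An [npc_model_spec()] (default: the built-in two-arm
#'   specification).
#' @param out_dir Output directory, created if needed; `NULL` for no files.
#' @param wastage Drug pricing policy.
#' @return Invisibly, a list with `results` (the table), `evaluation`
#'   and `summary`.
#' @export
run_base_case <- function(spec = npc_model_spec(), out_dir = NULL,
                          wastage = c("vial_based", "exact_dose")) {
  wastage <- match.arg(wastage)
  ev <- evaluate_model(spec, wastage)
  tab <- results_table(ev)
  cmp <- ev$comparison
  summary <- list(
    wastage = wastage,
    intervention = ev$arm_results[[1]]$arm,
    comparator = ev$arm_results[[2]]$arm,
    delta_cost = cmp$delta_cost,
    delta_qaly = cmp$delta_effect,
    delta_ly = ev$comparison_ly$delta_effect,
    verdict = cmp$verdict,
    icer_per_qaly = if (cmp$verdict == "icer") cmp$icer else NA,
    icer_per_ly = if (ev$comparison_ly$verdict == "icer") ev$comparison_ly$icer else NA,
    wtp = cmp$wtp,
    incremental_nmb = net_monetary_benefit(ev$arm_results[[1]], cmp$wtp) -
      net_monetary_benefit(ev$arm_results[[2]], cmp$wtp)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    f <- file.path(out_dir, "base_case_results.csv")
    utils::write.csv(tab, f, row.names = FALSE); files <- c(files, f)
    for (arm in names(spec$arms)) {
      r <- run_arm(spec, arm, wastage, keep_trace = TRUE)
      f <- file.path(out_dir, paste0("trace_", arm, ".csv"))
      write_cohort_trace(r$trace, spec$config, f); files <- c(files, f)
      f <- file.path(out_dir, paste0("costs_", arm, ".csv"))
      write_cycle_costs(build_cycle_costs(spec, arm, wastage), f)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "base_case_summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
    .write_manifest(out_dir, "base_case", NA, files)
  }
  invisible(list(results = tab, evaluation = ev, summary = summary))
}

#' Run and report the one-way sensitivity analysis
#'
#' @param spec An [npc_model_spec()].
#' @param out_dir Output directory; `NULL` for no files.  Writes the
#'   tornado table (sorted by spread) as CSV, the tornado diagram as SVG
#'   and a manifest.
#' @param parameters Optional parameter subset (dotted paths).
#' @return Invisibly, the `owsa_result`.
#' @export
run_owsa_report <- function(spec = npc_model_spec(), out_dir = NULL,
                            parameters = NULL) {
  tor <- owsa(spec, parameters)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f_csv <- file.path(out_dir, "tornado.csv")
    utils::write.csv(as.data.frame(tor), f_csv, row.names = FALSE)
    f_fig <- file.path(out_dir, "tornado.pdf")
    ggplot2::ggsave(f_fig, plot_tornado(tor), width = 8, height = 6)
    .write_manifest(out_dir, "owsa", NA, c(f_csv, f_fig))
  }
  invisible(tor)
}

#' Run and report the probabilistic sensitivity analysis
#'
#' @param spec An [npc_model_spec()].
#' @param n_samples Monte Carlo replicates (default 10000).
#' @param seed Integer RNG seed.
#' @param out_dir Output directory; `NULL` for no files.  Writes the
#'   sample table and acceptability curve as CSV, the CE-plane and CEAC
#'   figures as SVG, a JSON summary and a manifest.
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve;
#'   defaults to 0 to 60,000 in steps of 2,000 plus the specification's
#'   thresholds.
#' @return Invisibly, a list with `samples`, `ceac` and `summary`.
#' @export
run_psa_report <- function(spec = npc_model_spec(), n_samples = 10000,
                           seed = 1, out_dir = NULL, wtp_grid = NULL) {
  if (is.null(wtp_grid))
    wtp_grid <- sort(unique(c(seq(0, 60000, by = 2000), unname(spec$wtp))))
  samples <- run_psa(spec, n_samples, seed)
  curve <- ceac(samples, wtp_grid)
  summary <- c(list(n_samples = n_samples, seed = seed),
               stats::setNames(
                 lapply(unname(spec$wtp), function(w) prob_cost_effective(samples, w)),
                 paste0("prob_ce_at_", names(spec$wtp))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f_samp <- file.path(out_dir, "psa_samples.csv")
    utils::write.csv(as.data.frame(samples), f_samp, row.names = FALSE)
    f_ceac <- file.path(out_dir, "ceac.csv")
    utils::write.csv(curve, f_ceac, row.names = FALSE)
    f_plane <- file.path(out_dir, "ce_plane.pdf")
    ggplot2::ggsave(f_plane, plot_ce_plane(samples, wtp = unname(spec$wtp[length(spec$wtp)])),
                    width = 7, height = 6)
    f_fig <- file.path(out_dir, "ceac.pdf")
    ggplot2::ggsave(f_fig, plot_ceac(curve, wtp_lines = unname(spec$wtp)),
                    width = 7, height = 5)
    f_sum <- file.path(out_dir, "psa_summary.json")
    jsonlite::write_json(summary, f_sum, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    .write_manifest(out_dir, "psa", seed, c(f_samp, f_ceac, f_plane, f_fig, f_sum))
  }
  invisible(list(samples = samples, ceac = curve, summary = summary))
}
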