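make_trace <- function(df) structure(df, class = c("cohort_trace", "data.frame"))

test_that("transition schedules are row-stochastic with an absorbing death state", {
  spec <- npc_model_spec()
  cfg <- spec$config
  for (arm in c("GP", "TPF")) {
    for (method in c("independent", "hazard_partition")) {
      sch <- build_transition_schedule(arm_survival(spec, arm, "dfs"),
                                       arm_survival(spec, arm, "os"),
                                       cfg, method = method)
      for (M in schedule_matrices(sch)[c(1, 50, 173)]) {
        expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
        expect_true(all(M >= 0 & M <= 1))
        expect_identical(M["dead", ], c(dfs = 0, pd = 0, dead = 1))
      }
    }
  }
})

test_that("identical DFS and OS curves route nobody to PD under hazard partition", {
  m <- toy_exponential(0.01, unit = "cycles")
  cfg <- model_config()
  sch <- build_transition_schedule(m, m, cfg, method = "hazard_partition")
  expect_true(all(sch$dfs_pd == 0))
})

test_that("a zero-hazard OS curve produces no deaths", {
  cfg <- model_config()
  dfs <- toy_weibull(0.002, 1.3, unit = "cycles")
  os <- parametric_survival("exponential", 1e-300, time_unit = "cycles")
  for (method in c("independent", "hazard_partition")) {
    sch <- build_transition_schedule(dfs, os, cfg, method = method)
    expect_true(all(sch$dfs_death == 0))
    trace <- run_cohort(sch, cfg)
    expect_true(all(trace$dead == 0))
  }
})

test_that("cumulative cohort deaths track the overall-survival curve", {
  spec <- npc_model_spec()
  cfg <- spec$config
  u <- cfg$cycle_length_days / 21  # curves are parameterised per cycle
  for (arm in c("GP", "TPF")) {
    os <- arm_survival(spec, arm, "os")
    target <- 1 - survival_at(os, (1:n_cycles(cfg)) * u)
    sch_i <- build_transition_schedule(arm_survival(spec, arm, "dfs"), os, cfg)
    dead_i <- run_cohort(sch_i, cfg)$dead[-1]
    expect_lt(max(abs(dead_i - target)), 1e-12)
    # the calibrated partition scheme recovers the target after the initial
    # transient in which no PD mass exists yet
    sch_h <- build_transition_schedule(arm_survival(spec, arm, "dfs"), os, cfg,
                                       method = "hazard_partition")
    dead_h <- run_cohort(sch_h, cfg)$dead[-1]
    expect_lt(max(abs(dead_h - target)[20:n_cycles(cfg)]), 1e-6)
  }
})

test_that("cohort propagation preserves mass and keeps death monotone", {
  spec <- npc_model_spec()
  for (arm in c("GP", "TPF")) {
    tr <- run_cohort(build_transition_schedule(arm_survival(spec, arm, "dfs"),
                                               arm_survival(spec, arm, "os"),
                                               spec$config), spec$config)
    expect_lt(max(abs(tr$dfs + tr$pd + tr$dead - 1)), 1e-12)
    expect_true(all(diff(tr$dead) >= -1e-15))
    expect_true(all(tr$dfs >= 0 & tr$pd >= 0))
  }
})

test_that("degenerate schedules behave as fixed points", {
  cfg <- model_config(cycle_length_days = 365.25, horizon_years = 3)
  eye <- diag(3)
  trace <- run_cohort(rep(list(eye), 3), cfg, start = c(0.5, 0.3, 0.2))
  expect_true(all(trace$dfs == 0.5 & trace$pd == 0.3 & trace$dead == 0.2))
  # death is absorbing whatever the schedule says about other states
  spec <- npc_model_spec()
  sch <- build_transition_schedule(arm_survival(spec, "GP", "dfs"),
                                   arm_survival(spec, "GP", "os"), spec$config)
  tr <- run_cohort(sch, spec$config, start = c(0, 0, 1))
  expect_true(all(tr$dead == 1))
  expect_error(run_cohort(rep(list(eye), 2), cfg), "horizon")
})

test_that("constant per-cycle death probability gives the geometric closed form", {
  p <- 0.02
  K <- 40
  cfg <- model_config(cycle_length_days = 21,
                      horizon_years = K * 21 / 365.25 + 1e-9, annual_discount = 0.03)
  expect_identical(n_cycles(cfg), as.integer(K))
  sch <- structure(data.frame(cycle = 1:K, dfs_dfs = 1 - p, dfs_pd = 0,
                              dfs_death = p, pd_pd = 1 - p, pd_death = p),
                   class = c("transition_schedule", "data.frame"))
  trace <- run_cohort(sch, cfg)
  expect_equal(trace$dfs[-1], (1 - p)^(1:K), tolerance = 1e-12)
  cyc_years <- 21 / 365.25
  ly <- discounted_accrual(trace, list(dfs = rep(cyc_years, K), pd = rep(0, K)), cfg)
  v <- 1.03^(-cyc_years)
  r <- v * (1 - p)
  expect_equal(ly$total, cyc_years * r * (1 - r^K) / (1 - r), tolerance = 1e-10)
})

test_that("reward accrual respects discounting conventions and decomposition", {
  K <- 10
  cfg0 <- model_config(cycle_length_days = 36.525, horizon_years = 1,
                       annual_discount = 0)
  expect_identical(n_cycles(cfg0), 10L)
  alive <- make_trace(data.frame(cycle = 0:K, dfs = 1, pd = 0, dead = 0))
  cyc_years <- 36.525 / 365.25
  ly <- discounted_accrual(alive, list(dfs = rep(cyc_years, K), pd = rep(0, K)), cfg0)
  expect_equal(ly$total, K * cyc_years, tolerance = 1e-12)

  # utility-weighted accrual equals the definition applied by hand
  cfg <- model_config(cycle_length_days = 36.525, horizon_years = 1,
                      annual_discount = 0.03)
  tr <- make_trace(data.frame(cycle = 0:K, dfs = seq(1, 0.5, length.out = K + 1),
                              pd = seq(0, 0.3, length.out = K + 1)))
  tr$dead <- 1 - tr$dfs - tr$pd
  q <- discounted_accrual(tr, list(dfs = rep(0.76 * cyc_years, K),
                                   pd = rep(0.57 * cyc_years, K)), cfg)
  v <- 1.03^(-(1:K) * 36.525 / 365.25)
  expect_equal(q$total,
               0.76 * sum(v * tr$dfs[-1]) * cyc_years +
                 0.57 * sum(v * tr$pd[-1]) * cyc_years,
               tolerance = 1e-12)
  expect_equal(q$total, q$dfs + q$pd, tolerance = 1e-12)
  expect_error(discounted_accrual(tr, list(dfs = rep(1, 3), pd = rep(1, 3)), cfg),
               "one value per cycle")
})

test_that("discounted totals do not increase with the discount rate", {
  spec <- npc_model_spec()
  totals <- vapply(c(0, 0.03, 0.08), function(r) {
    s <- spec
    s$config$annual_discount <- r
    s$shared$discount$mean <- r
    run_arm(s, "GP")$total_cost
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("quality adjustment can only lose life-years", {
  spec <- npc_model_spec()
  for (arm in c("GP", "TPF")) {
    r <- run_arm(spec, arm)
    expect_lte(r$total_qaly, r$total_ly)
    expect_true(all(r$by_state$qaly <= r$by_state$ly))
  }
})
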