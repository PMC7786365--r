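test_that("expected adverse-event cost is the probability-weighted sum", {
  mk <- function(p12, c12, pl, pn, c34)
    list(g12_cost = c12, g34_cost = c34, p_g12 = p12,
         p_leucopenia_g34 = pl, p_neutropenia_g34 = pn)
  expect_identical(expected_ae_cost(mk(0, 100, 0, 0, 500)), 0)
  expect_equal(expected_ae_cost(mk(0, 0, 0.3448, 0, 655.52)), 0.3448 * 655.52)
  # linearity over classes
  expect_equal(expected_ae_cost(mk(0.5, 372.42, 0.1408, 0.1408, 655.52)),
               0.5 * 372.42 + (0.1408 + 0.1408) * 655.52)
})

test_that("periodic costs convert to cycle costs pro rata", {
  expect_equal(period_to_cycle_cost(631.10, 90, 21), 147.26, tolerance = 1e-4)
  expect_identical(period_to_cycle_cost(88, 30, 30), 88)
  expect_identical(period_to_cycle_cost(0, 90, 21), 0)
  expect_error(period_to_cycle_cost(10, 0, 21), "positive")
  expect_error(period_to_cycle_cost(10, 7, 21), "at least one cycle")
})

test_that("progressed-disease cost mixes subsequent therapy with supportive care", {
  spec <- npc_model_spec()
  costs_gp <- build_cycle_costs(spec, "GP")
  costs_tpf <- build_cycle_costs(spec, "TPF")
  expect_equal(costs_gp$pd[1], 0.75 * 541.36 + 0.25 * 52.53, tolerance = 1e-9)
  expect_equal(costs_gp$pd[1], 419.15, tolerance = 1e-2)
  expect_equal(costs_tpf$pd[1], 0.682 * 524.08 + 0.318 * 52.53, tolerance = 1e-9)
  # convex combination bounds, every cycle
  for (cc in list(costs_gp$pd, costs_tpf$pd)) {
    expect_true(all(cc >= 52.53 & cc <= 541.36))
    expect_identical(length(unique(cc)), 1L)
  }
})

test_that("cost streams land on the scheduled cycles", {
  spec <- npc_model_spec()
  costs <- build_cycle_costs(spec, "GP")
  K <- n_cycles(spec$config)
  # cycles 1-3: induction items; cycle 1 additionally PICC + expected AE cost
  ind <- sum(vapply(spec$arms$GP$induction, function(p) p$mean, numeric(1)))
  expect_equal(costs$dfs[2], ind, tolerance = 1e-9)
  expect_equal(costs$dfs[3], ind, tolerance = 1e-9)
  expect_equal(sum(costs$dfs[1:3]),
               3 * ind + 235.74 + expected_ae_cost(spec$arms$GP$ae),
               tolerance = 1e-9)
  # CCRT block: radiotherapy + concurrent cisplatin each cycle, one-times at 4
  rt <- spec$shared$ccrt$radiotherapy$mean + spec$shared$ccrt$cisplatin$mean
  expect_equal(costs$dfs[5], rt, tolerance = 1e-9)
  expect_equal(costs$dfs[4], rt + 1066.24 + 201.50, tolerance = 1e-9)
  # follow-up bands by end-of-cycle time; a cycle in year 7 costs 40.79
  k_year7 <- ceiling(6.5 * 365.25 / 21)
  expect_equal(costs$dfs[k_year7], 40.79, tolerance = 1e-9)
  expect_equal(costs$dfs[10], 147.26, tolerance = 1e-9)
  expect_equal(costs$dfs[60], 81.58, tolerance = 1e-9)
  expect_identical(length(costs$dfs), K)
})

test_that("zeroing every cost item yields zero cost vectors", {
  spec <- zero_cost_spec()
  for (arm in c("GP", "TPF")) {
    costs <- build_cycle_costs(spec, arm)
    expect_true(all(costs$dfs == 0))
    expect_true(all(costs$pd == 0))
  }
})

test_that("whole-vial pricing is never below exact-dose pricing", {
  spec <- npc_model_spec()
  for (arm in c("GP", "TPF")) {
    vial <- drug_cost_per_cycle(spec$doses[[arm]], spec$vial_catalogue,
                                spec$bsa_m2, "vial_based")
    exact <- drug_cost_per_cycle(spec$doses[[arm]], spec$vial_catalogue,
                                 spec$bsa_m2, "exact_dose")
    expect_true(all(vial >= exact))
  }
  # calibration: vial-based pricing reproduces the per-cycle acquisition costs
  vial_gp <- drug_cost_per_cycle(spec$doses$GP, spec$vial_catalogue, spec$bsa_m2)
  expect_equal(unname(vial_gp["gemcitabine"]), 559.26, tolerance = 1e-9)
  expect_equal(unname(vial_gp["cisplatin"]), 13.47, tolerance = 1e-9)
  vial_tpf <- drug_cost_per_cycle(spec$doses$TPF, spec$vial_catalogue, spec$bsa_m2)
  expect_equal(unname(vial_tpf["docetaxel"]), 764.46, tolerance = 1e-9)
  expect_equal(unname(vial_tpf["fluorouracil"]), 148.40, tolerance = 1e-9)
})

test_that("vial arithmetic rounds each administration up to whole vials", {
  catalogue <- list(drug = list(vial_sizes_mg = 20, price_per_mg = 2))
  rules <- list(drug = list(mg_per_m2 = 24, n_admin = 1))  # 1.2 vials at BSA 1
  expect_equal(drug_cost_per_cycle(rules, catalogue, 1, "vial_based")[["drug"]],
               40 * 2)
  expect_equal(drug_cost_per_cycle(rules, catalogue, 1, "exact_dose")[["drug"]],
               24 * 2)
  # an exact multiple of the vial size prices identically in both modes
  rules$drug$mg_per_m2 <- 40
  expect_identical(drug_cost_per_cycle(rules, catalogue, 1, "vial_based"),
                   drug_cost_per_cycle(rules, catalogue, 1, "exact_dose"))
  expect_error(drug_cost_per_cycle(rules, list(drug = list(vial_sizes_mg = numeric(0))),
                                   1, "vial_based"), "no vials")
})

test_that("missing mandatory arm items raise a configuration error naming them", {
  spec <- npc_model_spec()
  spec$arms$GP$induction$hospitalization <- NULL
  expect_error(build_cycle_costs(spec, "GP"), "hospitalization")
  expect_error(build_cycle_costs(npc_model_spec(), "XYZ"), "unknown arm")
})
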