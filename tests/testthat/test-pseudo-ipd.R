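test_that("reconstruction is exact when nobody is censored", {
  # 100 at risk, survival drops to 0.90 in one interval, none lost to follow-up
  curve <- digitized_curve(time = c(6, 12), survival = c(0.90, 0.90),
                           at_risk = data.frame(time = c(0, 12),
                                                n_at_risk = c(100, 90)))
  ipd <- reconstruct_pseudo_ipd(curve, c(0, 12))
  inside <- ipd$time < 12
  expect_identical(sum(ipd$event[inside]), 10L)
  expect_identical(sum(inside), 10L)           # exactly the 10 events
  expect_identical(sum(ipd$event == 0), 90L)   # survivors censored at the end
})

test_that("empty intervals contribute no records", {
  curve <- digitized_curve(time = c(5), survival = c(0.8),
                           at_risk = data.frame(time = c(0, 10, 20),
                                                n_at_risk = c(50, 40, 40)))
  ipd <- reconstruct_pseudo_ipd(curve, c(0, 10, 20))
  expect_identical(sum(ipd$time > 10 & ipd$time < 20), 0L)
})

test_that("inconsistent curves are rejected with the offending interval named", {
  rising <- digitized_curve(time = c(3, 9), survival = c(0.7, 0.7),
                            at_risk = data.frame(time = c(0, 6, 12),
                                                 n_at_risk = c(50, 30, 35)))
  expect_error(reconstruct_pseudo_ipd(rising, c(0, 6, 12)), "at-risk count increases")
  # survival cannot rise within an interval either
  pts <- data.frame(time = c(3, 9), survival = c(0.6, 0.9))
  bad <- structure(list(label = "", points = pts,
                        at_risk = data.frame(time = c(0, 6, 12),
                                             n_at_risk = c(50, 30, 20))),
                   class = "digitized_curve")
  expect_error(reconstruct_pseudo_ipd(bad, c(0, 6, 12)), "survival increases")
})

test_that("KM recomputed from reconstructed records matches the curve at boundaries", {
  m <- toy_weibull(0.003, 1.2, unit = "months")
  ipd <- simulate_ipd(m, 150, censoring = "uniform", cens_time = 80, seed = 11)
  bounds <- seq(0, 60, by = 12)
  curve <- km_estimate(ipd, at_risk_times = bounds)
  rec <- reconstruct_pseudo_ipd(curve, bounds)
  km_rec <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
  s_rec <- summary(km_rec, times = bounds, extend = TRUE)$surv
  s_orig <- summary(survival::survfit(survival::Surv(time, event) ~ 1, data = ipd),
                    times = bounds, extend = TRUE)$surv
  expect_lt(max(abs(s_rec - s_orig)), 0.02)
})

test_that("round-trip reconstruction refits to parameters consistent with the direct fit", {
  m <- toy_weibull(0.00059, 1.48831, unit = "cycles")
  ipd <- simulate_ipd(m, 150, censoring = "administrative", cens_time = 166,
                      seed = 404)
  direct <- fit_parametric(ipd, "weibull")
  bounds <- seq(0, 160, by = 20)
  rec <- reconstruct_pseudo_ipd(km_estimate(ipd, bounds), bounds)
  refit <- fit_parametric(rec, "weibull")
  expect_lt(abs(refit$model$scale - direct$model$scale), 2 * direct$scale_se)
  expect_lt(abs(refit$model$shape - direct$model$shape), 2 * direct$shape_se)
  # and still consistent with the generating truth
  expect_lt(abs(refit$model$scale - 0.00059), 2 * refit$scale_se)
  expect_lt(abs(refit$model$shape - 1.48831), 2 * refit$shape_se)
})

test_that("pseudo-IPD and digitized curves round-trip through CSV", {
  dir <- withr::local_tempdir()
  ipd <- simulate_ipd(toy_exponential(0.01), 40, seed = 3)
  p <- file.path(dir, "ipd.csv")
  write_pseudo_ipd(ipd, p)
  expect_equal(as.data.frame(read_pseudo_ipd(p)), as.data.frame(ipd))
  curve <- km_estimate(ipd, at_risk_times = c(0, 50, 100))
  cp <- file.path(dir, "curve.csv")
  write_digitized_curve(curve, cp)
  back <- read_digitized_curve(cp)
  expect_equal(back$points, curve$points)
  expect_equal(back$at_risk$n_at_risk, curve$at_risk$n_at_risk)
})
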