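test_that("counterfactual reconstruction follows the stated arithmetic", {
  rec <- data.frame(patient_id = "c1", arm = "control", pfs_time = 6,
                    pfs_event = 1L, os_time = 12, os_event = 1L,
                    switched = 1L, switch_time = 6)
  adj <- counterfactual_times(rec, accel_factor = 2, recensor = FALSE)
  expect_equal(adj$os_time, 9)          # 6 + (12 - 6) / 2
  ident <- counterfactual_times(rec, accel_factor = 1, recensor = FALSE)
  expect_equal(ident$os_time, 12)
  bad <- rec; bad$switch_time <- 13
  expect_error(counterfactual_times(bad, 2, recensor = FALSE), "exceeds")
  expect_error(counterfactual_times(rec, 0, recensor = FALSE), "> 0")
})

test_that("counterfactual times are monotone in the acceleration factor and recensoring truncates", {
  ipd <- base_ipd()
  a2 <- counterfactual_times(ipd, 2, recensor = FALSE)
  a3 <- counterfactual_times(ipd, 3, recensor = FALSE)
  sw <- ipd$switched == 1
  expect_true(all(a3$os_time[sw] <= a2$os_time[sw]))
  expect_true(all(a2$os_time[!sw] == ipd$os_time[!sw]))
  r <- counterfactual_times(ipd, 2, recensor = TRUE, censor_time = 26)
  ctl <- r$arm == "control"
  expect_true(all(r$os_time[ctl] <= 13 + 1e-12))
  expect_true(all(r$os_event[ctl & r$os_time >= 13 - 1e-12] == 0))
})

test_that("a noise-free doubling of switcher survival yields an acceleration factor of 2", {
  set.seed(77)
  n <- 60
  base_t <- rweibull(n, 1.4, 10)
  rec <- data.frame(
    patient_id = paste0("p", 1:(2 * n)), arm = "control",
    age = 60, male = 1, brain_met = 0, stage_iv = 1, smoker = 1, ecog1 = 1,
    pfs_time = 5, pfs_event = 1L,
    os_time = 5 + c(base_t, 2 * base_t), os_event = 1L,
    switched = rep(c(0L, 1L), each = n),
    switch_time = c(rep(NA, n), rep(5, n)))
  af <- estimate_accel_factor(rec)
  expect_equal(af$accel_factor, 2, tolerance = 1e-4)
})

test_that("the acceleration-factor estimate recovers the generator and covers the null", {
  # null effect: CI covers 1
  sc0 <- trial_scenario(n_per_arm = 1500, crossover_prob = 0.5,
                        crossover_accel = 1, seed = 31)
  af0 <- estimate_accel_factor(simulate_trial(sc0))
  expect_true(af0$ci[1] <= 1 && 1 <= af0$ci[2])
  # recovery within 10% when the AFT family matches the generator
  sc <- trial_scenario(
    n_per_arm = 2000, crossover_prob = 0.5, crossover_accel = 1.5,
    pps = list(active = list(family = "weibull", shape = 1.3, scale = 12),
               control = list(family = "weibull", shape = 1.3, scale = 10)),
    seed = 19)
  af <- estimate_accel_factor(simulate_trial(sc))
  expect_equal(af$accel_factor, 1.5, tolerance = 0.1)
})

test_that("no common support errors when all or none of the progressors switch", {
  ipd <- simulate_trial(trial_scenario(n_per_arm = 100, crossover_prob = 0,
                                       seed = 3))
  expect_error(estimate_accel_factor(ipd), "common support")
})

test_that("Cox HR matches the exponential closed form and is weight-scale invariant", {
  ipd <- base_ipd()
  h1 <- cox_hr(ipd, "os")
  h2 <- cox_hr(ipd, "os", weights = rep(2, nrow(ipd)))
  expect_equal(h1$hr, h2$hr, tolerance = 1e-8)
  # identical arms: HR exactly 1
  tt <- ipd$os_time[ipd$arm == "active"]
  ee <- ipd$os_event[ipd$arm == "active"]
  same <- data.frame(patient_id = paste0("s", seq_len(2 * length(tt))),
                     arm = rep(c("active", "control"), each = length(tt)),
                     os_time = c(tt, tt), os_event = c(ee, ee))
  expect_equal(cox_hr(same, "os")$hr, 1, tolerance = 1e-6)
  # exponential arms with rates 0.2 vs 0.4: HR = 0.5
  set.seed(55)
  n <- 5000
  exp_ipd <- data.frame(
    patient_id = paste0("x", 1:(2 * n)),
    arm = rep(c("active", "control"), each = n),
    os_time = c(rexp(n, 0.2), rexp(n, 0.4)), os_event = 1L)
  expect_equal(cox_hr(exp_ipd, "os")$hr, 0.5, tolerance = 0.025)
})

test_that("two-stage adjustment moves the ITT OS hazard ratio away from 1, toward the truth", {
  sc <- trial_scenario(n_per_arm = 2000, crossover_prob = 0.6,
                       crossover_accel = 1.8, seed = 47)
  ipd <- simulate_trial(sc)
  sc0 <- sc; sc0$crossover_prob <- 0
  truth <- cox_hr(simulate_trial(sc0), "os")$hr
  ts <- two_stage_adjust(ipd, censor_time = sc$censor_time)
  expect_lt(truth, 1)
  expect_lt(ts$hr_adjusted, ts$hr_unadjusted)  # dilution removed
  expect_lt(abs(log(ts$hr_adjusted) - log(truth)),
            abs(log(ts$hr_unadjusted) - log(truth)))
  expect_gt(ts$n_switchers, 0)
  expect_output(print(ts), "acceleration factor")
})
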