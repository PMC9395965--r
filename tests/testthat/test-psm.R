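test_that("trace occupancy conserves mass and the dead state is absorbing", {
  set.seed(12)
  for (r in 1:20) {
    pfs <- mock_fit("lognormal", c(meanlog = runif(1, 1, 2.5),
                                   sdlog = runif(1, 0.4, 1.2)))
    os <- mock_fit("lognormal", c(meanlog = runif(1, 2, 3.5),
                                  sdlog = runif(1, 0.4, 1.2)))
    tr <- build_trace(pfs, os, horizon_years = 15)
    expect_equal(tr$occ_pf + tr$occ_pp + tr$occ_dead, rep(1, nrow(tr)))
    expect_true(all(tr$occ_pf >= 0) && all(tr$occ_pp >= 0))
    expect_true(all(diff(tr$occ_dead) >= -1e-12))
    expect_true(all(tr$s_pfs <= tr$s_os))
  }
})

test_that("degenerate traces behave: no progression, no death", {
  f <- mock_fit("exponential", c(rate = 0.1))
  tr <- build_trace(f, f, horizon_years = 5)
  expect_true(all(tr$occ_pp == 0))          # PFS = OS: nobody in PP
  alive <- mock_fit("exponential", c(rate = 1e-12))
  tr2 <- build_trace(alive, alive, horizon_years = 5, annual_rate = 0)
  expect_true(all(tr2$occ_dead < 1e-9))
  q <- accrue_qalys(tr2, 1, 1)
  expect_equal(q$ly_undisc, 5, tolerance = 0.01)  # LY = horizon
  expect_equal(q$qaly_total, q$ly)                # unit utility
})

test_that("undiscounted life-years match the closed-form exponential integral", {
  pfs <- mock_fit("exponential", c(rate = 0.2))
  os <- mock_fit("exponential", c(rate = 0.1))
  tr <- build_trace(pfs, os, horizon_years = 10, annual_rate = 0)
  q <- accrue_qalys(tr, 1, 1, half_cycle = TRUE)   # trapezoid accrual
  ly_months <- (1 / 0.1) * (1 - exp(-0.1 * 120))
  expect_equal(q$ly_undisc, ly_months / 12, tolerance = 0.005)
})

test_that("discounting follows the continuous-time convention", {
  expect_equal(discount_factor(0), 1)
  expect_equal(discount_factor(10, annual_rate = 0), 1)
  expect_equal(discount_factor(365.25 / 21, annual_rate = 0.05), 1 / 1.05)
  expect_error(discount_factor(3, annual_rate = -0.1), ">= 0")
})

test_that("an immediately dying cohort accrues only AE and end-of-life costs", {
  dead <- mock_fit("exponential", c(rate = 1e6))
  tr <- build_trace(dead, dead, horizon_years = 2)
  pv <- param_values(load_parameters())
  costs <- accrue_costs(tr, default_regimens()$active, pv)
  ae <- sum(pv["inc_active_neutropenia"] * pv["cost_ae_neutropenia"],
            pv["inc_active_leukopenia"] * pv["cost_ae_leukopenia"],
            pv["inc_active_anemia"] * pv["cost_ae_anemia"],
            pv["inc_active_thrombocytopenia"] * pv["cost_ae_thrombocytopenia"])
  expect_equal(costs$drug, 0)
  expect_equal(costs$ae, unname(ae))
  expect_equal(costs$total, costs$ae + costs$eol, tolerance = 1e-9)
  expect_equal(costs$eol, unname(pv["cost_eol"]) * discount_factor(1),
               tolerance = 1e-6)
})

test_that("cost accrual is monotone in unit prices and respects treatment caps", {
  cfg <- calibrated_config()
  pv <- param_values(cfg$params)
  base <- run_cea(cfg, pv)
  pv2 <- pv; pv2["cost_gemcitabine"] <- pv["cost_gemcitabine"] * 2
  up <- run_cea(cfg, pv2)
  expect_gt(up$active$cost_total, base$active$cost_total)
  expect_equal(up$comp$cost_total, base$comp$cost_total)  # not in comparator regimen
  # a patient-assistance scheme making late cycles free can only lower drug cost
  cfg_free <- cfg
  cfg_free$regimens$active$drugs[[1]]$pap$frac <- 0
  free <- run_cea(cfg_free, pv)
  expect_lt(free$active$cost_components$drug, base$active$cost_components$drug)
  # raising u_pp raises both arms' QALYs
  pv3 <- pv; pv3["u_pp"] <- pv["u_pp"] + 0.05
  more <- run_cea(cfg, pv3)
  expect_gt(more$active$qaly_total, base$active$qaly_total)
  expect_gt(more$comp$qaly_total, base$comp$qaly_total)
})

test_that("QALYs never exceed life-years and AE losses are linear in incidence", {
  cfg <- calibrated_config()
  res <- run_cea(cfg)
  expect_lte(res$active$qaly_total, res$active$ly)
  expect_lte(res$comp$qaly_total, res$comp$ly)
  expect_equal(res$active$qaly_total,
               res$active$qaly_pf + res$active$qaly_pp)
  pv <- param_values(cfg$params)
  l1 <- ae_qaly_loss(pv, "inc_active_")
  pv2 <- pv
  for (a in c("neutropenia", "leukopenia", "anemia", "thrombocytopenia"))
    pv2[paste0("inc_active_", a)] <- 2 * pv[paste0("inc_active_", a)]
  expect_equal(ae_qaly_loss(pv2, "inc_active_"), 2 * l1)
  # the comparator-arm anemia term alone: incidence x disutility x duration
  anemia <- 0.158 * 0.07 * (6.83 / 365.25)
  expect_equal(unname(pv["inc_comp_anemia"] * pv["disu_anemia"] *
                        pv["dur_anemia"] / 365.25), anemia)
})

test_that("incremental summary labels dominance and quadrants correctly", {
  mk <- function(cost, qaly, ly = NA) list(cost_total = cost,
                                           qaly_total = qaly, ly = ly)
  sw <- incremental_summary(mk(12321, 0.9902), mk(36371, 1.0085))
  expect_equal(sw$d_cost, -24050)
  expect_equal(sw$d_qaly, -0.0183)
  expect_equal(sw$quadrant, "southwest")
  dom <- incremental_summary(mk(12321, 1.2319), mk(36371, 1.1815))
  expect_equal(dom$label, "dominant")
  expect_true(is.na(dom$icer))
  dominated <- incremental_summary(mk(100, 1), mk(50, 2))
  expect_equal(dominated$label, "dominated")
  same <- incremental_summary(mk(10, 1), mk(10, 1))
  expect_equal(same$label, "undefined ICER")
  expect_equal(unname(same$nmb), c(0, 0))
  ne <- incremental_summary(mk(200, 2), mk(100, 1), wtp = 150)
  expect_equal(ne$icer, 100)
  expect_equal(ne$quadrant, "northeast")
  expect_equal(unname(ne$nmb), 150 * 1 - 100)
})

test_that("southwest decision rule holds across the WTP band for the base-case increments", {
  inc <- incremental_summary(list(cost_total = 12321, qaly_total = 0.9902),
                             list(cost_total = 36371, qaly_total = 1.0085),
                             wtp = c(11250, 33749))
  # cheaper-but-slightly-less-effective is preferred iff ICER > WTP
  expect_gt(inc$icer, 33749)
  expect_true(all(inc$nmb > 0))
})

test_that("half-cycle correction and vial rounding change results in the expected direction", {
  cfg <- calibrated_config()
  base <- run_cea(cfg)
  cfg_hc <- cfg; cfg_hc$half_cycle <- TRUE
  hc <- run_cea(cfg_hc)
  # trapezoid occupancy >= end-of-cycle occupancy for non-increasing curves
  expect_gt(hc$active$ly, base$active$ly)
  cfg_nv <- cfg; cfg_nv$vial_round <- FALSE
  nv <- run_cea(cfg_nv)
  expect_lte(nv$active$cost_components$drug, base$active$cost_components$drug)
})
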