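test_that("exponential MLE matches the closed form d / sum(t)", {
  f <- fit_parametric(c(2, 4, 6), c(1, 1, 1), "exponential")
  expect_equal(unname(coef(f)["rate"]), 0.25, tolerance = 1e-6)
  expect_equal(f$aic, 2 * 1 - 2 * f$loglik)
  expect_equal(f$bic, log(3) - 2 * f$loglik)
})

test_that("weibull likelihood evaluated at shape 1 recovers the exponential fit", {
  set.seed(8)
  tt <- rexp(200, 0.2)
  ev <- as.integer(tt < 12); tt <- pmin(tt, 12)
  fe <- fit_parametric(tt, ev, "exponential")
  # nested-model identity: weibull(shape = 1, scale = 1/rate) has the same
  # log-likelihood as the exponential MLE
  ll_weib <- sum(ev * stats::dweibull(tt, 1, 1 / coef(fe)["rate"], log = TRUE) +
                   (1 - ev) * stats::pweibull(tt, 1, 1 / coef(fe)["rate"],
                                              lower.tail = FALSE, log.p = TRUE))
  expect_equal(ll_weib, fe$loglik, tolerance = 1e-8)
  fw <- fit_parametric(tt, ev, "weibull")
  expect_gte(fw$loglik, fe$loglik - 1e-8)
})

test_that("log-normal fit agrees with a grid-search likelihood oracle", {
  set.seed(15)
  n <- 500
  tt <- rlnorm(n, 1.7, 0.8)
  cens <- quantile(tt, 0.8)
  ev <- as.integer(tt <= cens); time <- pmin(tt, cens)
  f <- fit_parametric(time, ev, "lognormal")
  se <- f$vcov  # estimation scale; meanlog untransformed, sdlog on log scale
  expect_equal(unname(coef(f)["meanlog"]), 1.7,
               tolerance = 3 * sqrt(se[1, 1]) / 1.7)
  # brute-force grid over (meanlog, sdlog)
  grid <- expand.grid(m = seq(1.4, 2.0, by = 0.005),
                      s = seq(0.6, 1.0, by = 0.005))
  ll <- mapply(function(m, s) lnorm_cens_loglik(time, ev, m, s),
               grid$m, grid$s)
  best <- grid[which.max(ll), ]
  expect_gte(f$loglik, max(ll) - 1e-6)   # MLE attains at least the grid max
  expect_equal(unname(coef(f)["meanlog"]), best$m, tolerance = 0.01)
  expect_equal(unname(coef(f)["sdlog"]), best$s, tolerance = 0.01)
})

test_that("each family recovers its generating parameters within 3 SE at n = 1000", {
  gen <- list(exponential = c(rate = 0.1),
              weibull = c(shape = 1.3, scale = 12),
              lognormal = c(meanlog = 2, sdlog = 0.7),
              loglogistic = c(shape = 1.6, scale = 10),
              gompertz = c(shape = 0.05, rate = 0.05),
              gengamma = c(mu = 2, sigma = 0.7, Q = 0.8))
  set.seed(33)
  for (fam in names(gen)) {
    d <- as.list(gen[[fam]]); d$family <- fam
    tt <- psmcea:::r_family(1000, d)
    cens <- runif(1000, 0, 3 * quantile(tt, 0.9))
    f <- fit_parametric(pmin(tt, cens), as.integer(tt <= cens), fam)
    # compare on the estimation scale, where the SEs live
    tr <- f$transforms
    truth_t <- vapply(seq_along(d)[-length(d)],
                      function(j) tr[[j]](gen[[fam]][j]), numeric(1))
    z <- abs(f$params_t - truth_t) / sqrt(diag(f$vcov))
    expect_true(all(z < 3), info = fam)
  }
})

test_that("fit errors are informative", {
  expect_error(fit_parametric(c(1, 2, 3), c(0, 0, 0), "weibull"), "2 observed events")
  expect_error(fit_parametric(c(0, 2), c(1, 1), "weibull"), "> 0")
  expect_error(fit_parametric(c(1, 2), c(1, 1), "gamma"), "unknown")
})

test_that("rank_fits orders by AIC and refuses mismatched data", {
  set.seed(4)
  tt <- rexp(800, 0.15)
  fits <- lapply(c("exponential", "weibull", "gengamma"),
                 function(f) fit_parametric(tt, rep(1L, 800), f))
  tab <- rank_fits(fits)
  expect_equal(nrow(tab), 3)
  expect_true(!is.unsorted(tab$aic))
  # penalty dominates equal fit on truly exponential data
  expect_lt(tab$bic[tab$family == "exponential"],
            tab$bic[tab$family == "gengamma"])
  one <- rank_fits(fits[[1]])
  expect_equal(one$family, "exponential")
  other <- fit_parametric(rexp(100, 1), rep(1L, 100), "weibull")
  expect_error(rank_fits(list(fits[[1]], other)), "same data")
})

test_that("survival evaluation honors the family medians and domain", {
  fe <- mock_fit("exponential", c(rate = 0.25))
  expect_equal(surv_prob(fe, 0), 1)
  expect_equal(surv_prob(fe, log(2) / 0.25), 0.5)
  fl <- mock_fit("lognormal", c(meanlog = 1.3, sdlog = 0.6))
  expect_equal(surv_prob(fl, exp(1.3)), 0.5)
  expect_error(surv_prob(fe, -1), ">= 0")
  # S is non-increasing and heads to 0 for every family
  gens <- list(exponential = c(rate = 0.1), weibull = c(shape = 1.3, scale = 12),
               lognormal = c(meanlog = 2, sdlog = 0.7),
               loglogistic = c(shape = 1.6, scale = 10),
               gompertz = c(shape = 0.05, rate = 0.05),
               gengamma = c(mu = 2, sigma = 0.7, Q = 0.8))
  for (fam in names(gens)) {
    f <- mock_fit(fam, gens[[fam]])
    s <- surv_prob(f, seq(0, 500, by = 2.5))
    expect_true(all(diff(s) <= 1e-12), info = fam)
    expect_lt(s[length(s)], 0.02)
  }
})

test_that("survival equals exp(-integrated hazard) for every family", {
  gens <- list(exponential = c(rate = 0.1), weibull = c(shape = 1.3, scale = 12),
               lognormal = c(meanlog = 2, sdlog = 0.7),
               loglogistic = c(shape = 1.6, scale = 10),
               gompertz = c(shape = 0.05, rate = 0.05),
               gengamma = c(mu = 2, sigma = 0.7, Q = 0.8))
  for (fam in names(gens)) {
    f <- mock_fit(fam, gens[[fam]])
    for (t1 in c(3, 11, 40)) {
      H <- stats::integrate(function(u) haz_rate(f, u), 0, t1,
                            rel.tol = 1e-10)$value
      expect_equal(exp(-H), surv_prob(f, t1), tolerance = 1e-6,
                   info = paste(fam, t1))
    }
  }
})

test_that("hazard-ratio transformation scales hazards and powers survival", {
  f <- mock_fit("exponential", c(rate = 0.2))
  hc <- apply_hr(f, 2)
  tt <- c(0.5, 2, 7)
  expect_equal(surv_prob(hc, tt), surv_prob(f, tt)^2)
  expect_equal(haz_rate(hc, tt), 2 * haz_rate(f, tt))
  # exponential PH closed form: doubling the hazard doubles the rate
  expect_equal(surv_prob(hc, tt),
               surv_prob(mock_fit("exponential", c(rate = 0.4)), tt))
  expect_error(apply_hr(f, -1), "positive")
})

test_that("Cholesky parameter sampling reproduces the fit covariance", {
  f <- base_fits()$pfs
  d1 <- sample_parameters(f, 5, seed = 99)
  d2 <- sample_parameters(f, 5, seed = 99)
  expect_identical(d1, d2)              # determinism under a fixed seed
  d <- sample_parameters(f, 100000, seed = 1)
  # back to the estimation scale: meanlog identity, sdlog log
  dt <- cbind(d[, "meanlog"], log(d[, "sdlog"]))
  emp <- stats::cov(dt)
  expect_equal(unname(diag(emp)), unname(diag(f$vcov)), tolerance = 0.05)
  expect_equal(emp[1, 2], f$vcov[1, 2], tolerance = 0.05 * sqrt(prod(diag(f$vcov))))
  # zero covariance collapses to the point estimate
  f0 <- mock_fit("lognormal", c(meanlog = 1, sdlog = 0.5))
  dz <- sample_parameters(f0, 10, seed = 2)
  expect_true(all(dz[, 1] == 1) && all(dz[, 2] == 0.5))
  # an indefinite covariance surfaces as a decomposition error
  fbad <- f
  fbad$vcov <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sample_parameters(fbad, 5), "Cholesky")
})

test_that("fits round-trip through the text serialization", {
  f <- base_fits()$os
  path <- withr::local_tempfile(fileext = ".txt")
  write_parsurv(f, path)
  g <- read_parsurv(path)
  expect_equal(g$params, f$params)
  expect_equal(g$vcov, f$vcov)
  expect_equal(g$bic, f$bic)
  expect_equal(surv_prob(g, c(1, 10)), surv_prob(f, c(1, 10)))
  expect_equal(sample_parameters(g, 3, seed = 1),
               sample_parameters(f, 3, seed = 1))
})
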