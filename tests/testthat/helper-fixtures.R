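# shared fixtures, computed once per test run and memoised

.fixtures <- new.env()

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE))
    assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures, inherits = FALSE)
}

# reference two-arm trial at the default (published baseline) conditions
base_ipd <- function() memo("base_ipd", {
  simulate_trial(trial_scenario(n_per_arm = 1000, seed = 7))
})

# log-normal extrapolation fits to the active arm of a mid-sized trial
base_fits <- function() memo("base_fits", {
  act <- local({
    ipd <- simulate_trial(trial_scenario(n_per_arm = 400, seed = 42))
    ipd[ipd$arm == "active", ]
  })
  list(pfs = fit_parametric(act$pfs_time, act$pfs_event, "lognormal"),
       os = fit_parametric(act$os_time, act$os_event, "lognormal"))
})

# base case calibrated to the published deterministic increments
calibrated_config <- function() memo("calibrated_config", {
  f <- base_fits()
  calibrate_base_case(f$pfs, f$os)
})

# minimal parametric-curve object for trace tests (no fitting)
mock_fit <- function(family, params, vcov = NULL) {
  k <- length(params)
  if (is.null(vcov)) vcov <- matrix(0, k, k)
  dists <- c(exponential = "exp", weibull = "weibull", lognormal = "lnorm",
             loglogistic = "llogis", gompertz = "gompertz",
             gengamma = "gengamma")
  dl <- flexsurv::flexsurv.dists[[dists[[family]]]]
  tr <- dl$transforms
  params_t <- vapply(seq_len(k), function(j) tr[[j]](params[j]), numeric(1))
  structure(list(family = family, params = params,
                 params_t = stats::setNames(params_t, names(params)),
                 vcov = vcov, loglik = NA_real_, aic = NA_real_,
                 bic = NA_real_, n = 0L, nevent = 0L,
                 transforms = dl$transforms,
                 inv_transforms = dl$inv.transforms,
                 data_checksum = c(n = 0, d = 0, tsum = 0)),
            class = "parsurv")
}

# censored log-normal log-likelihood (independent oracle for fit checks)
lnorm_cens_loglik <- function(time, event, meanlog, sdlog) {
  sum(event * stats::dlnorm(time, meanlog, sdlog, log = TRUE) +
        (1 - event) * stats::plnorm(time, meanlog, sdlog,
                                    lower.tail = FALSE, log.p = TRUE))
}
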