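#' Trial scenario for synthetic IPD generation
#'
#' Describes a two-arm oncology trial with the statistical structure a
#' partitioned survival analysis assumes: independent baseline covariates
#' drawn from marginal prevalences (or mean/sd for age), latent
#' progression-free survival (PFS) drawn from a parametric family per arm,
#' latent overall survival constructed as OS = PFS + an independent
#' post-progression survival (PPS) draw (so PFS <= OS holds structurally),
#' optional control-arm crossover to active therapy at progression, and
#' administrative censoring.  All times are in months.
#'
#' @param n_per_arm patients per arm.
#' @param covariates named list of marginal specifications: scalar prevalence
#'   in \[0,1\] for the binary covariates \code{male}, \code{brain_met},
#'   \code{stage_iv}, \code{smoker}, \code{ecog1}, and \code{list(mean, sd)}
#'   for \code{age} (years).
#' @param pfs,pps per-arm latent distributions: a list with elements
#'   \code{active} and \code{control}, each \code{list(family, ...)} where
#'   \code{family} is one of the six families supported by
#'   \code{\link{fit_parametric}} and \code{...} its natural-scale parameters
#'   (e.g. \code{list(family = "lognormal", meanlog = log(5.5), sdlog = 0.8)}).
#'   \code{pps} is the post-progression survival component; the implied
#'   marginal OS law is the convolution PFS + PPS.
#' @param crossover_prob probability that a progressed control-arm patient
#'   switches onto active therapy at progression.
#' @param crossover_accel acceleration factor (> 0) multiplying the latent
#'   post-progression survival of switchers.
#' @param censor_time administrative censoring time in months.
#' @param seed integer seed used by \code{\link{simulate_trial}}.
#' @return object of class \code{trial_scenario}.
#' @export
trial_scenario <- function(n_per_arm = 180,
                           covariates = default_covariates(),
                           pfs = list(
                             active  = list(family = "lognormal", meanlog = log(5.5), sdlog = 0.8),
                             control = list(family = "lognormal", meanlog = log(4.9), sdlog = 0.8)
                           ),
                           pps = list(
                             active  = list(family = "lognormal", meanlog = log(12), sdlog = 0.9),
                             control = list(family = "lognormal", meanlog = log(10), sdlog = 0.9)
                           ),
                           crossover_prob = 0.45,
                           crossover_accel = 1.5,
                           censor_time = 26,
                           seed = 1L) {
  if (!is.numeric(n_per_arm) || length(n_per_arm) != 1 || n_per_arm < 1)
    stop("n_per_arm must be a positive count", call. = FALSE)
  if (crossover_prob < 0 || crossover_prob > 1)
    stop("crossover_prob must lie in [0, 1]", call. = FALSE)
  if (crossover_accel <= 0)
    stop("crossover_accel must be > 0", call. = FALSE)
  if (censor_time < 0)
    stop("censor_time must be >= 0", call. = FALSE)
  for (nm in c("male", "brain_met", "stage_iv", "smoker", "ecog1")) {
    p <- covariates[[nm]]
    if (is.null(p) || p < 0 || p > 1)
      stop("covariate prevalence '", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(covariates$age) || covariates$age$sd < 0 || covariates$age$mean <= 0)
    stop("covariate 'age' needs positive mean and non-negative sd", call. = FALSE)
  for (d in c(pfs, pps)) check_family_spec(d)
  structure(list(n_per_arm = as.integer(n_per_arm), covariates = covariates,
                 pfs = pfs, pps = pps, crossover_prob = crossover_prob,
                 crossover_accel = crossover_accel, censor_time = censor_time,
                 seed = as.integer(seed)),
            class = "trial_scenario")
}

#' Default baseline covariate marginals
#'
#' The reference-trial "before adjustment" profile: 91.60% male, mean age
#' 61.48 years, 3.92% brain metastasis, 65.83% stage IV, 84.59% smoking
#' history, 85.43% ECOG performance status 1.  Age sd is not published;
#' 9 years is typical of advanced-NSCLC trial populations.
#' @return named list understood by \code{\link{trial_scenario}}.
#' @export
default_covariates <- function() {
  list(male = 0.9160, age = list(mean = 61.48, sd = 9),
       brain_met = 0.0392, stage_iv = 0.6583,
       smoker = 0.8459, ecog1 = 0.8543)
}

# family name -> random generator on natural-scale parameters
check_family_spec <- function(d) {
  fam <- d$family
  ok <- c("exponential", "weibull", "lognormal", "loglogistic",
          "gompertz", "gengamma")
  if (is.null(fam) || !fam %in% ok)
    stop("unknown survival family '", fam, "'; must be one of ",
         paste(ok, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

r_family <- function(n, d) {
  switch(d$family,
    exponential = stats::rexp(n, rate = d$rate),
    weibull     = stats::rweibull(n, shape = d$shape, scale = d$scale),
    lognormal   = stats::rlnorm(n, meanlog = d$meanlog, sdlog = d$sdlog),
    loglogistic = flexsurv::rllogis(n, shape = d$shape, scale = d$scale),
    gompertz    = flexsurv::rgompertz(n, shape = d$shape, rate = d$rate),
    gengamma    = flexsurv::rgengamma(n, mu = d$mu, sigma = d$sigma, Q = d$Q))
}

#' Simulate a two-arm trial
#'
#' Draws baseline covariates and latent PFS/PPS per arm, applies control-arm
#' crossover at progression via \code{\link{apply_crossover}}, then applies
#' administrative censoring via \code{\link{censor_records}}.  With the
#' scenario seed fixed the output is identical across runs.
#'
#' @param scenario a \code{\link{trial_scenario}}.
#' @return a data frame of IPD records, one row per patient, with columns
#'   \code{patient_id, arm, age, male, brain_met, stage_iv, smoker, ecog1,
#'   pfs_time, pfs_event, os_time, os_event, switched, switch_time}
#'   (\code{switch_time} is \code{NA} for non-switchers).  Satisfies
#'   \code{pfs_time <= os_time} and, for switchers,
#'   \code{pfs_time <= switch_time <= os_time}.
#' @export
simulate_trial <- function(scenario) {
  stopifnot(inherits(scenario, "trial_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_per_arm
  arms <- c("active", "control")
  out <- lapply(arms, function(a) {
    cv <- scenario$covariates
    data.frame(
      patient_id = paste0(substr(a, 1, 1), seq_len(n)),
      arm = a,
      age = stats::rnorm(n, cv$age$mean, cv$age$sd),
      male = stats::rbinom(n, 1, cv$male),
      brain_met = stats::rbinom(n, 1, cv$brain_met),
      stage_iv = stats::rbinom(n, 1, cv$stage_iv),
      smoker = stats::rbinom(n, 1, cv$smoker),
      ecog1 = stats::rbinom(n, 1, cv$ecog1),
      pfs_time = r_family(n, scenario$pfs[[a]]),
      os_time = NA_real_,
      pps = r_family(n, scenario$pps[[a]]),
      stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, out)
  rec$os_time <- rec$pfs_time + rec$pps
  rec$pps <- NULL
  # latent records: everything observed until censoring is applied
  rec$pfs_event <- 1L
  rec$os_event <- 1L
  rec$switched <- 0L
  rec$switch_time <- NA_real_
  rec <- apply_crossover(rec, scenario$crossover_prob, scenario$crossover_accel)
  censor_records(rec, scenario$censor_time)
}

#' Apply post-progression crossover to control-arm records
#'
#' Each control-arm patient with an observed progression switches onto the
#' active therapy with probability \code{crossover_prob}; for switchers the
#' post-progression survival time is multiplied by \code{crossover_accel}
#' (an accelerated-failure-time effect on the latent scale, before any
#' recensoring), \code{switched} is set and \code{switch_time} records the
#' progression time.  The active arm is untouched.
#'
#' @param records IPD data frame (latent or observed times).
#' @param crossover_prob switch probability in \[0,1\].
#' @param crossover_accel acceleration factor > 0.
#' @param seed optional seed for the switch draws.
#' @return the records with \code{os_time}, \code{switched},
#'   \code{switch_time} updated.
#' @export
apply_crossover <- function(records, crossover_prob, crossover_accel,
                            seed = NULL) {
  if (crossover_accel <= 0)
    stop("crossover_accel must be > 0", call. = FALSE)
  if (crossover_prob < 0 || crossover_prob > 1)
    stop("crossover_prob must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (crossover_prob == 0) return(records)
  eligible <- records$arm == "control" & records$pfs_event == 1
  sw <- eligible & stats::rbinom(nrow(records), 1, crossover_prob) == 1
  ppt <- records$os_time[sw] - records$pfs_time[sw]
  records$os_time[sw] <- records$pfs_time[sw] + ppt * crossover_accel
  records$switched[sw] <- 1L
  records$switch_time[sw] <- records$pfs_time[sw]
  records
}

#' Administratively censor IPD records
#'
#' Truncates PFS and OS at \code{censor_time}, sets event flags, and clears
#' switch information for progressions that fall beyond the censoring time
#' (unobserved switches).
#'
#' @param records IPD data frame with latent times.
#' @param censor_time administrative censoring time in months.
#' @return censored records satisfying the IPD invariants.
#' @export
censor_records <- function(records, censor_time) {
  if (censor_time < 0) stop("censor_time must be >= 0", call. = FALSE)
  records$pfs_event <- as.integer(records$pfs_time <= censor_time)
  records$pfs_time <- pmin(records$pfs_time, censor_time)
  records$os_event <- as.integer(records$os_time <= censor_time)
  records$os_time <- pmin(records$os_time, censor_time)
  unseen <- records$switched == 1 & records$switch_time > censor_time
  records$switched[unseen] <- 0L
  records$switch_time[unseen] <- NA_real_
  records
}

#' Validate IPD invariants
#'
#' Checks the structural invariants every record must satisfy:
#' non-negative times, \code{pfs_time <= os_time}, binary flags, switching
#' confined to progressed control-arm patients, and
#' \code{pfs_time <= switch_time <= os_time} for switchers.
#'
#' @param records IPD data frame.
#' @return invisibly \code{TRUE}; stops with a message otherwise.
#' @export
validate_ipd <- function(records) {
  need <- c("patient_id", "arm", "pfs_time", "pfs_event",
            "os_time", "os_event", "switched", "switch_time")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("IPD missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  stopifnot(all(records$arm %in% c("active", "control")),
            all(records$pfs_time >= 0), all(records$os_time >= 0),
            all(records$pfs_time <= records$os_time + 1e-12),
            all(records$pfs_event %in% 0:1), all(records$os_event %in% 0:1),
            all(records$switched %in% 0:1))
  sw <- records$switched == 1
  if (any(sw)) {
    stopifnot(all(records$arm[sw] == "control"),
              all(records$pfs_event[sw] == 1),
              all(!is.na(records$switch_time[sw])),
              all(records$switch_time[sw] >= records$pfs_time[sw] - 1e-12),
              all(records$switch_time[sw] <= records$os_time[sw] + 1e-12))
  }
  invisible(TRUE)
}

#' Read/write IPD as CSV
#'
#' Plain CSV with exactly the IPD column names as header; a missing
#' \code{switch_time} is encoded as an empty field.
#' @param records IPD data frame.
#' @param path file path.
#' @return \code{read_ipd} returns the IPD data frame.
#' @export
write_ipd <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec$switch_time[rec$switch_time == ""] <- NA
  rec$switch_time <- as.numeric(rec$switch_time)
  validate_ipd(rec)
  rec
}

#' Read a trial scenario from a YAML-like key:value config
#'
#' Accepts a YAML file with the fields of \code{\link{trial_scenario}}
#' (nested lists for \code{covariates}, \code{pfs}, \code{pps}).
#' @param path config file path.
#' @return a \code{\link{trial_scenario}}.
#' @export
read_scenario <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read scenario configs", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  do.call(trial_scenario, cfg)
}
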