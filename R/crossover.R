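#' Cox hazard ratio between trial arms
#'
#' Partial-likelihood hazard ratio (active vs control) with Efron tie
#' handling, optionally weighted per record (as required when combining with
#' matching-adjusted indirect comparison weights).  The weighted partial
#' likelihood is invariant to rescaling all weights by a constant.
#'
#' @param records IPD data frame with an \code{arm} column.
#' @param endpoint \code{"os"} or \code{"pfs"}.
#' @param weights optional non-negative per-record weights.
#' @return list with \code{hr}, \code{log_hr}, \code{se_log_hr},
#'   \code{ci} (95\%), \code{n_events}.
#' @export
cox_hr <- function(records, endpoint = c("os", "pfs"), weights = NULL) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  if (sum(records[[ecol]][records$arm == "active"]) < 1 ||
      sum(records[[ecol]][records$arm == "control"]) < 1)
    stop("each arm needs at least one observed event", call. = FALSE)
  df <- data.frame(time = records[[tcol]], event = records[[ecol]],
                   active = as.integer(records$arm == "active"))
  if (is.null(weights)) weights <- rep(1, nrow(df))
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  df$.w <- weights
  fit <- survival::coxph(survival::Surv(time, event) ~ active, data = df,
                         weights = .w, ties = "efron")
  b <- unname(stats::coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  list(hr = exp(b), log_hr = b, se_log_hr = se,
       ci = exp(b + c(-1, 1) * 1.96 * se),
       n_events = sum(df$event))
}

#' Estimate the switching acceleration factor at the secondary baseline
#'
#' Stage one of the two-stage treatment-switching adjustment: among
#' control-arm patients with an observed progression, post-progression
#' survival is regressed on the switch indicator (plus secondary-baseline
#' covariates, measured at randomization) in a Weibull accelerated
#' failure-time model.  The exponentiated switch coefficient is the factor
#' by which switching onto the active therapy multiplies post-progression
#' survival time.
#'
#' @param records IPD data frame (control arm is selected internally).
#' @param covariates character vector of adjustment covariates; defaults to
#'   the six baseline factors used for population matching.
#' @return list with \code{accel_factor}, \code{ci} (95\%),
#'   \code{se_log}, \code{n_switchers}, \code{n_progressed}.
#' @export
estimate_accel_factor <- function(records,
                                  covariates = c("age", "male", "brain_met",
                                                 "stage_iv", "smoker",
                                                 "ecog1")) {
  ctl <- records[records$arm == "control" & records$pfs_event == 1, ,
                 drop = FALSE]
  if (!nrow(ctl)) stop("no progressed control-arm patients", call. = FALSE)
  ppt <- ctl$os_time - ctl$pfs_time
  keep <- ppt > 0
  ctl <- ctl[keep, , drop = FALSE]
  ppt <- ppt[keep]
  ns <- sum(ctl$switched == 1)
  if (ns == 0 || ns == nrow(ctl))
    stop("no common support: need both switchers and non-switchers among ",
         "progressed control-arm patients", call. = FALSE)
  covariates <- intersect(covariates, names(ctl))
  # drop covariates without variation (they make the AFT design singular)
  covariates <- covariates[vapply(covariates, function(v)
    stats::sd(ctl[[v]]) > 0, logical(1))]
  fml <- stats::reformulate(c("switched", covariates),
                            response = "survival::Surv(ppt, os_event)")
  fit <- survival::survreg(fml, data = cbind(ctl, ppt = ppt),
                           dist = "weibull")
  b <- stats::coef(fit)[["switched"]]
  se <- sqrt(diag(stats::vcov(fit)))[["switched"]]
  list(accel_factor = exp(b), ci = exp(b + c(-1, 1) * 1.96 * se),
       se_log = se, n_switchers = ns, n_progressed = nrow(ctl))
}

#' Rebuild counterfactual survival times for switchers
#'
#' Stage two: shrink the post-switch survival of switchers by the estimated
#' acceleration factor — adjusted OS = switch time + (observed OS − switch
#' time) / accel — leaving non-switchers untouched.  With
#' \code{recensor = TRUE} (the standard choice, avoiding informative
#' censoring on the counterfactual time scale) all control-arm times are
#' recensored at min(censor time, censor time / accel) with event flags
#' updated.
#'
#' @param records IPD data frame.
#' @param accel_factor acceleration factor > 0.
#' @param recensor logical.
#' @param censor_time administrative censoring time (months); required when
#'   \code{recensor = TRUE}.
#' @return adjusted records.
#' @export
counterfactual_times <- function(records, accel_factor, recensor = TRUE,
                                 censor_time = NULL) {
  if (accel_factor <= 0) stop("accel_factor must be > 0", call. = FALSE)
  sw <- records$switched == 1
  if (any(sw & records$switch_time > records$os_time + 1e-12))
    stop("switch_time exceeds os_time in input", call. = FALSE)
  records$os_time[sw] <- records$switch_time[sw] +
    (records$os_time[sw] - records$switch_time[sw]) / accel_factor
  if (recensor) {
    if (is.null(censor_time))
      stop("censor_time is required when recensor = TRUE", call. = FALSE)
    cstar <- min(censor_time, censor_time / accel_factor)
    ctl <- records$arm == "control"
    over <- ctl & records$os_time > cstar
    records$os_event[over] <- 0L
    records$os_time[ctl] <- pmin(records$os_time[ctl], cstar)
  }
  records
}

#' Two-stage treatment-switching adjustment of the OS hazard ratio
#'
#' Full pipeline: estimate the acceleration factor among progressed
#' control-arm patients (\code{\link{estimate_accel_factor}}), rebuild
#' counterfactual control-arm times (\code{\link{counterfactual_times}}),
#' and re-estimate the intention-to-treat OS hazard ratio.  Control-arm
#' crossover onto the active therapy dilutes the apparent benefit (pulls the
#' ITT HR toward 1); the adjusted HR moves away from 1 toward the
#' no-switching counterfactual.
#'
#' @param records IPD data frame.
#' @param recensor logical, see \code{\link{counterfactual_times}}.
#' @param censor_time administrative censoring time (months).
#' @param covariates secondary-baseline covariates for the AFT model.
#' @return object of class \code{two_stage}: \code{accel_factor}, \code{ci},
#'   \code{hr_unadjusted}, \code{hr_adjusted} (each with \code{se_log_hr}),
#'   \code{recensored}, \code{n_switchers}.
#' @export
two_stage_adjust <- function(records, recensor = TRUE, censor_time = NULL,
                             covariates = c("age", "male", "brain_met",
                                            "stage_iv", "smoker", "ecog1")) {
  if (recensor && is.null(censor_time))
    censor_time <- max(records$os_time)
  af <- estimate_accel_factor(records, covariates)
  unadj <- cox_hr(records, "os")
  adj_rec <- counterfactual_times(records, af$accel_factor,
                                  recensor = recensor,
                                  censor_time = censor_time)
  adj <- cox_hr(adj_rec, "os")
  structure(list(accel_factor = af$accel_factor, ci = af$ci,
                 se_log_accel = af$se_log,
                 hr_unadjusted = unadj$hr,
                 se_log_hr_unadjusted = unadj$se_log_hr,
                 hr_adjusted = adj$hr,
                 se_log_hr_adjusted = adj$se_log_hr,
                 recensored = recensor,
                 n_switchers = af$n_switchers),
            class = "two_stage")
}

#' @export
print.two_stage <- function(x, ...) {
  cat("Two-stage treatment-switching adjustment\n")
  cat(sprintf("  acceleration factor: %.3f (95%% CI %.3f-%.3f), %d switchers\n",
              x$accel_factor, x$ci[1], x$ci[2], x$n_switchers))
  cat(sprintf("  OS HR (ITT, unadjusted): %.3f\n", x$hr_unadjusted))
  cat(sprintf("  OS HR (two-stage adjusted%s): %.3f\n",
              if (x$recensored) ", recensored" else "", x$hr_adjusted))
  invisible(x)
}
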