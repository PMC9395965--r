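#' Aggregate baseline profile of a comparator trial
#'
#' First-moment targets for the six matching covariates.  The default is the
#' comparator trial's published profile: 81.40% male, mean age 65.00 years,
#' 7.69% brain metastasis, 63.15% stage IV, 92.67% smoking history, 73.70%
#' ECOG 1.
#'
#' @param male,brain_met,stage_iv,smoker,ecog1 proportions in (0,1).
#' @param age mean age in years (> 0).
#' @return named numeric vector of class \code{aggregate_baseline}.
#' @export
aggregate_baseline <- function(male = 0.8140, age = 65.00,
                               brain_met = 0.0769, stage_iv = 0.6315,
                               smoker = 0.9267, ecog1 = 0.7370) {
  p <- c(male = male, brain_met = brain_met, stage_iv = stage_iv,
         smoker = smoker, ecog1 = ecog1)
  if (any(p <= 0 | p >= 1))
    stop("proportions must lie in (0, 1)", call. = FALSE)
  if (age <= 0) stop("age must be > 0", call. = FALSE)
  structure(c(male = male, age = age, brain_met = brain_met,
              stage_iv = stage_iv, smoker = smoker, ecog1 = ecog1),
            class = "aggregate_baseline")
}

#' Solve matching-adjusted indirect comparison weights
#'
#' Method-of-moments / entropy-balancing weights \eqn{w_i =
#' \exp(a^\top x_i)} with \eqn{a} solving \eqn{\sum_i w_i (x_i - \bar x^*) =
#' 0}, i.e. the weighted first moments of the IPD match the comparator
#' trial's aggregate baseline exactly.  The coefficients are found by Newton
#' minimization of the convex dual \eqn{\sum_i \exp\{a^\top (x_i - \bar
#' x^*)\}}; covariates are standardized internally so the solution is
#' invariant to affine rescaling.  Weights are normalized to sum to the
#' sample size.
#'
#' @param records IPD data frame containing the target covariate columns.
#' @param target an \code{\link{aggregate_baseline}} (or named vector).
#' @param tol gradient tolerance of the Newton solver.
#' @param max_iter maximum Newton iterations.
#' @return numeric weight vector (length \code{nrow(records)}), with
#'   attributes \code{coefficients} and \code{ess}.
#' @export
solve_weights <- function(records, target, tol = 1e-10, max_iter = 200L) {
  nm <- names(target)
  miss <- setdiff(nm, names(records))
  if (length(miss))
    stop("IPD lacks matching covariates: ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(records[, nm, drop = FALSE])
  n <- nrow(X)
  for (j in seq_along(nm)) {
    r <- range(X[, j])
    if (target[j] < r[1] || target[j] > r[2])
      stop("target for '", nm[j], "' (", target[j],
           ") lies outside the observed covariate range [",
           signif(r[1], 4), ", ", signif(r[2], 4),
           "]: infeasible matching", call. = FALSE)
  }
  sc <- apply(X, 2, stats::sd)
  sc[sc == 0] <- 1
  Z <- sweep(sweep(X, 2, as.numeric(target)), 2, sc, "/")
  a <- rep(0, ncol(Z))
  for (it in seq_len(max_iter)) {
    ew <- exp(drop(Z %*% a))
    g <- drop(crossprod(Z, ew))
    if (max(abs(g)) / n < tol) break
    H <- crossprod(Z * ew, Z)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step))
      stop("Newton step failed: singular Hessian in MAIC weight solver",
           call. = FALSE)
    # damped Newton: halve until the dual decreases
    f0 <- sum(ew)
    lam <- 1
    repeat {
      a_new <- a - lam * step
      f1 <- sum(exp(drop(Z %*% a_new)))
      if (f1 <= f0 || lam < 1e-8) break
      lam <- lam / 2
    }
    a <- a_new
  }
  ew <- exp(drop(Z %*% a))
  if (max(abs(drop(crossprod(Z, ew)))) / n >= tol * 10)
    stop("MAIC weight solver failed to converge", call. = FALSE)
  w <- ew / sum(ew) * n
  attr(w, "coefficients") <- stats::setNames(a / sc, nm)
  attr(w, "ess") <- effective_sample_size(w)
  w
}

#' Effective sample size of a weighted sample
#'
#' \eqn{(\sum w)^2 / \sum w^2}: the size of an equally weighted sample
#' carrying the same information; the standard diagnostic for how much a
#' matching adjustment shrinks the evidence base.
#'
#' @param weights non-negative weights, not all zero.
#' @return scalar ESS, at most \code{length(weights)}.
#' @export
effective_sample_size <- function(weights) {
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (all(weights == 0)) stop("weights must not all be zero", call. = FALSE)
  sum(weights)^2 / sum(weights^2)
}

#' Bucher anchored indirect comparison
#'
#' Combines two trials' anchored log hazard ratios against a common
#' comparator: \eqn{\log \mathrm{HR}_{AB} = \log \mathrm{HR}_{AC} - \log
#' \mathrm{HR}_{BC}}, variance = sum of variances, 95\% CI by normal
#' approximation.
#'
#' @param hr_ac,hr_bc anchored hazard ratios (> 0) of treatments A and B vs
#'   the common anchor C.
#' @param se_ac,se_bc standard errors of the log hazard ratios (>= 0).
#' @return list with \code{hr}, \code{log_hr}, \code{se_log_hr}, \code{ci}.
#' @export
bucher_indirect <- function(hr_ac, se_ac, hr_bc, se_bc) {
  if (hr_ac <= 0 || hr_bc <= 0)
    stop("hazard ratios must be > 0", call. = FALSE)
  if (se_ac < 0 || se_bc < 0) stop("SEs must be >= 0", call. = FALSE)
  b <- log(hr_ac) - log(hr_bc)
  se <- sqrt(se_ac^2 + se_bc^2)
  list(hr = exp(b), log_hr = b, se_log_hr = se,
       ci = exp(b + c(-1, 1) * 1.96 * se))
}

#' Anchored matching-adjusted indirect comparison
#'
#' Reweights the reference trial's IPD to the comparator trial's aggregate
#' baseline (\code{\link{solve_weights}}), re-estimates the anchored hazard
#' ratio by a weighted Cox model (reference active vs shared comparator
#' arm), and combines it with the comparator trial's published anchored HR
#' by the Bucher method.
#'
#' @param records reference-trial IPD (both arms).
#' @param target \code{\link{aggregate_baseline}} of the comparator trial.
#' @param endpoint \code{"os"} or \code{"pfs"}.
#' @param hr_comp,se_comp comparator trial's anchored HR (vs the common
#'   anchor) and log-scale SE.
#' @return object of class \code{maic}: \code{weights}, \code{ess},
#'   \code{hr_anchored} (weighted reference HR with \code{se_log_hr}),
#'   \code{hr_indirect} (Bucher A-vs-B result).
#' @export
maic_compare <- function(records, target = aggregate_baseline(),
                         endpoint = c("os", "pfs"),
                         hr_comp, se_comp) {
  endpoint <- match.arg(endpoint)
  w <- solve_weights(records, target)
  anchored <- cox_hr(records, endpoint, weights = as.numeric(w))
  indirect <- bucher_indirect(anchored$hr, anchored$se_log_hr,
                              hr_comp, se_comp)
  structure(list(weights = as.numeric(w),
                 coefficients = attr(w, "coefficients"),
                 ess = attr(w, "ess"), n = nrow(records),
                 endpoint = endpoint,
                 hr_anchored = anchored,
                 hr_comparator = list(hr = hr_comp, se_log_hr = se_comp),
                 hr_indirect = indirect),
            class = "maic")
}

#' @export
print.maic <- function(x, ...) {
  cat("Anchored MAIC (", x$endpoint, ")\n", sep = "")
  cat(sprintf("  n = %d, ESS after weighting = %.1f\n", x$n, x$ess))
  cat(sprintf("  weighted anchored HR (reference vs anchor): %.3f (SE log %.3f)\n",
              x$hr_anchored$hr, x$hr_anchored$se_log_hr))
  cat(sprintf("  comparator anchored HR: %.3f\n", x$hr_comparator$hr))
  cat(sprintf("  Bucher indirect HR: %.3f (95%% CI %.3f-%.3f)\n",
              x$hr_indirect$hr, x$hr_indirect$ci[1], x$hr_indirect$ci[2]))
  invisible(x)
}

#' Weighted covariate moments
#'
#' Convenience check of moment matching after weighting.
#' @param records IPD data frame.
#' @param weights weight vector.
#' @param covariates covariate names.
#' @return named vector of weighted means.
#' @export
weighted_moments <- function(records, weights,
                             covariates = c("male", "age", "brain_met",
                                            "stage_iv", "smoker", "ecog1")) {
  X <- as.matrix(records[, covariates, drop = FALSE])
  drop(crossprod(X, weights)) / sum(weights)
}
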