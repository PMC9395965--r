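#' Fit a parametric survival model to right-censored data
#'
#' Maximum-likelihood fit of one of six parametric families, used for
#' extrapolating trial PFS/OS curves over a lifetime horizon.  Fitting is
#' delegated to \code{\link[flexsurv]{flexsurvreg}}; the returned object
#' pins the parameterization conventions used throughout the package:
#' \describe{
#'   \item{exponential}{rate \eqn{\lambda}; \eqn{S(t) = e^{-\lambda t}}}
#'   \item{weibull}{shape \eqn{a}, scale \eqn{b}; \eqn{S(t)=\exp\{-(t/b)^a\}}}
#'   \item{lognormal}{meanlog \eqn{\mu}, sdlog \eqn{\sigma};
#'     \eqn{S(t)=1-\Phi((\log t-\mu)/\sigma)}}
#'   \item{loglogistic}{shape \eqn{a}, scale \eqn{b};
#'     \eqn{S(t)=1/(1+(t/b)^a)}}
#'   \item{gompertz}{shape \eqn{a}, rate \eqn{b};
#'     \eqn{S(t)=\exp\{-b/a\,(e^{at}-1)\}}}
#'   \item{gengamma}{generalized gamma (Prentice): location \eqn{\mu},
#'     scale \eqn{\sigma}, shape \eqn{Q}}
#' }
#' The variance-covariance matrix is the inverse observed information at the
#' optimum, held on the unconstrained estimation scale (log for positive
#' parameters) — the scale on which \code{\link{sample_parameters}} draws.
#'
#' @param times positive event/censoring times (months).
#' @param events binary event indicators (1 = observed).
#' @param family one of \code{"exponential"}, \code{"weibull"},
#'   \code{"lognormal"}, \code{"loglogistic"}, \code{"gompertz"},
#'   \code{"gengamma"}.
#' @return object of class \code{parsurv} with elements \code{family},
#'   \code{params} (natural scale), \code{params_t} (estimation scale),
#'   \code{vcov} (estimation scale), \code{loglik}, \code{aic}, \code{bic},
#'   \code{n}, \code{nevent}.
#' @examples
#' f <- fit_parametric(c(2, 4, 6), c(1, 1, 1), "exponential")
#' coef(f)  # rate = 3/12
#' @export
fit_parametric <- function(times, events, family) {
  fam_map <- c(exponential = "exp", weibull = "weibull", lognormal = "lnorm",
               loglogistic = "llogis", gompertz = "gompertz",
               gengamma = "gengamma")
  if (length(family) != 1 || !family %in% names(fam_map))
    stop("unknown survival family '", family, "'", call. = FALSE)
  if (any(times <= 0)) stop("times must be > 0", call. = FALSE)
  if (!all(events %in% 0:1)) stop("events must be binary", call. = FALSE)
  if (sum(events) < 2)
    stop("estimation requires at least 2 observed events", call. = FALSE)
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(times, events) ~ 1,
                          dist = fam_map[[family]]),
    error = function(e) stop("estimation failed for family '", family,
                             "': ", conditionMessage(e), call. = FALSE))
  k <- fit$npars
  n <- length(times)
  structure(list(
    family = family,
    params = stats::setNames(fit$res[, "est"], rownames(fit$res)),
    params_t = stats::setNames(fit$res.t[, "est"], rownames(fit$res.t)),
    vcov = fit$cov,
    loglik = fit$loglik,
    aic = 2 * k - 2 * fit$loglik,
    bic = k * log(n) - 2 * fit$loglik,
    n = n,
    nevent = sum(events),
    transforms = fit$dlist$transforms,
    inv_transforms = fit$dlist$inv.transforms,
    data_checksum = c(n = n, d = sum(events), tsum = sum(times))
  ), class = "parsurv")
}

#' @export
coef.parsurv <- function(object, ...) object$params

#' @export
logLik.parsurv <- function(object, ...) {
  structure(object$loglik, df = length(object$params),
            nobs = object$n, class = "logLik")
}

#' @export
print.parsurv <- function(x, ...) {
  cat("Parametric survival fit:", x$family, "\n")
  cat("  n =", x$n, " events =", x$nevent, "\n")
  print(round(x$params, 5))
  cat(sprintf("  logLik = %.3f  AIC = %.2f  BIC = %.2f\n",
              x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Rank candidate fits by information criteria
#'
#' Orders fits of different families to the same data by AIC (ascending),
#' reporting BIC alongside; ties broken by fewer parameters, then by family
#' name.  Distribution selection in practice combines this table with visual
#' inspection against the Kaplan-Meier curve (see \code{\link{plot.parsurv}}).
#'
#' @param fits list of \code{parsurv} objects fitted to the same data.
#' @return data frame with columns \code{family, k, loglik, aic, bic},
#'   best first.
#' @export
rank_fits <- function(fits) {
  if (inherits(fits, "parsurv")) fits <- list(fits)
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  cks <- vapply(fits, function(f) f$data_checksum, numeric(3))
  if (any(apply(cks, 1, function(v) diff(range(v)) > 1e-8)))
    stop("fits were not computed on the same data", call. = FALSE)
  tab <- data.frame(
    family = vapply(fits, function(f) f$family, character(1)),
    k = vapply(fits, function(f) length(f$params), numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    stringsAsFactors = FALSE)
  tab[order(tab$aic, tab$k, tab$family), , drop = FALSE]
}

# dispatch table of p<dist> functions (lower.tail = FALSE gives S(t))
psurv_fun <- function(family) {
  switch(family,
    exponential = function(t, p) stats::pexp(t, rate = p[["rate"]], lower.tail = FALSE),
    weibull     = function(t, p) stats::pweibull(t, shape = p[["shape"]], scale = p[["scale"]], lower.tail = FALSE),
    lognormal   = function(t, p) stats::plnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]], lower.tail = FALSE),
    loglogistic = function(t, p) flexsurv::pllogis(t, shape = p[["shape"]], scale = p[["scale"]], lower.tail = FALSE),
    gompertz    = function(t, p) flexsurv::pgompertz(t, shape = p[["shape"]], rate = p[["rate"]], lower.tail = FALSE),
    gengamma    = function(t, p) flexsurv::pgengamma(t, mu = p[["mu"]], sigma = p[["sigma"]], Q = p[["Q"]], lower.tail = FALSE))
}

hsurv_fun <- function(family) {
  switch(family,
    exponential = function(t, p) rep(p[["rate"]], length(t)),
    weibull     = function(t, p) flexsurv::hweibull(t, shape = p[["shape"]], scale = p[["scale"]]),
    lognormal   = function(t, p) flexsurv::hlnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
    loglogistic = function(t, p) flexsurv::hllogis(t, shape = p[["shape"]], scale = p[["scale"]]),
    gompertz    = function(t, p) flexsurv::hgompertz(t, shape = p[["shape"]], rate = p[["rate"]]),
    gengamma    = function(t, p) flexsurv::hgengamma(t, mu = p[["mu"]], sigma = p[["sigma"]], Q = p[["Q"]]))
}

#' Survival, hazard and simulation for fitted curves
#'
#' \code{surv_prob} evaluates \eqn{S(t)}; \code{haz_rate} the hazard
#' \eqn{h(t)}.  Both are generics with methods for \code{parsurv} fits and
#' for proportional-hazards transformed curves (\code{\link{apply_hr}}).
#'
#' @param object a fitted curve object.
#' @param t non-negative times (months), scalar or vector.
#' @param ... unused.
#' @return survival probabilities in \[0,1\] (resp. hazards).
#' @export
surv_prob <- function(object, t, ...) UseMethod("surv_prob")

#' @rdname surv_prob
#' @export
haz_rate <- function(object, t, ...) UseMethod("haz_rate")

#' @export
surv_prob.parsurv <- function(object, t, ...) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  psurv_fun(object$family)(t, object$params)
}

#' @export
haz_rate.parsurv <- function(object, t, ...) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  hsurv_fun(object$family)(t, object$params)
}

#' Replace the parameters of a fitted curve
#'
#' Returns a copy of the fit with natural-scale parameters replaced —
#' used when propagating sampled parameter vectors through the decision
#' model in probabilistic sensitivity analysis.
#'
#' @param fit a \code{parsurv} object.
#' @param params named (or positionally ordered) natural-scale parameter
#'   vector.
#' @return a \code{parsurv} object.
#' @export
set_params <- function(fit, params) {
  stopifnot(inherits(fit, "parsurv"),
            length(params) == length(fit$params))
  fit$params[] <- as.numeric(params)
  fit
}

#' Proportional-hazards transformation of a survival curve
#'
#' Applies a hazard ratio to a baseline curve on the hazard scale:
#' \eqn{h_c(t) = \mathrm{HR}\, h_0(t)}, which integrates in closed form to
#' \eqn{S_c(t) = S_0(t)^{\mathrm{HR}}}.  This is how an external comparator's
#' hazard ratio is applied to a (possibly non-PH, e.g. log-normal) baseline
#' extrapolation.
#'
#' @param curve a \code{parsurv} fit or another \code{hr_curve}.
#' @param hr hazard ratio > 0 (comparator vs baseline).
#' @return object of class \code{hr_curve} supporting
#'   \code{\link{surv_prob}} and \code{\link{haz_rate}}.
#' @export
apply_hr <- function(curve, hr) {
  if (!is.numeric(hr) || length(hr) != 1 || hr <= 0)
    stop("hr must be a positive scalar", call. = FALSE)
  structure(list(base = curve, hr = hr), class = "hr_curve")
}

#' @export
surv_prob.hr_curve <- function(object, t, ...)
  surv_prob(object$base, t)^object$hr

#' @export
haz_rate.hr_curve <- function(object, t, ...)
  object$hr * haz_rate(object$base, t)

#' Sample correlated parameter vectors from a fit
#'
#' Multivariate-normal parameter draws for probabilistic sensitivity
#' analysis via Cholesky decomposition of the estimation-scale covariance:
#' draws = estimate + L z with L lower triangular, z iid standard normal,
#' back-transformed to the natural scale (so positive parameters are sampled
#' on the log scale and remain positive).  A jitter of 1e-10 on the diagonal
#' is added once if the matrix is not numerically positive definite; if it
#' still fails the decomposition the function errors rather than silently
#' repairing the matrix (an indefinite covariance signals an unstable fit and
#' is a reason to prefer another family).
#'
#' @param fit a \code{parsurv} object.
#' @param n_draws number of draws (>= 1).
#' @param seed optional integer seed.
#' @return matrix \code{n_draws x k} of natural-scale parameter vectors,
#'   columns named as \code{coef(fit)}.
#' @export
sample_parameters <- function(fit, n_draws, seed = NULL) {
  stopifnot(inherits(fit, "parsurv"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- length(fit$params_t)
  V <- (fit$vcov + t(fit$vcov)) / 2
  if (all(V == 0)) {
    out <- matrix(rep(fit$params, each = n_draws), nrow = n_draws)
    colnames(out) <- names(fit$params)
    return(out)
  }
  L <- tryCatch(t(chol(V)), error = function(e) NULL)
  if (is.null(L))
    L <- tryCatch(t(chol(V + diag(1e-10, k))), error = function(e) NULL)
  if (is.null(L))
    stop("covariance matrix is not positive definite beyond jitter ",
         "tolerance; Cholesky decomposition failed for family '",
         fit$family, "'", call. = FALSE)
  z <- matrix(stats::rnorm(n_draws * k), nrow = k)
  draws_t <- t(fit$params_t + L %*% z)
  out <- vapply(seq_len(k),
                function(j) fit$inv_transforms[[j]](draws_t[, j]),
                numeric(n_draws))
  out <- matrix(out, nrow = n_draws)
  colnames(out) <- names(fit$params)
  out
}

#' Plot a fitted curve against the Kaplan-Meier estimate
#'
#' Visual-inspection diagnostic used alongside \code{\link{rank_fits}} when
#' choosing an extrapolation family.
#'
#' @param x a \code{parsurv} object.
#' @param times,events the data to overlay as a Kaplan-Meier curve
#'   (optional).
#' @param horizon plotting horizon in months.
#' @param ... passed to \code{plot}.
#' @export
plot.parsurv <- function(x, times = NULL, events = NULL,
                         horizon = NULL, ...) {
  if (is.null(horizon))
    horizon <- if (is.null(times)) 60 else 2 * max(times)
  tt <- seq(0, horizon, length.out = 200)
  graphics::plot(tt, surv_prob(x, tt), type = "l", ylim = c(0, 1),
                 xlab = "months", ylab = "S(t)",
                 main = paste("Fitted", x$family, "curve"), ...)
  if (!is.null(times)) {
    km <- survival::survfit(survival::Surv(times, events) ~ 1)
    graphics::lines(km$time, km$surv, type = "s", col = "grey40")
  }
  invisible(x)
}

#' Serialize / restore a fitted curve as plain text
#'
#' Writes family, natural- and estimation-scale parameters, covariance,
#' log-likelihood and sample size to a small JSON-free key:value text file
#' so fits can be reused across sessions without binary artifacts.
#'
#' @param fit a \code{parsurv} object.
#' @param path file path.
#' @return \code{read_parsurv} returns the \code{parsurv} object.
#' @export
write_parsurv <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("family:", fit$family),
    paste("params:", paste(names(fit$params), collapse = ",")),
    paste("est:", paste(format(fit$params, digits = 17), collapse = ",")),
    paste("est_t:", paste(format(fit$params_t, digits = 17), collapse = ",")),
    paste("vcov:", paste(format(as.vector(fit$vcov), digits = 17), collapse = ",")),
    paste("loglik:", format(fit$loglik, digits = 17)),
    paste("n:", fit$n),
    paste("nevent:", fit$nevent),
    paste("checksum:", paste(format(fit$data_checksum, digits = 17), collapse = ","))
  ), con)
  invisible(path)
}

#' @rdname write_parsurv
#' @export
read_parsurv <- function(path) {
  kv <- strsplit(readLines(path), ": ", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  family <- vals$family
  nm <- strsplit(vals$params, ",")[[1]]
  est <- as.numeric(strsplit(vals$est, ",")[[1]])
  est_t <- as.numeric(strsplit(vals$est_t, ",")[[1]])
  k <- length(est)
  V <- matrix(as.numeric(strsplit(vals$vcov, ",")[[1]]), k, k,
              dimnames = list(nm, nm))
  dists <- c(exponential = "exp", weibull = "weibull", lognormal = "lnorm",
             loglogistic = "llogis", gompertz = "gompertz",
             gengamma = "gengamma")
  dl <- flexsurv::flexsurv.dists[[dists[[family]]]]
  structure(list(
    family = family,
    params = stats::setNames(est, nm),
    params_t = stats::setNames(est_t, nm),
    vcov = V,
    loglik = as.numeric(vals$loglik),
    aic = 2 * k - 2 * as.numeric(vals$loglik),
    bic = k * log(as.numeric(vals$n)) - 2 * as.numeric(vals$loglik),
    n = as.integer(vals$n),
    nevent = as.integer(vals$nevent),
    transforms = dl$transforms,
    inv_transforms = dl$inv.transforms,
    data_checksum = as.numeric(strsplit(vals$checksum, ",")[[1]])
  ), class = "parsurv")
}
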