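#' Build a sampler for one parameter specification
#'
#' Distribution parameters are derived by method of moments from the
#' deterministic value (the mean) and the standard deviation implied by the
#' 95\% interval width rule SD = (high − low)/3.92: gamma for non-negative
#' costs, beta for probabilities/utilities, normal for durations, degenerate
#' for constants.  Gamma and beta samplers never leave their supports.
#'
#' @param value,dist,low,high one row of the parameter table.
#' @return function \code{f(n)} returning \code{n} draws.
#' @export
fit_distribution <- function(value, dist, low, high) {
  if (low > high) stop("low > high in parameter spec", call. = FALSE)
  sd <- (high - low) / 3.92
  if (dist == "constant" || sd == 0) return(function(n) rep(value, n))
  switch(dist,
    normal = function(n) stats::rnorm(n, value, sd),
    gamma = {
      if (value <= 0) stop("gamma requires positive mean", call. = FALSE)
      shape <- value^2 / sd^2; rate <- value / sd^2
      function(n) stats::rgamma(n, shape = shape, rate = rate)
    },
    beta = {
      if (value <= 0 || value >= 1)
        stop("beta requires mean in (0, 1)", call. = FALSE)
      v <- sd^2
      if (v >= value * (1 - value))
        stop("beta moments infeasible: variance too large for mean ",
             value, call. = FALSE)
      a <- value * (value * (1 - value) / v - 1)
      b <- (1 - value) * (value * (1 - value) / v - 1)
      function(n) stats::rbeta(n, a, b)
    },
    stop("unknown distribution '", dist, "'", call. = FALSE))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the deterministic model at each parameter's low and high bound
#' (others held at base) and measures the effect on net monetary benefit at
#' the chosen willingness-to-pay threshold; the ICER at each bound is
#' reported alongside.  NMB is the primary metric because the ICER changes
#' sign unstably when the QALY increment is near zero (as it is here, in the
#' southwest quadrant).  Rows are sorted by |NMB(high) − NMB(low)|
#' descending — the tornado order.
#'
#' @param config a \code{\link{cea_config}}.
#' @param wtp scalar willingness-to-pay for the NMB metric.
#' @return data frame of class \code{dsa_table}: \code{name, label, low,
#'   high, nmb_low, nmb_high, bar, icer_low, icer_high}.
#' @export
one_way_dsa <- function(config, wtp = 33749) {
  params <- config$params
  pv0 <- param_values(params)
  base <- run_cea(config, pv0)
  nmb_of <- function(res) wtp * res$increments$d_qaly - res$increments$d_cost
  rows <- lapply(seq_len(nrow(params)), function(i) {
    lo <- params$low[i]; hi <- params$high[i]
    if (lo > hi) stop("low > high for ", params$name[i], call. = FALSE)
    if (lo == hi)
      return(data.frame(name = params$name[i], label = params$label[i],
                        low = lo, high = hi, nmb_low = nmb_of(base),
                        nmb_high = nmb_of(base), bar = 0,
                        icer_low = base$increments$icer,
                        icer_high = base$increments$icer,
                        stringsAsFactors = FALSE))
    run_at <- function(v) {
      pv <- pv0; pv[params$name[i]] <- v
      run_cea(config, pv)
    }
    r_lo <- run_at(lo); r_hi <- run_at(hi)
    data.frame(name = params$name[i], label = params$label[i],
               low = lo, high = hi,
               nmb_low = nmb_of(r_lo), nmb_high = nmb_of(r_hi),
               bar = abs(nmb_of(r_hi) - nmb_of(r_lo)),
               icer_low = r_lo$increments$icer,
               icer_high = r_hi$increments$icer,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$bar), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dsa_table", "data.frame")
  attr(out, "wtp") <- wtp
  attr(out, "nmb_base") <- nmb_of(base)
  out
}

#' Tornado diagram
#'
#' Horizontal bars of NMB at each parameter's bounds for the top
#' \code{n_top} parameters.
#' @param x a \code{dsa_table}.
#' @param n_top number of parameters displayed.
#' @param ... unused.
#' @export
plot.dsa_table <- function(x, n_top = 10, ...) {
  d <- utils::head(x[x$bar > 0, ], n_top)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "nmb_base")
  op <- graphics::par(mar = c(4, 14, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(c(d$nmb_low, d$nmb_high)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = paste0("NMB at WTP ", attr(x, "wtp"), " (USD)"),
                 ylab = "", main = "One-way sensitivity (tornado)")
  for (i in seq_len(nrow(d))) {
    graphics::rect(min(d$nmb_low[i], d$nmb_high[i]), i - 0.35,
                   max(d$nmb_low[i], d$nmb_high[i]), i + 0.35,
                   col = "grey70")
  }
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$label, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: each iteration draws every non-constant
#' parameter from its distribution, correlated survival-curve parameters
#' via Cholesky decomposition of the fitted covariance
#' (\code{\link{sample_parameters}}), and — when comparator curves are
#' hazard-ratio transforms — log-normal hazard-ratio draws around the
#' base-case ratio, then re-runs both arms.  Iterations failing model
#' validation are dropped and counted; more than 1\% drops is an error.
#'
#' The intervention-arm curves must be \code{parsurv} fits; comparator
#' curves may be \code{parsurv} fits or \code{hr_curve} transforms of the
#' intervention fits.
#'
#' @param config a \code{\link{cea_config}}.
#' @param n_iter iterations (10,000 in a full run; smaller for testing).
#' @param seed integer seed; the full draw stream is generated up front so
#'   results are reproducible.
#' @param hr_se log-scale standard error for hazard-ratio uncertainty
#'   (assumption: the source comparisons publish no CIs for the adjusted
#'   ratios).
#' @return object of class \code{psa}: \code{draws} (data frame with
#'   \code{d_cost, d_qaly}), \code{summary} (mean increments, probabilistic
#'   ICER, quadrant shares), \code{n_dropped}.
#' @export
run_psa <- function(config, n_iter = 1000, seed = 1, hr_se = 0.15) {
  stopifnot(inherits(config, "cea_config"), n_iter >= 1)
  set.seed(seed)
  params <- config$params
  pmat <- vapply(seq_len(nrow(params)), function(i)
    fit_distribution(params$value[i], params$dist[i],
                     params$low[i], params$high[i])(n_iter),
    numeric(n_iter))
  pmat <- matrix(pmat, nrow = n_iter,
                 dimnames = list(NULL, params$name))
  fit_draws <- list()
  hr_draws <- list()
  for (arm in names(config$curves)) for (ep in c("pfs", "os")) {
    cv <- config$curves[[arm]][[ep]]
    key <- paste(arm, ep)
    if (inherits(cv, "parsurv")) {
      fit_draws[[key]] <- sample_parameters(cv, n_iter)
    } else if (inherits(cv, "hr_curve")) {
      if (!inherits(cv$base, "parsurv"))
        stop("hr_curve base must be a parsurv fit for PSA", call. = FALSE)
      fit_draws[[key]] <- sample_parameters(cv$base, n_iter)
      hr_draws[[key]] <- stats::rlnorm(n_iter, log(cv$hr), hr_se)
    } else stop("unsupported curve class in PSA", call. = FALSE)
  }
  # share the base fit's draws across curves built on the same fit, so the
  # anchor extrapolation is perturbed coherently in both arms
  for (arm in names(config$curves)) for (ep in c("pfs", "os")) {
    cv <- config$curves[[arm]][[ep]]
    if (inherits(cv, "hr_curve")) {
      for (arm2 in names(config$curves)) {
        cv2 <- config$curves[[arm2]][[ep]]
        if (inherits(cv2, "parsurv") && identical(cv2$params, cv$base$params))
          fit_draws[[paste(arm, ep)]] <- fit_draws[[paste(arm2, ep)]]
      }
    }
  }
  d_cost <- d_qaly <- rep(NA_real_, n_iter)
  dropped <- 0L
  cfg_i <- config
  for (i in seq_len(n_iter)) {
    for (arm in names(config$curves)) for (ep in c("pfs", "os")) {
      cv <- config$curves[[arm]][[ep]]
      key <- paste(arm, ep)
      if (inherits(cv, "parsurv")) {
        cfg_i$curves[[arm]][[ep]] <- set_params(cv, fit_draws[[key]][i, ])
      } else {
        cfg_i$curves[[arm]][[ep]] <-
          apply_hr(set_params(cv$base, fit_draws[[key]][i, ]),
                   hr_draws[[key]][i])
      }
    }
    res <- tryCatch(run_cea(cfg_i, pmat[i, ]), error = function(e) NULL)
    if (is.null(res)) { dropped <- dropped + 1L; next }
    d_cost[i] <- res$increments$d_cost
    d_qaly[i] <- res$increments$d_qaly
  }
  if (dropped / n_iter > 0.01)
    stop(dropped, " of ", n_iter, " PSA iterations failed model validation",
         call. = FALSE)
  ok <- !is.na(d_cost)
  draws <- data.frame(iter = which(ok), d_cost = d_cost[ok],
                      d_qaly = d_qaly[ok])
  quad <- table(factor(ifelse(draws$d_qaly >= 0,
                              ifelse(draws$d_cost >= 0, "NE", "SE"),
                              ifelse(draws$d_cost >= 0, "NW", "SW")),
                       levels = c("NE", "SE", "SW", "NW")))
  structure(list(
    draws = draws,
    summary = list(mean_d_cost = mean(draws$d_cost),
                   mean_d_qaly = mean(draws$d_qaly),
                   icer = mean(draws$d_cost) / mean(draws$d_qaly),
                   quadrant_share = quad / nrow(draws)),
    n_iter = n_iter, n_dropped = dropped, seed = seed, hr_se = hr_se,
    wtp = config$wtp), class = "psa")
}

#' @export
print.psa <- function(x, ...) {
  cat("Probabilistic sensitivity analysis (", nrow(x$draws),
      " iterations)\n", sep = "")
  cat(sprintf("  mean incremental cost: %.0f USD\n", x$summary$mean_d_cost))
  cat(sprintf("  mean incremental QALY: %.4f\n", x$summary$mean_d_qaly))
  cat(sprintf("  probabilistic ICER:    %.0f USD/QALY\n", x$summary$icer))
  cat("  quadrant shares:\n")
  print(round(x$summary$quadrant_share, 3))
  invisible(x)
}

#' Cost-effectiveness plane scatter
#' @param x a \code{psa} object.
#' @param wtp threshold line(s) to draw.
#' @param ... passed to \code{plot}.
#' @export
plot.psa <- function(x, wtp = x$wtp, ...) {
  graphics::plot(x$draws$d_qaly, x$draws$d_cost, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "incremental QALYs", ylab = "incremental cost (USD)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey60")
  for (w in wtp) graphics::abline(0, w, lty = 2, col = "grey40")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention has the higher net monetary benefit,
#' per willingness-to-pay value: P(wtp x dQALY − dCost > 0) over the PSA
#' draws.  At wtp = 0 this is the fraction of cost-saving draws.
#'
#' @param psa a \code{\link{run_psa}} result (or its draws data frame).
#' @param wtp_grid willingness-to-pay grid (USD/QALY).
#' @return data frame of class \code{ceac} with columns \code{wtp, prob}.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 60000, by = 2000)) {
  draws <- if (inherits(psa, "psa")) psa$draws else psa
  if (!nrow(draws)) stop("no PSA draws", call. = FALSE)
  prob <- vapply(wtp_grid, function(w)
    mean(w * draws$d_qaly - draws$d_cost > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, prob = prob),
            class = c("ceac", "data.frame"))
}

#' @export
plot.ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$prob, type = "l", ylim = c(0, 1),
                 xlab = "willingness to pay (USD/QALY)",
                 ylab = "P(intervention cost-effective)",
                 main = "Cost-effectiveness acceptability curve", ...)
  invisible(x)
}
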