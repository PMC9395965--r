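#' Calibrate the base-case model to published increments
#'
#' The comparator trial's individual patient data and the original fitted
#' extrapolation parameters are not public, so a reproducible base case is
#' constructed by calibration: starting from reference-arm parametric fits,
#' the comparator arm's PFS and OS curves are derived by hazard scaling
#' (\code{\link{apply_hr}}) with two multipliers, and the two
#' patient-assistance-program price fractions are treated as free schedule
#' terms (their source documents state no reusable numbers).  Four knobs are
#' solved sequentially by one-dimensional root finding:
#' \enumerate{
#'   \item comparator OS hazard multiplier so the life-year increment
#'     (intervention − comparator) equals \code{d_ly};
#'   \item comparator PFS hazard multiplier so the QALY increment equals
#'     \code{d_qaly} (this reallocates time between the PF and PP states
#'     without changing life-years);
#'   \item intervention PAP fraction so the intervention drug component
#'     equals \code{drug_active};
#'   \item comparator PAP fraction so the total cost increment equals
#'     \code{d_cost}.
#' }
#' Each target is met to the root-finder tolerance; everything else (prices,
#' utilities, incidences, care patterns) stays at its deterministic value.
#'
#' @param fit_pfs,fit_os reference-arm \code{parsurv} fits (months).
#' @param params parameter table.
#' @param d_qaly,d_ly,d_cost target increments (intervention − comparator).
#' @param drug_active target intervention-arm drug cost component (USD).
#' @param regimens,care,dosing,... passed to \code{\link{cea_config}}.
#' @param tol root-finding tolerance.
#' @return calibrated \code{\link{cea_config}} with attribute
#'   \code{calibration} = list(m_pfs, m_os, pap_frac_active,
#'   pap_frac_comp).
#' @export
calibrate_base_case <- function(fit_pfs, fit_os,
                                params = load_parameters(),
                                d_qaly = -0.0183, d_ly = 0.1005,
                                d_cost = -24050, drug_active = 2523,
                                regimens = default_regimens(),
                                care = default_care_patterns(),
                                dosing = default_dosing(),
                                tol = 1e-8, ...) {
  make_config <- function(m_pfs, m_os, frac_a, frac_c) {
    regs <- regimens
    regs$active$drugs[[1]]$pap$frac <- frac_a
    regs$comp$drugs[[1]]$pap$frac <- frac_c
    cea_config(
      curves = list(
        active = list(pfs = fit_pfs, os = fit_os),
        comp = list(pfs = apply_hr(fit_pfs, m_pfs),
                    os = apply_hr(fit_os, m_os))),
      params = params, regimens = regs, care = care, dosing = dosing, ...)
  }
  solve1 <- function(f, interval, what) {
    lo <- f(interval[1]); hi <- f(interval[2])
    if (is.na(lo) || is.na(hi) || lo * hi > 0)
      stop("calibration target '", what, "' not bracketed on [",
           interval[1], ", ", interval[2], "]", call. = FALSE)
    stats::uniroot(f, interval, tol = tol)$root
  }
  m_os <- solve1(function(m) {
    r <- run_cea(make_config(1, m, 0.5, 0.5))
    r$increments$d_ly - d_ly
  }, c(1 + 1e-6, 4), "life-year increment")
  m_pfs <- solve1(function(m) {
    r <- run_cea(make_config(m, m_os, 0.5, 0.5))
    r$increments$d_qaly - d_qaly
  }, c(0.1, 1.5), "QALY increment")
  frac_a <- solve1(function(fr) {
    r <- run_cea(make_config(m_pfs, m_os, fr, 0.5))
    r$active$cost_components$drug - drug_active
  }, c(0, 1), "intervention drug component")
  frac_c <- solve1(function(fr) {
    r <- run_cea(make_config(m_pfs, m_os, frac_a, fr))
    r$increments$d_cost - d_cost
  }, c(0, 1), "cost increment")
  cfg <- make_config(m_pfs, m_os, frac_a, frac_c)
  attr(cfg, "calibration") <- list(m_pfs = m_pfs, m_os = m_os,
                                   pap_frac_active = frac_a,
                                   pap_frac_comp = frac_c)
  cfg
}
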