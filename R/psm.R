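#' Load the cost/utility parameter table
#'
#' Reads the model parameter table (unit costs in 2021 USD at 6.44 CNY/USD,
#' adverse-event incidences and durations, state utilities and AE
#' disutilities), each row carrying a deterministic value, a distribution
#' family for probabilistic analysis (\code{gamma}, \code{beta},
#' \code{normal}, \code{constant}) and low/high bounds used in one-way
#' deterministic sensitivity analysis.
#'
#' @param path CSV path; defaults to the table shipped with the package.
#' @return data frame with columns \code{name, label, group, value, dist,
#'   low, high}.
#' @export
load_parameters <- function(path = system.file("extdata", "parameters.csv",
                                               package = "psmcea")) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "group", "value", "dist", "low", "high")
                %in% names(p)))
  bad <- p$low > p$value + 1e-9 | p$value > p$high + 1e-9
  if (any(bad))
    stop("parameter bounds violate low <= value <= high: ",
         paste(p$name[bad], collapse = ", "), call. = FALSE)
  if (!all(p$dist %in% c("gamma", "beta", "normal", "constant")))
    stop("unknown distribution in parameter table", call. = FALSE)
  p
}

param_values <- function(params) stats::setNames(params$value, params$name)

#' Default dosing assumptions
#'
#' Mean body weight 65 kg and body surface area 1.6 m2; doses rounded up to
#' whole vials (wastage) unless \code{vial_round} is disabled in the model
#' settings.
#' @return named list.
#' @export
default_dosing <- function() list(weight = 65, bsa = 1.6)

#' Default treatment regimens
#'
#' Drug schedules for the two strategies.  Intervention: sintilimab 200 mg
#' every 3 weeks (maintenance up to 24 months) plus gemcitabine
#' 1000 mg/m2 (days 1 and 8) and cisplatin 75 mg/m2, both capped at 4
#' cycles.  Comparator: pembrolizumab 200 mg every 3 weeks (up to 24
#' months) plus nab-paclitaxel 100 mg/m2 (days 1, 8, 15) and carboplatin
#' (AUC-based, 750 mg flat under the dosing assumptions), both capped at 4
#' cycles.  Patient-assistance programs (PAP) are expressed as a per-cycle
#' price schedule: full price for the first \code{n_paid} cycles, a
#' fraction \code{frac} of the price afterwards.  PAP terms are program
#' documents, not trial data, and are expected to be calibrated or supplied
#' by the user (see \code{\link{calibrate_base_case}}).
#'
#' @return list with elements \code{active} and \code{comp}.
#' @export
default_regimens <- function() {
  list(
    active = list(
      name = "sintilimab + gemcitabine/cisplatin",
      ae_prefix = "inc_active_",
      drugs = list(
        list(drug = "sintilimab", price = "cost_sintilimab",
             dose = list(flat = 200), n_admin = 1, vial_mg = 200,
             max_cycles = Inf, max_months = 24,
             pap = list(n_paid = 4, frac = 0.25)),
        list(drug = "gemcitabine", price = "cost_gemcitabine",
             dose = list(per_m2 = 1000), n_admin = 2, vial_mg = 200,
             max_cycles = 4, max_months = Inf, pap = NULL),
        list(drug = "cisplatin", price = "cost_cisplatin_high",
             dose = list(per_m2 = 75), n_admin = 1, vial_mg = 30,
             max_cycles = 4, max_months = Inf, pap = NULL))),
    comp = list(
      name = "pembrolizumab + nab-paclitaxel/carboplatin",
      ae_prefix = "inc_comp_",
      drugs = list(
        list(drug = "pembrolizumab", price = "cost_pembrolizumab",
             dose = list(flat = 200), n_admin = 1, vial_mg = 100,
             max_cycles = Inf, max_months = 24,
             pap = list(n_paid = 4, frac = 0.5)),
        list(drug = "nab-paclitaxel", price = "cost_paclitaxel_high",
             dose = list(per_m2 = 100), n_admin = 3, vial_mg = 100,
             max_cycles = 4, max_months = Inf, pap = NULL),
        list(drug = "carboplatin", price = "cost_carboplatin_high",
             dose = list(flat = 750), n_admin = 1, vial_mg = 100,
             max_cycles = 4, max_months = Inf, pap = NULL))))
}

#' Default care-resource patterns
#'
#' Per-cycle frequencies of administration, progression-free follow-up /
#' monitoring, and post-progression management resource items (unit prices
#' come from the parameter table).  Administration accrues over
#' progression-free occupancy while any drug is still scheduled; follow-up
#' over all progression-free occupancy (labs every cycle, imaging every
#' second cycle); management over post-progression occupancy.
#'
#' @return list of named frequency vectors \code{admin}, \code{followup_pf},
#'   \code{management_pp}.
#' @export
default_care_patterns <- function() {
  list(
    admin = c(cost_diagnosis = 1, cost_iv_injection = 3,
              cost_nursing = 3, cost_hospitalization = 3),
    followup_pf = c(cost_blood_chemistry = 1, cost_blood_routine = 1,
                    cost_urine_routine = 1, cost_imaging = 0.5),
    management_pp = c(cost_diagnosis = 1, cost_nursing = 3,
                      cost_imaging = 1 / 3))
}

#' Discount factor at a model cycle
#'
#' Continuous-time convention \eqn{(1+r)^{-t}} with \eqn{t} in years,
#' \eqn{t = \mathrm{cycle} \times 7\,\mathrm{cycle\_weeks} / 365.25}.
#'
#' @param cycle cycle index (0-based), scalar or vector.
#' @param annual_rate annual discount rate (>= 0); 5\% by default per
#'   Chinese pharmacoeconomic guidance.
#' @param cycle_weeks cycle length in weeks.
#' @return discount factors.
#' @export
discount_factor <- function(cycle, annual_rate = 0.05, cycle_weeks = 3) {
  if (annual_rate < 0) stop("annual_rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-(cycle * cycle_weeks * 7 / 365.25))
}

#' Build a partitioned survival trace
#'
#' Evaluates the PFS and OS curves on the cycle grid and partitions the
#' cohort into progression-free (PF), post-progression (PP) and dead:
#' occ_pf = S_pfs, occ_pp = S_os − S_pfs, occ_dead = 1 − S_os, after
#' enforcing the ordering constraint S_pfs <- min(S_pfs, S_os).  Occupancies
#' sum to one exactly at every cycle and the dead compartment is
#' non-decreasing.
#'
#' @param pfs_curve,os_curve objects supporting \code{\link{surv_prob}}
#'   evaluated in months.
#' @param horizon_years model horizon (> 0).
#' @param cycle_weeks cycle length in weeks (3 = the administration cycle).
#' @param annual_rate discount rate for the trace's discount-factor column.
#' @return data frame of class \code{psm_trace} with columns \code{cycle,
#'   t_months, t_years, s_pfs, s_os, occ_pf, occ_pp, occ_dead, deaths, df}.
#' @export
build_trace <- function(pfs_curve, os_curve, horizon_years = 20,
                        cycle_weeks = 3, annual_rate = 0.05) {
  if (horizon_years <= 0) stop("horizon must be > 0", call. = FALSE)
  n_cycles <- ceiling(horizon_years * 365.25 / (cycle_weeks * 7))
  cyc <- 0:n_cycles
  t_months <- cyc * cycle_weeks * 7 / 30.4375
  s_pfs <- surv_prob(pfs_curve, t_months)
  s_os <- surv_prob(os_curve, t_months)
  for (v in list(s_pfs, s_os))
    if (any(v < -1e-12 | v > 1 + 1e-12) || any(!is.finite(v)))
      stop("survival curve returned values outside [0, 1]", call. = FALSE)
  s_pfs <- pmin(pmax(s_pfs, 0), 1)
  s_os <- pmin(pmax(s_os, 0), 1)
  s_pfs <- pmin(s_pfs, s_os)
  tr <- data.frame(
    cycle = cyc, t_months = t_months, t_years = cyc * cycle_weeks * 7 / 365.25,
    s_pfs = s_pfs, s_os = s_os,
    occ_pf = s_pfs, occ_pp = s_os - s_pfs, occ_dead = 1 - s_os,
    deaths = c(0, -diff(s_os)),
    df = discount_factor(cyc, annual_rate, cycle_weeks))
  class(tr) <- c("psm_trace", "data.frame")
  attr(tr, "cycle_weeks") <- cycle_weeks
  attr(tr, "annual_rate") <- annual_rate
  tr
}

# effective per-cycle occupancy: state time spent during cycle c (rows 2..N)
# valued at cycle-end occupancy (no half-cycle correction; a cohort dying
# within a cycle accrues no state time or drug for it), or at the start/end
# average (trapezoid) when half_cycle = TRUE.
cycle_occupancy <- function(x, half_cycle = FALSE) {
  n <- length(x)
  if (half_cycle) (x[-n] + x[-1]) / 2 else x[-1]
}

ae_names <- c("neutropenia", "leukopenia", "anemia", "thrombocytopenia")

#' Quality-adjusted-life-year loss from adverse events
#'
#' Sum over grade >= 3 adverse events of incidence x disutility x
#' (duration_days / 365.25); applied once, on treatment, against the
#' progression-free QALY accrual.
#'
#' @param pv named parameter-value vector (see \code{\link{load_parameters}}).
#' @param ae_prefix incidence prefix, \code{"inc_active_"} or
#'   \code{"inc_comp_"}.
#' @return scalar QALY loss.
#' @export
ae_qaly_loss <- function(pv, ae_prefix) {
  sum(vapply(ae_names, function(a)
    pv[[paste0(ae_prefix, a)]] * pv[[paste0("disu_", a)]] *
      pv[[paste0("dur_", a)]] / 365.25, numeric(1)))
}

ae_cost_once <- function(pv, ae_prefix) {
  sum(vapply(ae_names, function(a)
    pv[[paste0(ae_prefix, a)]] * pv[[paste0("cost_ae_", a)]], numeric(1)))
}

#' Accrue discounted costs over a trace
#'
#' Drug acquisition accrues over progression-free occupancy while each
#' component is scheduled (combination chemotherapy capped at 4 cycles,
#' immunotherapy at 24 months), at vial-rounded doses and the per-cycle PAP
#' price schedule.  Administration visits accrue while on treatment;
#' follow-up/monitoring over PF occupancy; management over PP occupancy.
#' Adverse-event management is charged once at model entry (incidence x
#' per-episode cost), subsequent therapy once per new progressor (PF exits
#' net of the PF share of deaths), end-of-life care per death, all
#' discounted at the event time.
#'
#' @param trace a \code{\link{build_trace}} result.
#' @param regimen one element of \code{\link{default_regimens}}.
#' @param pv named parameter-value vector.
#' @param care \code{\link{default_care_patterns}}.
#' @param dosing \code{\link{default_dosing}}.
#' @param vial_round round doses up to whole vials (wastage).
#' @param half_cycle average start/end occupancy per cycle.
#' @param subsequent_per_patient charge the subsequent-therapy cost once per
#'   patient at model entry (undiscounted lump) instead of per discounted
#'   progressor.
#' @return named list of cost components: \code{drug, administration,
#'   management, ae, subsequent, eol, total}.
#' @export
accrue_costs <- function(trace, regimen, pv, care = default_care_patterns(),
                         dosing = default_dosing(), vial_round = TRUE,
                         half_cycle = FALSE,
                         subsequent_per_patient = FALSE) {
  n <- nrow(trace) - 1          # cycles 1..n
  occ_pf <- cycle_occupancy(trace$occ_pf, half_cycle)
  occ_pp <- cycle_occupancy(trace$occ_pp, half_cycle)
  df_start <- trace$df[-nrow(trace)]
  df_end <- trace$df[-1]
  t_start <- trace$t_months[-nrow(trace)]
  cyc <- seq_len(n)

  # --- drug acquisition
  drug <- 0
  on_treatment <- rep(FALSE, n)
  for (d in regimen$drugs) {
    dose_mg <- if (!is.null(d$dose$flat)) d$dose$flat
      else if (!is.null(d$dose$per_m2)) d$dose$per_m2 * dosing$bsa
      else if (!is.null(d$dose$per_kg)) d$dose$per_kg * dosing$weight
      else stop("drug '", d$drug, "' has no dose rule", call. = FALSE)
    if (is.null(pv[[d$price]]))
      stop("missing unit price '", d$price, "' for regimen component '",
           d$drug, "'", call. = FALSE)
    vials <- if (vial_round) ceiling(dose_mg / d$vial_mg) else dose_mg / d$vial_mg
    per_cycle <- vials * d$n_admin * pv[[d$price]]
    sched <- cyc <= d$max_cycles & t_start < d$max_months
    mult <- rep(1, n)
    if (!is.null(d$pap)) mult <- ifelse(cyc <= d$pap$n_paid, 1, d$pap$frac)
    drug <- drug + sum(per_cycle * mult * sched * occ_pf * df_start)
    on_treatment <- on_treatment | sched
  }

  unit_cost <- function(freq) sum(freq * vapply(names(freq), function(nm)
    pv[[nm]], numeric(1)))
  administration <- sum(unit_cost(care$admin) * on_treatment * occ_pf * df_start)
  management <- sum(unit_cost(care$followup_pf) * occ_pf * df_start) +
    sum(unit_cost(care$management_pp) * occ_pp * df_start)
  ae <- ae_cost_once(pv, regimen$ae_prefix)

  deaths <- trace$deaths[-1]
  alive_start <- trace$s_os[-nrow(trace)]
  pf_share <- ifelse(alive_start > 0, trace$occ_pf[-nrow(trace)] / alive_start, 0)
  progressors <- pmax(0, -diff(trace$s_pfs) - deaths * pf_share)
  subsequent <- if (subsequent_per_patient) pv[["cost_subsequent"]]
    else pv[["cost_subsequent"]] * sum(progressors * df_end)
  eol <- pv[["cost_eol"]] * sum(deaths * df_end)

  comp <- list(drug = drug, administration = administration,
               management = management, ae = ae,
               subsequent = subsequent, eol = eol)
  comp$total <- sum(unlist(comp))
  comp
}

#' Accrue QALYs and life-years over a trace
#'
#' qaly_pf = sum over cycles of PF occupancy x u_pf x discount x cycle
#' length (minus the one-off adverse-event QALY loss), qaly_pp analogously;
#' life-years use unit utility.  Both discounted and undiscounted life-years
#' are reported.
#'
#' @param trace a \code{\link{build_trace}} result.
#' @param u_pf,u_pp health-state utilities in \[0,1\].
#' @param ae_loss one-off QALY loss (see \code{\link{ae_qaly_loss}}).
#' @param half_cycle average start/end occupancy per cycle.
#' @return list \code{qaly_pf, qaly_pp, qaly_total, ly, ly_undisc}.
#' @export
accrue_qalys <- function(trace, u_pf, u_pp, ae_loss = 0, half_cycle = FALSE) {
  if (u_pf < 0 || u_pf > 1 || u_pp < 0 || u_pp > 1)
    stop("utilities must lie in [0, 1]", call. = FALSE)
  cyl <- attr(trace, "cycle_weeks") * 7 / 365.25
  occ_pf <- cycle_occupancy(trace$occ_pf, half_cycle)
  occ_pp <- cycle_occupancy(trace$occ_pp, half_cycle)
  df <- trace$df[-nrow(trace)]
  qaly_pf <- sum(occ_pf * df) * cyl * u_pf - ae_loss
  qaly_pp <- sum(occ_pp * df) * cyl * u_pp
  list(qaly_pf = qaly_pf, qaly_pp = qaly_pp,
       qaly_total = qaly_pf + qaly_pp,
       ly = sum((occ_pf + occ_pp) * df) * cyl,
       ly_undisc = sum(occ_pf + occ_pp) * cyl)
}

#' Incremental cost-effectiveness summary
#'
#' Computes incremental cost, QALYs and life-years (intervention minus
#' comparator), the ICER when cost and effect increments share a
#' direction of trade-off, a dominance label otherwise, and net monetary
#' benefit at each willingness-to-pay threshold.  In the southwest quadrant
#' (cheaper, less effective) the intervention is preferred when the ICER
#' exceeds the threshold.
#'
#' @param result_a intervention arm result (list with \code{cost_total},
#'   \code{qaly_total}, \code{ly}).
#' @param result_b comparator arm result.
#' @param wtp willingness-to-pay threshold(s), USD per QALY.
#' @return object of class \code{cea_increments}: \code{d_cost, d_qaly,
#'   d_ly, icer, label, quadrant, nmb}.
#' @export
incremental_summary <- function(result_a, result_b,
                                wtp = c(11250, 33749)) {
  d_cost <- result_a$cost_total - result_b$cost_total
  d_qaly <- result_a$qaly_total - result_b$qaly_total
  d_ly <- if (!is.null(result_a$ly)) result_a$ly - result_b$ly else NA_real_
  nmb <- wtp * d_qaly - d_cost
  names(nmb) <- paste0("wtp_", wtp)
  if (d_qaly == 0) {
    icer <- NA_real_; label <- "undefined ICER"; quadrant <- NA_character_
  } else if (d_qaly > 0 && d_cost < 0) {
    icer <- NA_real_; label <- "dominant"; quadrant <- "southeast"
  } else if (d_qaly < 0 && d_cost > 0) {
    icer <- NA_real_; label <- "dominated"; quadrant <- "northwest"
  } else {
    icer <- d_cost / d_qaly
    quadrant <- if (d_qaly > 0) "northeast" else "southwest"
    label <- if (quadrant == "southwest")
      "ICER (southwest: cheaper, less effective; preferred when ICER > WTP)"
    else "ICER"
  }
  structure(list(d_cost = d_cost, d_qaly = d_qaly, d_ly = d_ly,
                 icer = icer, label = label, quadrant = quadrant,
                 nmb = nmb, wtp = wtp),
            class = "cea_increments")
}

#' @export
print.cea_increments <- function(x, ...) {
  cat(sprintf("Incremental cost:  %12.2f USD\n", x$d_cost))
  cat(sprintf("Incremental QALY:  %12.4f\n", x$d_qaly))
  if (!is.na(x$d_ly)) cat(sprintf("Incremental LY:    %12.4f\n", x$d_ly))
  if (!is.na(x$icer)) cat(sprintf("ICER:              %12.0f USD/QALY (%s)\n",
                                  x$icer, x$quadrant))
  else cat("Decision:         ", x$label, "\n")
  for (i in seq_along(x$wtp))
    cat(sprintf("NMB at WTP %6.0f: %12.0f\n", x$wtp[i], x$nmb[i]))
  invisible(x)
}

#' Assemble a cost-effectiveness model configuration
#'
#' Bundles everything a deterministic model run needs: per-arm PFS/OS curves
#' (objects supporting \code{\link{surv_prob}}), the parameter table,
#' regimens, care patterns, dosing and settings.  Utilities default to the
#' table's \code{u_pf}/\code{u_pp} for both arms; per-arm overrides support
#' the utility-mapping scenario.
#'
#' @param curves \code{list(active = list(pfs =, os =), comp = list(...))}.
#' @param params parameter table (\code{\link{load_parameters}}).
#' @param regimens \code{\link{default_regimens}} or a modified copy.
#' @param care \code{\link{default_care_patterns}}.
#' @param dosing \code{\link{default_dosing}}.
#' @param utilities \code{NULL}, or \code{list(active = c(pf=, pp=),
#'   comp = c(pf=, pp=))}.
#' @param horizon_years,cycle_weeks,discount model settings.
#' @param wtp willingness-to-pay thresholds (USD/QALY).
#' @param half_cycle,vial_round,subsequent_per_patient accrual flags.
#' @return list of class \code{cea_config}.
#' @export
cea_config <- function(curves, params = load_parameters(),
                       regimens = default_regimens(),
                       care = default_care_patterns(),
                       dosing = default_dosing(),
                       utilities = NULL,
                       horizon_years = 20, cycle_weeks = 3, discount = 0.05,
                       wtp = c(11250, 33749), half_cycle = FALSE,
                       vial_round = TRUE, subsequent_per_patient = FALSE) {
  structure(list(curves = curves, params = params, regimens = regimens,
                 care = care, dosing = dosing, utilities = utilities,
                 horizon_years = horizon_years, cycle_weeks = cycle_weeks,
                 discount = discount, wtp = wtp, half_cycle = half_cycle,
                 vial_round = vial_round,
                 subsequent_per_patient = subsequent_per_patient),
            class = "cea_config")
}

run_arm <- function(config, arm, pv) {
  cv <- config$curves[[arm]]
  tr <- build_trace(cv$pfs, cv$os, config$horizon_years,
                    config$cycle_weeks, config$discount)
  reg <- config$regimens[[arm]]
  costs <- accrue_costs(tr, reg, pv, config$care, config$dosing,
                        config$vial_round, config$half_cycle,
                        config$subsequent_per_patient)
  if (!is.null(config$utilities)) {
    # overridden utilities (mapped from patient-reported outcomes) embed the
    # adverse-event burden already: no separate disutility subtraction
    u_pf <- config$utilities[[arm]][["pf"]]
    u_pp <- config$utilities[[arm]][["pp"]]
    ae_loss <- 0
  } else {
    u_pf <- pv[["u_pf"]]; u_pp <- pv[["u_pp"]]
    ae_loss <- ae_qaly_loss(pv, reg$ae_prefix)
  }
  q <- accrue_qalys(tr, u_pf, u_pp, ae_loss = ae_loss,
                    half_cycle = config$half_cycle)
  c(q, list(cost_total = costs$total, cost_components = costs, trace = tr))
}

#' Run the partitioned survival cost-effectiveness model
#'
#' Deterministic model run: builds both arms' traces, accrues discounted
#' costs and QALYs, and summarizes the incremental comparison.
#'
#' @param config a \code{\link{cea_config}}.
#' @param pv optional named parameter-value vector overriding the table's
#'   deterministic column (used by sensitivity analyses).
#' @return object of class \code{cea} with elements \code{active},
#'   \code{comp} (per-arm results) and \code{increments}.
#' @export
run_cea <- function(config, pv = NULL) {
  stopifnot(inherits(config, "cea_config"))
  if (is.null(pv)) pv <- param_values(config$params)
  active <- run_arm(config, "active", pv)
  comp <- run_arm(config, "comp", pv)
  structure(list(active = active, comp = comp,
                 increments = incremental_summary(active, comp, config$wtp),
                 wtp = config$wtp),
            class = "cea")
}

#' @export
print.cea <- function(x, ...) {
  fmt <- function(r) c(
    QALYs = round(r$qaly_total, 4),
    `PF QALYs` = round(r$qaly_pf, 4), `PP QALYs` = round(r$qaly_pp, 4),
    LYs = round(r$ly, 4),
    `Total cost` = round(r$cost_total, 0),
    `Drug` = round(r$cost_components$drug, 0),
    `Administration` = round(r$cost_components$administration, 0),
    `Management/monitoring` = round(r$cost_components$management, 0),
    `AE` = round(r$cost_components$ae, 0),
    `Subsequent therapy` = round(r$cost_components$subsequent, 0),
    `End of life` = round(r$cost_components$eol, 0))
  tab <- cbind(intervention = fmt(x$active), comparator = fmt(x$comp))
  cat("Partitioned survival cost-effectiveness results\n")
  print(tab)
  cat("\n")
  print(x$increments)
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  data.frame(
    arm = c("active", "comp"),
    qaly = c(object$active$qaly_total, object$comp$qaly_total),
    qaly_pf = c(object$active$qaly_pf, object$comp$qaly_pf),
    qaly_pp = c(object$active$qaly_pp, object$comp$qaly_pp),
    ly = c(object$active$ly, object$comp$ly),
    cost = c(object$active$cost_total, object$comp$cost_total))
}
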