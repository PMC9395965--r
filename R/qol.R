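#' Mapping coefficients from QLQ-C30 scores to an EQ-5D-5L index
#'
#' A linear mapping: utility = intercept + sum of coefficient x domain
#' score, clamped to the value-set range.  Domain scores follow the QLQ-C30
#' scoring manual (0-100; higher = better for functioning/global scales,
#' higher = worse for symptom scales).
#'
#' @param intercept scalar intercept.
#' @param coefs named numeric vector of per-domain coefficients.
#' @param range utility clamp range of the target value set
#'   (\code{c(-0.391, 1)} for a typical EQ-5D-5L set).
#' @return object of class \code{qlq_mapping}.
#' @export
mapping_coefficients <- function(intercept, coefs, range = c(-0.391, 1)) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefs), !is.null(names(coefs)),
            length(range) == 2, range[1] < range[2])
  structure(list(intercept = intercept, coefs = coefs, range = range),
            class = "qlq_mapping")
}

#' Synthetic default mapping coefficient set
#'
#' A plausibility-shaped SYNTHETIC coefficient set for demonstration and
#' testing only — it is not any published QLQ-C30 to EQ-5D-5L mapping
#' algorithm and must not be used for real valuation.  Published mappings
#' are injected via \code{\link{mapping_coefficients}}.
#'
#' @return a \code{\link{mapping_coefficients}} object over the domains
#'   physical, role, emotional, global (functioning; positive weights) and
#'   fatigue, pain (symptoms; negative weights).
#' @export
synthetic_qlq_mapping <- function() {
  mapping_coefficients(
    intercept = 0.20,
    coefs = c(physical = 0.0040, role = 0.0010, emotional = 0.0010,
              global = 0.0020, fatigue = -0.0015, pain = -0.0015))
}

#' Map a QLQ-C30 record to a utility
#'
#' Evaluates the linear predictor over the mapping's domains and clamps to
#' the value-set range.
#'
#' @param record named numeric vector (or one-row data frame) of QLQ-C30
#'   domain scores on the 0-100 scale.
#' @param coeffs a \code{\link{mapping_coefficients}} object.
#' @return scalar utility within the value-set range.
#' @export
map_to_utility <- function(record, coeffs) {
  stopifnot(inherits(coeffs, "qlq_mapping"))
  if (is.data.frame(record)) record <- unlist(record[1, , drop = TRUE])
  need <- names(coeffs$coefs)
  miss <- setdiff(need, names(record))
  if (length(miss))
    stop("missing required domain score(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sc <- as.numeric(record[need])
  if (any(is.na(sc))) stop("missing required domain score value", call. = FALSE)
  if (any(sc < 0 | sc > 100))
    stop("QLQ-C30 scores must lie in [0, 100]", call. = FALSE)
  u <- coeffs$intercept + sum(coeffs$coefs * sc)
  min(max(u, coeffs$range[1]), coeffs$range[2])
}

#' Derive health-state utilities from longitudinal utility records
#'
#' Computes each patient's mean utility over progression-free (PF) visits
#' and over post-progression (PP) visits.  With the logical-consistency
#' filter on, patients whose mean PF utility is below their mean PP utility
#' are excluded (a PF health state should not be valued below PP).  Cohort
#' state utilities are the means over included patients; patients observed
#' in only one state contribute to that state only and cannot be
#' inconsistent.  The result is invariant to the order of visits.
#'
#' @param records data frame with columns \code{patient_id}, \code{state}
#'   (\code{"PF"}/\code{"PP"}) and \code{utility}.
#' @param filter_inconsistent apply the consistency filter.
#' @return list \code{u_pf}, \code{u_pp}, \code{n_included},
#'   \code{n_excluded}.
#' @export
state_utilities <- function(records, filter_inconsistent = TRUE) {
  stopifnot(all(c("patient_id", "state", "utility") %in% names(records)),
            all(records$state %in% c("PF", "PP")))
  per <- lapply(split(records, records$patient_id), function(d) {
    c(pf = if (any(d$state == "PF")) mean(d$utility[d$state == "PF"]) else NA,
      pp = if (any(d$state == "PP")) mean(d$utility[d$state == "PP"]) else NA)
  })
  m <- do.call(rbind, per)
  if (!any(!is.na(m[, "pf"]) & !is.na(m[, "pp"])))
    stop("no patient observed in both states: state utilities not ",
         "estimable", call. = FALSE)
  keep <- rep(TRUE, nrow(m))
  if (filter_inconsistent) {
    both <- !is.na(m[, "pf"]) & !is.na(m[, "pp"])
    keep[both] <- m[both, "pf"] >= m[both, "pp"]
  }
  kept <- m[keep, , drop = FALSE]
  list(u_pf = mean(kept[, "pf"], na.rm = TRUE),
       u_pp = mean(kept[, "pp"], na.rm = TRUE),
       n_included = sum(keep), n_excluded = sum(!keep))
}

#' Adjust comparator utilities for differential adverse-event burden
#'
#' When reference-arm utilities are derived from patient-reported outcomes
#' they already embed that arm's adverse-event (AE) burden, so the
#' comparator's utilities are shifted by the annualized AE disutility
#' differential:
#' \deqn{u^{comp}_{PF} = u^{ref}_{PF} + \sum_{AE} (inc_{ref} - inc_{comp})
#'   \cdot disutility \cdot (duration_{days}/365.25) / E_{PF}}
#' where \eqn{E_{PF}} is the progression-free exposure (years) over which
#' AEs are experienced.  The PP utility is unchanged (AEs occur on
#' treatment).  A result outside \[0,1\] is clamped with a warning.
#'
#' @param u_ref_pf,u_ref_pp reference-arm state utilities.
#' @param ae_inc_ref,ae_inc_comp named incidence vectors over the same AEs.
#' @param disutilities,durations named vectors over the same AEs
#'   (durations in days).
#' @param exposure_years_pf PF exposure in years (> 0).
#' @return list \code{u_pf}, \code{u_pp} for the comparator arm.
#' @export
adjust_comparator_utilities <- function(u_ref_pf, u_ref_pp,
                                        ae_inc_ref, ae_inc_comp,
                                        disutilities, durations,
                                        exposure_years_pf = 1) {
  stopifnot(exposure_years_pf > 0)
  aes <- names(ae_inc_ref)
  stopifnot(!is.null(aes), all(aes %in% names(ae_inc_comp)),
            all(aes %in% names(disutilities)),
            all(aes %in% names(durations)))
  delta <- sum((ae_inc_ref[aes] - ae_inc_comp[aes]) * disutilities[aes] *
                 (durations[aes] / 365.25)) / exposure_years_pf
  u_pf <- u_ref_pf + delta
  if (u_pf < 0 || u_pf > 1) {
    warning("adjusted comparator PF utility outside [0, 1]; clamped")
    u_pf <- min(max(u_pf, 0), 1)
  }
  list(u_pf = u_pf, u_pp = u_ref_pp)
}

#' Utility set for the mapped-utility scenario
#'
#' Builds the per-arm utility override for \code{\link{cea_config}} used in
#' the scenario analysis: reference-arm utilities come from mapped
#' patient-reported outcomes (defaults 0.730 progression-free, 0.615
#' post-progression), comparator-arm PF utility is AE-differential adjusted
#' via \code{\link{adjust_comparator_utilities}} using the parameter
#' table's incidences, disutilities and durations.
#'
#' @param pv named parameter-value vector.
#' @param u_pf,u_pp reference-arm mapped utilities.
#' @param exposure_years_pf PF exposure in years.
#' @return \code{list(active = c(pf, pp), comp = c(pf, pp))}.
#' @export
scenario_utility_set <- function(pv, u_pf = 0.730, u_pp = 0.615,
                                 exposure_years_pf = 1) {
  get <- function(prefix) stats::setNames(
    vapply(ae_names, function(a) pv[[paste0(prefix, a)]], numeric(1)),
    ae_names)
  adj <- adjust_comparator_utilities(
    u_pf, u_pp,
    ae_inc_ref = get("inc_active_"), ae_inc_comp = get("inc_comp_"),
    disutilities = get("disu_"), durations = get("dur_"),
    exposure_years_pf = exposure_years_pf)
  list(active = c(pf = u_pf, pp = u_pp),
       comp = c(pf = adj$u_pf, pp = adj$u_pp))
}
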