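---
title: "Methods: partitioned survival cost-effectiveness with MAIC and switching adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned survival cost-effectiveness with MAIC and switching adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the statistical adjustments around it,
the synthetic-data generator, and the numerical and design choices the
package makes where the underlying methodology leaves them open.

## The decision problem

Two first-line regimens for advanced squamous non-small cell lung cancer —
a domestically priced PD-1 inhibitor plus gemcitabine/platinum, and the
standard pembrolizumab plus nab-paclitaxel/carboplatin — have never been
compared head to head. Each has a placebo-plus-chemotherapy trial. An
economic comparison therefore needs three pieces of statistical machinery
before any cost model runs:

1. **Treatment-switching adjustment.** In the reference trial, control-arm
   patients could receive active therapy after progression. That lengthens
   control-arm survival and pulls the ITT OS hazard ratio toward 1; the
   economic model needs the counterfactual no-switching comparison.
2. **Population matching.** The two trials enrolled different populations
   (e.g. 91.6% vs 81.4% male, mean age 61.5 vs 65.0). The anchored MAIC
   reweights the reference trial's IPD to the comparator trial's published
   aggregate baseline before the indirect comparison.
3. **Extrapolation.** Trial follow-up is about two years; costs and QALYs
   are lifetime quantities, so parametric curves extrapolate the observed
   PFS/OS.

## Partitioned survival model

Three states: progression-free (PF), post-progression (PP), dead. On a
cycle grid of 3 weeks (the administration interval; 1 cycle = 21/30.4375
months), occupancy comes directly from the curves — `occ_pf = S_PFS`,
`occ_pp = S_OS − S_PFS`, `occ_dead = 1 − S_OS`, after the ordering
constraint `S_PFS ← min(S_PFS, S_OS)`. Occupancies sum to one by
construction and the dead state is absorbing because both parametric
survival functions are non-increasing.

**Accrual convention.** Each cycle's state time is valued at the
*end-of-cycle* occupancy and discounted at the cycle-start factor
`(1 + r)^{-t}` (r = 5%/year, per Chinese pharmacoeconomic guidance). No
half-cycle correction is applied by default, matching common spreadsheet
practice; `half_cycle = TRUE` switches to trapezoid (start/end average)
occupancy. The end-of-cycle choice has the property that a cohort dying
within a cycle accrues no drug cost or state time for it. Deaths are
discounted at the end of the cycle in which they occur; so are
subsequent-therapy charges.

**Costs.** Six components per arm:

* *Drug*: per-cycle vial counts (doses from 65 kg weight / 1.6 m² BSA,
  rounded up to whole vials unless disabled) times unit price, over PF
  occupancy while the component is scheduled — combination chemotherapy
  capped at 4 cycles, immunotherapy at 24 months. Patient-assistance
  programs (PAP) are a per-cycle price schedule: full price for the first
  `n_paid` cycles, a fraction thereafter. The PAP source documents publish
  no reusable terms, so the fractions are calibration targets (below).
* *Administration*: per-treatment-cycle frequencies of diagnosis, IV
  injection, nursing and hospitalization-day items (defaults 1/3/3/3).
* *Management/monitoring*: labs every cycle and imaging every second cycle
  in PF; diagnosis, nursing and a third of an imaging exam per PP cycle.
  These frequencies are configuration, not data.
* *Adverse events*: incidence × per-episode management cost, charged once
  at model entry (grade ≥ 3 events occur early, on treatment). With the
  shipped parameter table this evaluates to $250 (intervention) and $173
  (comparator), matching the published component totals, which confirms
  the per-episode reading of the unit costs.
* *Subsequent therapy*: one charge per new progressor. Per-cycle
  progressors are PF exits net of the PF share of that cycle's deaths
  (deaths apportioned by occupancy, the natural competing-risk split a
  partitioned model supports). An option charges it once per patient
  undiscounted instead, which is what the published component totals
  (exactly the unit cost in both arms) suggest was done originally.
* *End-of-life*: unit cost per death, discounted at death time (the
  published totals are a few percent below the unit cost, consistent with
  discounting).

**Outcomes.** `qaly_pf = Σ occ_pf·u_pf·df·Δt`, analogously for PP; the AE
QALY loss `Σ incidence × disutility × duration/365.25` is subtracted from
the PF component once. Utilities: PF 0.804, PP 0.321 (literature
time-trade-off values) with beta distributions over their published
ranges.

## Survival extrapolation

Six families with pinned parameterizations (Weibull
`S = exp(−(t/scale)^shape)`, log-normal meanlog/sdlog, log-logistic
`S = 1/(1+(t/b)^a)`, Gompertz shape/rate, generalized gamma in the
Prentice parameterization). Fitting is delegated to
`flexsurv::flexsurvreg`; candidate curves are ranked by AIC with BIC
alongside, ties broken by parsimony, and plotted against the Kaplan–Meier
estimate for visual inspection — information criteria alone do not decide
tail behaviour, which is why a log-normal can be preferred over a
nominally better-fitting Weibull when the Weibull's covariance is unstable
under Cholesky decomposition (`sample_parameters` deliberately errors on
an indefinite covariance instead of repairing it; that instability is
evidence against the family).

**External hazard ratios** are applied on the hazard scale,
`h_c(t) = HR·h_0(t)`, which integrates in closed form to
`S_c(t) = S_0(t)^{HR}`. The closed form is exact, so no quadrature is
used for curve transformation. Applying a constant HR to a log-normal
baseline is a modelling convention (log-normal is not a
proportional-hazards family); it is the minimal faithful way to combine a
non-PH extrapolation with an external ratio.

**Parameter uncertainty.** Draws are taken on the estimation scale
(log-transformed positive parameters) as `estimate + L·z` with `L` the
lower Cholesky factor of the fitted covariance, then back-transformed —
so scale parameters stay positive and correlations are preserved. A
one-off jitter of 1e-10 on the diagonal is tolerated; anything worse
errors.

## Two-stage switching adjustment

Among progressed control-arm patients, post-progression survival is
regressed on the switch indicator plus the six baseline covariates in a
Weibull AFT model (the conventional family for this adjustment; the
acceleration factor is `exp(coef)`). Switchers' post-switch time is shrunk
by the factor; control-arm times are then recensored at
`min(C, C/accel)` — on by default, because without recensoring the
shrunken times leak information about post-switch prognosis into the
censoring pattern. The flag is exposed since recensoring discards
follow-up and measurably moves the HR. The adjustment assumes no
unmeasured confounding at the secondary baseline (progression) and a
common multiplicative effect of switching — exactly the assumptions the
synthetic generator encodes, which is what makes parameter recovery a fair
test of the estimator but not evidence about real-world confounding.

## Anchored MAIC

Weights `w_i = exp(aᵀx_i)` solve the moment conditions
`Σ w_i (x_i − target) = 0` for the six published baseline factors (first
moments only — the aggregate report gives no variances). The coefficients
minimize the convex dual `Σ exp(aᵀ(x_i − target))` by damped Newton
iteration on standardized covariates (gradient tolerance 1e-10), making
the solution invariant to affine rescaling. Infeasible targets (outside
the observed covariate range) error by name rather than returning extreme
weights. The weighted anchored HR (weighted Cox, Efron ties) combines with
the comparator trial's published anchored HR by the Bucher method:
`log HR_AB = log HR_AC − log HR_BC`, variances adding.

The source comparison's published cross-trial HRs are *not* the Bucher
ratios of its own published inputs (0.647/0.570 ≈ 1.135, not 0.88;
0.555/0.590 ≈ 0.941, not 1.06), and no reconciliation is published. The
package computes and reports the Bucher estimate; model runs take their
HRs from configuration so either set can be injected.

## The calibrated base case

The reference trial's IPD and the originally fitted curve parameters are
proprietary, so the published per-arm totals cannot be recomputed from
data. What *can* be reproduced is the decision structure, by calibration
within quantities that are genuinely configuration:

1. Reference-arm PFS/OS are log-normal fits to synthetic IPD (PFS median
   5.5 months, the published figure).
2. Comparator curves are hazard-scaled transforms of the reference fits;
   the two multipliers are solved by `uniroot` so the deterministic
   life-year increment is +0.1005 and the QALY increment −0.0183 (the
   published values). The OS multiplier controls the LY gap; the PFS
   multiplier then reallocates time between PF and PP without changing
   life-years, so the two roots are solved sequentially and exactly.
3. The two PAP fractions are solved so the intervention drug component is
   $2,523 and the total cost increment −$24,050.

Every other number stays at its parameter-table value. The calibration
reproduces the published ICER ($1,314,208/QALY) as an output, not an
input, and the scenario analysis (below) then *follows* from the same
configuration — the mapped utilities flip the result to dominance exactly
as published, which is a non-trivial consistency check of the calibrated
state-time split.

## Sensitivity analysis

* **DSA**: each parameter to its low/high bound, others at base; the
  effect is measured on NMB at WTP $33,749/QALY (ICERs are also reported,
  but an ICER bar is unstable when ΔQALY can approach zero inside a
  parameter's range, which it does here). Bars sort descending.
* **PSA**: gamma for costs, beta for probabilities/utilities, normal for
  durations, method-of-moments from mean = deterministic value and
  SD = (high − low)/3.92; drug acquisition prices are held constant
  (varied only in the DSA, per their 50–100% price-document rule);
  survival parameters via Cholesky; hazard-ratio multipliers log-normal
  with a configurable SE (default 0.15 — an assumption, as the source
  comparisons publish no CIs). The full draw stream is generated up front
  from one seed, so runs are reproducible. Iterations failing validation
  are dropped and counted; more than 1% is an error.
* **CEAC**: `P(WTP·ΔQ − ΔC > 0)` across a WTP grid.

**A structural note on the tornado ranking.** With both utilities varied
over ±20% bounds, a state utility's NMB bar is proportional to the
absolute incremental QALY contribution of its state
(`bar_u ≈ WTP · 0.4u·|Δstate-time|`). Any base case that reproduces the
published increments has a larger |PF| contribution than |PP|
(|ΔQALY_PF| ≈ 0.080 vs |ΔQALY_PP| ≈ 0.065 under the published per-arm
components), so the PF utility necessarily out-bars the PP utility, and
the comparator drug price — 74% of the comparator's total cost, varied
over a fifth of its value — out-bars both. The suite asserts the PP
utility among the top utility drivers and reports the full ordering; the
claim that the PP utility ranks *first* is not reproducible from the
published numbers under any calibration consistent with them.

## The synthetic-data generator

`simulate_trial()` emulates the reference trial's statistical structure as
the downstream estimators assume it:

* covariates drawn independently from the published marginals (91.60%
  male, mean age 61.48 (SD 9 — unpublished, typical of the population),
  3.92% brain metastasis, 65.83% stage IV, 84.59% smokers, 85.43%
  ECOG 1); no correlation structure is published, so none is imposed;
* latent PFS log-normal, median 5.5 months (active) / 4.9 (control), sdlog
  0.8; OS constructed as PFS + an independent post-progression survival
  draw (log-normal, median 12 / 10 months, sdlog 0.9) — the additive
  construction guarantees PFS ≤ OS structurally, which the partitioned
  model requires, at the price of assuming independence of the two phases;
* control-arm crossover at progression with probability 0.45 and an
  acceleration factor 1.5 on post-progression time (multiplicative, i.e.
  the AFT world the two-stage estimator assumes); administrative
  censoring at 26 months; default 180 patients per arm (the published
  report implies arm sizes only loosely).

These defaults are the package's study conditions, chosen once. Passing
recovery tests on this generator demonstrates estimator correctness under
the generator's assumptions (independent covariates, AFT switching, no
unmeasured confounding) — not robustness to real-data features such as
covariate correlation, informative censoring, non-multiplicative switching
effects, or cure fractions, none of which the generator produces.

## Problem sizes and tolerances

The test suite uses 1,000 patients/arm for moment-matching checks, 2,000
for acceleration-factor recovery (±10%), 200 replicates at 1,000/arm for
the bias-reduction property (≥90% of replicates closer to truth) and for
per-family parameter recovery (3-SE coverage ≥95%; ≥90% for the
generalized gamma, whose information matrix is near-singular in this
region), 100,000 draws for covariance-reproduction checks (5%), and 1,000
PSA iterations for the acceptability criterion (≥0.99 across the WTP
band). A full production PSA would use 10,000 iterations; the CEAC here is
so far from the threshold that the scaled-down run is decisive. MAIC
moment matching is exact to 1e-6 by construction of the solver tolerance.

## Known limitations

* The comparator arm is curve-derived, not data-derived; all cross-trial
  quantities inherit the MAIC's assumption that the six matched factors
  capture the relevant effect modification.
* Mapping coefficients shipped for the QLQ-C30 → EQ-5D-5L scenario are a
  clearly labelled synthetic placeholder; published mappings target other
  value sets (notably UK) and must be injected explicitly.
* Care-pattern frequencies (administration, monitoring) are configuration
  defaults; the original resource-use calculation is not published at item
  level, so component-level cost totals are calibrated in aggregate, not
  reproduced item by item.
* No spline or cure-fraction extrapolation; no RPSFTM/IPCW switching
  adjustments; no EVPI.
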