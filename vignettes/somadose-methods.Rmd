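---
title: "Modelling the dose-IGF-I response of once-weekly growth hormone replacement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the dose-IGF-I response of once-weekly growth hormone replacement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adults with growth hormone deficiency (AGHD) receive GH replacement that
is titrated per patient against serum IGF-I, expressed as a standard
deviation score (SDS) relative to an age- and sex-matched healthy
reference distribution, with the usual treatment target in the upper
normal range (roughly 0 to +2 SDS).  Somapacitan is a long-acting,
albumin-binding GH derivative given once weekly; somatropin is daily
recombinant GH.  `somadose` models the chain

dose &rarr; drug exposure &rarr; IGF-I concentration &rarr; IGF-I SDS

at the individual and population level, so that questions that matter
clinically — what starting doses by patient group achieve, how large the
weekly IGF-I swing is and when to sample it, what a delayed or missed
dose costs, how much more somapacitan than daily GH a switching patient
needs — can be answered by simulation.  Individual patient data from the
trials behind these questions are not public, so the package pairs the
model with (i) a calibration stage that anchors a reference parameter
set to published group-level results and (ii) a synthetic virtual-trial
generator for testing every stage without any external data.

## Structural model

**Pharmacokinetics.** One-compartment disposition with first-order
absorption from the subcutaneous depot and parallel linear plus
saturable elimination:

$$\frac{dA}{dt} = -k_a A, \qquad
V\frac{dC}{dt} = k_a A - CL\,C - \frac{V_{max} C}{K_m + C}.$$

The saturable term stands in for receptor-mediated clearance.  With
$V_{max}=0$ the model is linear and closed-form Bateman superposition
applies; this linear limit is used for the packaged reference set, since
the published group-level results do not constrain the saturable term,
and it is what makes 20&#8239;000-subject simulation loops cheap.  The
saturable pathway remains fully implemented (solved with `deSolve`) and
is exercised by the test suite.

**Pharmacodynamics.** An indirect-response (turnover) model in which
drug stimulates IGF-I production through a Hill function:

$$\frac{dR}{dt} = k_{out} R_0\left(1 +
\frac{E_{max} C^{\gamma}}{EC_{50}^{\gamma}+C^{\gamma}}\right) - k_{out} R.$$

Given a concentration series, this equation is linear in $R$, so the
package never integrates it with an ODE solver: each grid step applies
the exact integrating-factor recurrence (`stats::filter` on uniform
grids).  A useful exact property follows from averaging the equation
over a steady-state interval: the interval-average IGF-I equals
$R_0(1 + \overline{E(C)})$ and is *independent of* $k_{out}$ — so average
response levels are pinned by potency parameters while $k_{out}$ shapes
only the within-week profile and the missed-dose dynamics.  The test
suite asserts this property; the calibration design relies on it.

**SDS transform.** The normative reference is modelled log-normally per
age and sex: `SDS = (log conc − mu(age, sex)) / sigma(age, sex)`, with
`mu`, `sigma` tabulated on a 1-year grid (ages 18–80) and interpolated
linearly, no extrapolation.  The packaged grid is synthetic (median
260 ng/mL at age 20 declining 1.2%/year, females 5% lower, log-SD 0.25,
emulating the known age decline of GH secretion); the CSV format lets
users substitute exact published normative coefficients.  Published
reference models for IGF-I use a skewed-normal family; the
two-parameter log-normal keeps the monotone bijection the analysis
needs while remaining a deliberate simplification.

## Covariates and variability

The reference subject is male, White, 85 kg, 40 years, treatment-naive;
with zero random effects he receives exactly `theta`.  Covariates enter
multiplicatively: allometric weight on CL (exponent 0.75) and V (1.0);
female sex and oral oestrogen raise CL (lower exposure per dose) and
raise EC50 (lower response per concentration), with oestrogen by far the
stronger effect; age lowers CL (higher exposure) while raising EC50 and
the baseline SDS, reproducing the pattern that older patients sit higher
at equal doses although younger patients respond more per unit exposure;
weight lowers EC50 (exponent −0.6) so that dose–response is nearly
weight-invariant even though exposure is not; race effects on CL and
EC50 are near-cancelling.  Baselines are defined on the SDS scale —
`R0 = conc_from_sds(b, age, sex)` with `b` the typical baseline (−2 SDS
at the reference, rising 0.027 SDS/year after calibration) — so baseline
IGF-I automatically tracks the normative age decline.

Inter-individual variability is log-normal and diagonal on CL, V, EC50
and R0 (variance 0.04 each before calibration, i.e. ~20% CV).  The R0
component acts *additively on the SDS scale* and is therefore symmetric
in SDS, whereas CL/EC50 variability passes through the convex
$\log(1+E)$ response and skews right.  The published starting-dose
distributions are left-skewed (far more patients below −2 than above
+2), which is why the calibrated variability is dominated by the
baseline component — and why the model cannot be made exactly as
left-skewed as printed (see Limitations).  Baseline spread of 0.8 SDS
corresponds to the 0.2 log-scale SD through the reference log-SD 0.25;
per-subject baseline variability is carried entirely by this random
effect rather than by a separately truncated baseline draw (the mass
below −4 SDS that truncation would remove is ~0.6%).

Residual error is proportional for concentrations (20% CV) and additive
on the SDS scale for IGF-I (0.30 SDS), with concentrations below
0.002 mg/L flagged as below quantification, never dropped.

## Calibration

`calibrate_mean_curves()` adjusts {EC50, Emax, R0, oestrogen-CL effect,
age-CL effect, age-baseline slope} by weighted least squares so that the
group-mean dose–response curves cross 0 and 2 SDS at the published doses
(weights inverse to dose; the oestrogen 2-SDS crossing enters as a
one-sided penalty at the 8 mg/week cap; a ridge of 1e-3 toward the
initial values keeps the 6-parameter/5-anchor problem well posed).
Group-mean curves are defined as covariate-typical subjects — a
sex-balanced pair at ages 45 or 70 and mean weight 75 kg for the age
groups, a 40-year-old female for the oestrogen group — rather than
population averages of individual curves: this matches the reading of
mean predicted dose–response lines while keeping calibration
deterministic.  Inside the optimiser, curves are evaluated on a fixed
41-point log-dose grid with crossings interpolated in log dose; the
final residual check re-solves each crossing with a root finder and
requires residuals at or below 0.1 mg/week.

`calibrate_iiv()` rescales the random-effect SDs with two factors — one
on the symmetric baseline component, one on the multiplicative
components — against the two *low* starting-dose tail anchors (10%
below −2 SDS, 1% above +2 SDS) using a fixed 20&#8239;000-subject
common-random-numbers population.  The lower tail is hit exactly by
root-finding the baseline scale; the multiplicative scale is then chosen
on a coarse grid to best approach the upper-tail anchor (the attainable
surface is nearly flat in it).  The higher starting-dose distribution is
never fitted and serves as a genuine cross-prediction.

`calibrate_somatropin()` builds the daily comparator from the calibrated
weekly set (shared covariate effects, variability, baseline, Emax),
root-finds the somatropin EC50 so the group-mix average SDS at
0.289 mg/day matches somapacitan at 2.364 mg/week (the two printed mean
maintenance doses; tolerance 0.02 SDS), then root-finds the somatropin
turnover rate so that 3 missed daily doses cost 0.4 SDS averaged over 14
days.  Because the interval-average is independent of `kout`, the two
tunings cannot interfere.  The somapacitan `kout` stays at its design
value of 0.7/day, so the somapacitan 3-day-delay deficit (~0.1 SDS) and
the ~2-day SDS peak are predictions, not fitted quantities.

## Scenario semantics

*Average SDS* is the trapezoidal time average of the SDS trajectory over
one steady-state interval (SDS first, then average), consistent with the
day-3–4 sampling logic operating on SDS.  *Steady state* for the
reported profile means run-in until successive intervals differ by less
than 0.1% in relative L-infinity norm (cap 52 intervals); the
population-scale engines use the exact periodic solution of the linear
model, which agrees with the run-in definition to ~1e-4 and is checked
against it.  *Missed-dose deficits* delay one weekly somapacitan dose
(schedule resuming on planned days) or skip consecutive daily somatropin
doses, and average the paired difference from the uninterrupted profile
over 14 days from the planned dosing day; both trajectories share their
full history up to the perturbation, so run-in residue cancels.  The
default deficit summary is the deterministic Table-2 group-mix weighted
average over the covariate-typical subjects (57% under-60, 21.2%
over-60, 21.8% oestrogen); a per-subject mode is available through the
`cov`/`eta` arguments.  *Titration* uses the target range (−0.5, 1.75),
four biweekly visits, observations 3 days after the pre-visit dose with
the PD residual noise, and a surrogate step table (0.5 / 1.0 / 1.5 mg
per week for deviations up to 1, up to 2, beyond 2 SDS outside the
range; somatropin steps scaled by the weekly-to-daily ratio and rounded
to 0.05 mg) — the trials' exact per-protocol adjustment table is not
published, so only the step range is matched.

## Estimation

`fit_population()` maximises a per-subject Laplace approximation to the
marginal likelihood: the empirical Bayes mode is found by a damped
Gauss-Newton iteration whose gradient includes the eta-dependence of the
proportional residual SD (the fixed point is the true joint mode; a BFGS
fallback guards non-convergence), and the curvature at the mode is the
Gauss-Newton Hessian plus the prior precision — exact whenever the
observation mean is linear in the random effects, which is also the
regime where Laplace itself is exact; the test suite verifies equality
with the closed-form marginal likelihood on random linear-Gaussian
models at 1e-8.  Positive parameters are optimised on the log scale,
covariate coefficients untransformed; bioavailability is fixed (only
F·dose is identified from extravascular data, which the tests assert);
below-quantification concentration records are excluded so affected
subjects contribute IGF-I likelihood only.  The outer optimiser is
Nelder-Mead with a relative-change stop of 1e-6, warm-starting every
subject's mode between evaluations; an optional first pass on an evenly
spaced subject subsample (`stage1_n`) locates the optimum cheaply before
the full-data fit.  The simulation-estimation round trip in the test
suite uses 100 virtual subjects on a 12-week sparse design (~8 PK and
~9 IGF-I samples per subject, including near-peak day-2, trough day-6.5
and titration day-3 offsets plus a naive baseline sample) and recovers
CL, EC50 and R0 within a few percent; these problem sizes keep the full
suite within a desk-scale run.

## The virtual-trial generator

`generate_demographics()` draws age and weight from truncated normals
(46.5 ± 15.1 years on 19–77; 75 ± 21.5 kg on 34.5–150.5), sex at 50.6%
female, oral oestrogen among females at the rate implying 21.8% overall,
race at 63 / 28.2 / 8.8% and 68.2% treatment-naive.  The over-60
fraction emerges from the age distribution (~19%) rather than being
forced to the printed group split (21.2%), which the stated age
distribution cannot quite produce; deterministic group-mix summaries use
the printed split.  `generate_trial()` runs titration per subject,
perturbs the dosing diary with 1–3-day delays on 8% of doses, simulates
the full trajectory, and samples the design offsets with residual noise
and BQL flagging; at the default 34-week design and n = 330 this yields
on the order of 5&#8239;000 observations of each type.  What the
generator does *not* emulate: dropout, adverse-event-driven dose
reductions, anti-drug antibodies, assay harmonisation between IGF-I
platforms, clinician deviation from the titration algorithm, and any
within-subject time-variation of covariates.  Tests passing on these
synthetic trials therefore demonstrate internal consistency of
model + estimator + calibration, not fidelity to any real dataset.

## Numerical choices

Steady-state interval grids use 241 points; trial simulation grids use
one-seventieth of the dosing interval; missed-dose grids 0.02 day
(weekly) or 0.01 day (daily).  Convergence: steady state 0.1% L-infinity
(52-interval cap; at a clinically meaningful resolution of 0.05 SDS the
reference profile converges within 2 weekly doses, which the suite
checks separately); inner mode tolerance 1e-5 on eta (the Laplace value
is second-order insensitive to mode error); outer relative change 1e-6.
Ties in `profile_tmax` break to the earliest time.  Crossing doses
interpolate linearly in log dose; targets outside a curve's range return
explicit `above_max` / `below_min` sentinels (the oestrogen curve at
2 SDS is the real case).  Degenerate inputs are legitimate: zero dose
gives flat baseline profiles, zero variances give zero random effects
and degenerate (0/1) tail fractions, an empty regimen gives zero
concentrations everywhere.

## Known limitations

The structural surrogate (one-compartment, single turnover compartment,
log-normal SDS reference) was chosen for identifiability from
group-level anchors, not estimated from patient data; absolute parameter
values should not be read as estimates for the real drugs.  The
within-group SDS distribution cannot be left-skewed under this model
(symmetric baseline plus convex response), so while the calibrated set
reproduces the 10% lower tail exactly and the higher-dose tails as
cross-predictions, its low-dose *upper* tail is ~2–3% rather than the
printed ~1%.  The somatropin turnover rate that reproduces the 0.4-SDS
missed-dose deficit (about 0.37/day) implies re-entry into a 0.05-SDS
band roughly 6–7 days after resuming dosing, slower than the published
3–4-day description — under first-order turnover the 14-day deficit and
the recovery time cannot both be matched, and the deficit anchor takes
precedence.  Switched patients are initialised at SDS 0 rather than at
their individual prior-treatment steady state.  Two-compartment
kinetics, mechanistic albumin-binding (target-mediated) disposition,
pediatric dosing and non-subcutaneous routes are out of scope.
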