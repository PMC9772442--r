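---
title: "Methods: the joint VEN/ODV population model in venpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the joint VEN/ODV population model in venpk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venpk)
```

This vignette records the modeling assumptions, numerical choices and
design decisions behind `venpk`, at the level of detail a maintainer or a
reviewer of a population-pharmacokinetic analysis would want.

## Structural model and its assumptions

Venlafaxine (VEN) is given orally and absorbed from a depot at a first-order
rate $k_a$.  A fraction $F_P$ of the absorbed amount is converted to
O-desmethylvenlafaxine (ODV) before reaching the systemic circulation; the
rest enters a one-compartment VEN disposition space.  Both analytes use
one-compartment disposition — the pragmatic choice for data dominated by
sparse troughs, even though richer intravenous data would support more
compartments.

A key identifiability decision: *all* systemic elimination of VEN is
treated as conversion to ODV, i.e. the VEN elimination rate constant is
$k_p = \mathrm{CL}/F \div V/F$ and no separate exit path exists.  After
oral dosing with only plasma concentration data, the formed fraction of a
metabolite is not identifiable; folding it into the apparent metabolite
parameters ($\mathrm{CL}_M/F$, $V_M/F$) is the standard constraint.  Under
this reading the published healthy-subject half-life of VEN follows
directly as $\ln 2 \cdot V/F \div \mathrm{CL}/F = 5.4$ h, which is how the
package computes it.  The molar mass correction VEN→ODV is deliberately
omitted for the same reason — it is absorbed into the apparent metabolite
parameters.

Units: dose amounts are mg of the labeled venlafaxine hydrochloride dose,
volumes are L, times are hours, and concentrations are ng/ml (amount/volume
scaled by 1000).

Typical values (the defaults of `default_structural_params()` and of the
synthetic-data generator) are the final-model estimates of the joint
analysis: CL/F 80.9 L/h, V/F 628 L, CL~M~/F 22.1 L/h, V~M~/F 238 L,
$k_a$ 0.63 1/h (fixed in estimation, pre-estimated externally), $F_P$
0.048.

## Closed-form evaluation

The amount system is a linear cascade with rates $k_a, k_p, k_m$, so
single-dose amounts are sums of exponentials.  The implementation writes
them in terms of stable divided differences of $e^{-\lambda t}$:
first-order differences via `expm1` (never subtracting nearly equal
exponentials) and a second-order divided difference for the metabolite.
Node confluence ($k_a \approx k_p$, and any other near-degeneracy within a
relative $10^{-7}$) switches to the analytic limit forms
($t e^{-\lambda t}$, $\tfrac{t^2}{2} e^{-\lambda t}$), so profiles are
continuous through the degeneracies — including the L'Hôpital form of the
Bateman equation at $k_a = k_p$.

Repeated dosing superposes per-dose contributions.  For dose trains the
per-exponential geometric sums are used, and at steady state each
exponential term carries the accumulation factor
$1/(1 - e^{-\lambda\tau})$.  When rate constants are too close for the
coefficient representation (relative gap below $10^{-4}$), the code falls
back to explicit truncated superposition with the confluent single-dose
forms.  A steady-state event record *resets* the system: it represents an
established dosing train, and the most recent such train (plus later
discrete doses) governs predictions — the usual event semantics for
therapeutic-drug-monitoring records, where each visit is recorded as a
steady-state dose with the trough sampled at the end of the interval.

The user-facing predictors raise a numerical error when
$\lambda\tau$ underflows the accumulation factor; the estimation code
paths instead cap the factor, so that a transient optimizer excursion
yields a huge-but-finite objective value that is simply rejected.

`amounts_ode()` integrates the same system with `deSolve::lsoda` (plus a
cumulative-elimination state for mass-balance checks) and serves as the
independent oracle: the test suite requires closed-form/ODE agreement to
$10^{-6}$ relative over randomized parameter draws, in the spirit of the
six-significant-digit integrator precision used in the original analysis.

## Statistical model and FOCEI implementation

Between-subject variability is log-normal on the four disposition
parameters (diagonal $\Omega$; the reported model lists no covariances),
and residual error is proportional per analyte.  One deliberate
interpretation: the reported variability magnitudes (0.219/0.106/0.156/1.38
between subjects; 0.123/0.101 residual) are used as *variances*
($\omega^2$, $\sigma^2$), the conventional reporting scale of
population-PK estimation software, even though the source table labels the
column "%CV".  Nothing else reproduces the reported uncertainty ladder
coherently.

The mixture/combined residual option mentioned in passing in the source
analysis is not reproduced: the reported final model lists proportional
errors only, so the package implements proportional error with a small
additive floor (`add_sd`, default $10^{-4}$ ng/ml).  The floor exists for a
numerical reason: retained pre-dose records predict exactly zero, where a
purely proportional variance would be singular.  Rows with structurally
zero predictions then contribute a parameter-independent constant to the
objective and nothing to any gradient.

The FOCEI objective follows the standard construction.  Per subject, the
inner (conditional) problem

$$\min_\eta \sum_j \left[ \frac{(y_j - f_j(\eta))^2}{h_j(\eta)} +
\log h_j(\eta)\right] + \eta^\top \Omega^{-1} \eta,
\qquad h_j = \sigma^2_{a(j)} f_j^2 + \text{add}^2$$

is solved by a damped Gauss–Newton method with finite-difference
Jacobians of $f$ (central, step $10^{-4}$ on the eta scale), Levenberg
regularization and an Armijo line search, to a gradient infinity-norm of
$10^{-6}$.  Because the interaction term $\log h(\eta)$ has nonzero
gradient at $\eta = 0$ even when observations equal the typical
predictions, the mode is not exactly zero for perfect data — a property of
FOCE *with interaction*, not a defect; it vanishes with $\sigma^2$.  The
solver warm-starts from the previous outer iteration's modes and falls
back to the prior mode whenever that is no worse, which prevents trapping
after wild outer excursions.  Subjects with no retained observations are
skipped.

With $G_i = \partial f_i/\partial\eta$ at the mode, the subject
contributes $\log|C_i| + r_i^\top C_i^{-1} r_i$ where
$C_i = G_i \Omega G_i^\top + \mathrm{diag}(h_i(\hat\eta))$ and
$r_i = y_i - f_i(\hat\eta) + G_i \hat\eta$; the $n\log 2\pi$ constant is
omitted.  A non-positive-definite $C_i$ receives a $10^{-10}$ ridge with a
warning counter.  The suite checks this approximation against 64-node
adaptive Gauss–Hermite quadrature on single-eta subjects (agreement within
0.5 objective units) and against an extended-least-squares closed form at
$\Omega = 0$.

The outer search runs on an unconstrained scale — log for positive
parameters, logit for $F_P$, $\log(1+\theta)$ for categorical covariate
coefficients (keeping $1 + \theta > 0$) — with `nlminb`, finite-difference
gradients, and box bounds $\omega^2 \le 50$, $\sigma^2 \le 10$ that only
exist to keep degenerate excursions finite.  Two gradient profiles are
provided: central differences (default; accurate near the optimum) and a
`fast` profile (forward differences, relative objective tolerance
$10^{-5}$) for covariate screening, where objective differences only need
to be resolved against likelihood-ratio thresholds of 6.63/10.83.  A newly
added covariate coefficient is presolved one-dimensionally before the full
refit.  `nlminb`'s "false convergence" diagnostic is common at
finite-difference noise level and is reported in the fit message while the
best iterate is returned.

Standard errors come from the inverse of half the central
finite-difference Hessian of the objective on the natural parameter scale
($\mathrm{RSE}\% = 100\,SE/|\hat\theta|$); a non-positive-definite Hessian
triggers a case-resampling bootstrap fallback (default 50 subject-level
replicates, flagged in the output).  Fixed parameters ($k_a$) report `NA`.

## Dataset dialect and quantitation-limit rules

Datasets are CSV event streams (`ID,TIME,EVID,AMT,DVID,DV,MDV,SS,II,ADDL,
BLQ` plus covariate columns), a minimal NONMEM-compatible superset; floats
are written at full round-trip precision.  Assay limits are kept per
health-status/analyte pair because the two designs used different assays:
0.2–200 ng/ml (healthy VEN), 4–400 ng/ml (patient VEN), 20–2000 ng/ml
(patient ODV).

The quantitation rules mirror the two designs.  Healthy (intensive) data:
below-LLOQ values in the absorption phase are retained as zero with the
BLQ flag set; below-LLOQ values in the elimination phase are excluded.
The absorption phase is not defined in the source text, so the package
uses the closest operational reading: an observation is absorption-phase
if its time does not exceed the time of the maximum observed concentration
of that analyte in that dosing interval (ties count as absorption phase).
Patient (TDM) data: values outside the quantitation range are excluded.
The operation is idempotent, and the exclusion report conserves counts.

## Covariate engine

Categorical covariates enter as $TV(1 + \theta X)$ with signed $\theta$
(a reported "61.7% decrease" is $\theta = -0.617$); continuous covariates
as $TV (X/\mathrm{ref})^\theta$ normalized to the pooled median.  The
candidate grid crosses {health status, formulation, sex, age, weight,
smoking, drinking, six comedications} with the four disposition
parameters, *except* morbid state on the metabolite parameters: the
healthy arm contributes no ODV observations, so a morbid effect on an ODV
parameter is structurally confounded with the parameter itself.  Effects
on $F_P$ and $k_a$ are not searched by default (the grid is configurable).

Forward inclusion accepts the candidate with the largest objective drop
strictly above 6.63 ($\chi^2_1$, $p<0.01$); ties break lexicographically
on (parameter, covariate) for reproducibility.  Backward elimination is
iterative: the weakest retained effect is removed while its removal raises
the objective by no more than 10.83 ($p<0.001$).  The published procedure
describes removals "independently"; iterative elimination is the field
standard, satisfies the same boundary behavior, and the first backward
round of the trace is exactly the independent-removal table.  Only effects
added during the forward phase are subject to elimination.

Within one search, fits are cached by the set of covariate labels, so a
model revisited during backward elimination reuses the forward-round fit
verbatim.  Besides saving refits, this guarantees that nested-model
objective differences are internally consistent at screening tolerances —
without the cache, two fits of the same model from different warm starts
can differ by a few objective units, which is exactly the scale of the
decision thresholds.  The base model is additionally refit from its own
solution until the objective stabilizes (within 0.1) before the search
starts.

## Synthetic data generators

The generators produce datasets with the statistical structure the
analysis assumes, so that every pipeline stage is testable without any
external data.

*Intensive arm* (healthy volunteers): 24 males, single 50 mg oral dose,
two crossover periods separated by a 7-day washout (≫ 5 half-lives; no
carryover or period effect is simulated, since the bioequivalence contrast
is out of scope), 15 scheduled samples per period at 0–36 h, VEN assay
only with LLOQ 0.2 ng/ml.  Ages are uniform integers on 18–27, weights
truncated-normal 62.5 ± 6.9 kg on 54–80 kg.

*TDM arm* (psychiatric patients): 127 patients at steady state (titration
dynamics are not simulated; steady state is reached within 3–5 days of
dosing, short against TDM time scales).  Daily doses are truncated-normal
132.86 ± 64.2 mg on 25–300 mg, rounded to 12.5 mg steps; sustained-release
patients (probability 0.8362) take one daily dose, rapid-release patients
the same daily amount split every 12 h.  Each patient contributes 2–4
trough visits of both analytes at the end of a dosing interval ± 1 h
(a late sample models a morning dose taken after sampling).  Binary
covariates reproduce the reported frequencies — by exact rounded counts by
default (`deterministic_freq`), which keeps design-dependent tests stable;
independent Bernoulli draws are available.  Laboratory covariates
(ALT/AST/BUN/CR) are drawn from the reported moments but carry no true
effect: they exist to exercise null-covariate behavior.

True parameters default to the final-model estimates, including the three
covariate effects (morbid −61.7% on CL/F; amisulpride −39.2% on CL/F and
+59.3% on CL~M~/F), so the generator doubles as the truth for recovery
experiments.  Each dataset carries its truth record (per-subject etas,
parameters, seed); identical seeds give byte-identical files.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: model misspecification (real disposition is
multi-compartmental; real error has assay structure), nonadherence and
dosing-history errors in TDM records, covariate correlations (covariates
are sampled independently), enzyme-phenotype strata, and visit-level
dependence beyond the shared subject etas.

## Diagnostics

`gof_table()` reports PRED (covariate-adjusted typical prediction, etas at
zero), IPRED (prediction at the empirical-Bayes modes) and CWRES — the
FOCEI residual $y_i - (f_i(\hat\eta) - G_i\hat\eta)$ decorrelated by the
inverse symmetric square root of $C_i$.  At $\Omega = 0$ with proportional
error this reduces exactly to $(y-f)/(\sigma f)$.

`npde()` simulates `K` replicates of the whole population (re-drawing etas
and residual errors at the observed design; `K` defaults to 1000, floor
100), decorrelates observed and simulated vectors per subject with the
inverse Cholesky factor of the empirical simulation covariance (both
analytes stacked in one vector), and maps the rank fraction of each
observation among its replicates through the standard-normal quantile.
Rank fractions of 0 or 1 are clamped to $1/(2K)$ and $1-1/(2K)$.  A
singular empirical covariance is shrunk toward its diagonal (escalating,
with a warning).  Observations whose replicates are all identical —
structurally fixed values such as pre-dose zeros — get `NA` and are
excluded from the summary statistics (mean, variance, t-statistic, and a
Shapiro–Wilk test, or Kolmogorov–Smirnov beyond 5000 points).
`diagnostic_export()` writes four GOF and four NPDE panels per analyte as
deterministic TSV files, with optional rendered figures.

## Experiment sizes used by the test suite

Simulation-backed tests state their sizes explicitly; they are the
package's own choices, made once:

- *Parameter recovery*: one combined dataset at the full design
  (24 + 127 subjects, seed 978202), refit by FOCEI; recovered values are
  required to land within ±3 standard errors of the generating values,
  with SEs anchored at the reported relative-standard-error ladder
  (5.8–33.1%).
- *Selection consistency*: 20 replicate stepwise searches on a scaled
  combined design — 8 intensive subjects with the full two-period
  sampling schedule, the full 127-patient arm with 2–3 visits — over a
  focused candidate grid (the three true effects plus a null covariate).
  The intensive arm is scaled because it only anchors the healthy/patient
  contrast (at the cost of making the morbid-state objective drop itself
  fluctuate near the thresholds in unlucky replicates); the full sampling
  schedule is retained because halving it opens a spurious likelihood
  mode with an inflated first-pass fraction; and the patient arm is kept
  whole because the amisulpride effects draw all their information from
  the 7 exposed patients.
- *Diagnostic calibration*: NPDE with $K = 1000$ on twenty 30-patient
  replicates; CWRES calibration on one 100-patient replicate.
- Oracle comparisons run on single-subject toys (quadrature, grid search)
  and 100 random parameter draws (ODE agreement).

A note on power: with only 7 of 127 patients on amisulpride and the
reported variability, the expected objective drop for the
amisulpride→CL~M~/F effect is close to the 6.63 inclusion threshold, and
its retention at the stricter 10.83 backward threshold is far from
certain.  Replicate searches therefore recover {morbid→CL, amisulpride→CL}
reliably but the full three-effect model only in a minority of runs —
an honest reflection of the design's information content rather than a
defect of the search, and the main caveat when transporting the reported
covariate model to other datasets.

## Known limitations

- One-compartment disposition for both analytes; no N-desmethyl
  metabolites; no nonlinear kinetics.
- Diagonal $\Omega$; no inter-occasion variability.
- FOCEI is a linearization; its known bias for very sparse/noisy designs
  is inherited (the quadrature comparison bounds it on toy problems only).
- The BLQ absorption-phase rule is an operational reconstruction of a
  tersely described procedure; alternatives (e.g. time-of-peak from the
  typical model) would reclassify a handful of samples.
- Estimation-scale bounds ($\omega^2 \le 50$, $\sigma^2 \le 10$) are
  harmless for realistic data but would bite on pathological inputs.
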