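---
title: "Methods: population-based vitamin A kinetics and isotope dilution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-based vitamin A kinetics and isotope dilution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the model, the synthetic-cohort calibration, the
estimation procedure and the numerical choices behind `superchild`, and
states what the package's validation does and does not demonstrate.

## 1. The compartmental model

Whole-body retinol kinetics after an oral tracer dose are described by a
linear compartmental system with one pure transport delay:

* **Full variant.** Gut compartment 1 → chylomicron compartment 2 → delay
  component 3 (residence time `DT3`, days) → hepatic compartment 4 →
  plasma compartment 5. Plasma exchanges with the storage pool 6
  (`L(6,5)`, `L(5,6)`) and optionally a faster extravascular pool 7
  (`L(7,5)`, `L(5,7)`). Irreversible disposal leaves from the storage pool
  at `L(10,6)` per day ("compartment 10" is a notational sink).
* **Simplified variant.** The pre-delay chain is dropped and the oral input
  enters the delay directly. It is used to fit reduced data sets, whose
  sparse early samples cannot identify the chain; the absorbed fraction and
  the post-plasma kinetics are unaffected.

The delay is exact, not a chain-of-compartments approximation: everything
entering component 3 re-emerges `DT3` days later, scaled by the absorption
efficiency (default 0.80); the unabsorbed fraction is discarded at delay
exit. Because the system upstream of the delay is feed-forward, the full
solution is available in closed form: the post-delay subsystem is a
constant-coefficient linear ODE driven by the delayed upstream efflux, and
the convolution is evaluated with a block (Van Loan) matrix exponential.
An independent route integrates the same forced system with `deSolve`'s
adaptive solver; the two agree to better than 1e-8 in relative terms and
the agreement is asserted in the test suite over a grid of random valid
models, together with dose conservation (compartment contents plus
cumulative disposal plus unabsorbed loss sum to 1 at every time, tolerance
1e-6).

Steady state is solved algebraically at a fixed plasma pool `M(5)`:
`M(6) = L(6,5)·M(5)/(L(5,6)+L(10,6))`, `M(7) = L(7,5)·M(5)/L(5,7)`,
disposal `= L(10,6)·M(6)`, dietary input `U = disposal / absorption`
(balanced state). The mean sojourn time from ingestion to plasma
appearance on retinol-binding protein is the sum of the pre-plasma
turnover times (`1/L(2,1) + 1/L(3,2) + DT3 + 1/L(5,4)` for the full
variant).

## 2. The synthetic cohort ("known values")

`generate_cohort()` builds the theoretical database the validation runs
on: 50 children (23 with one extravascular pool, 27 with two), each a full
model with assigned values. Free quantities are drawn from truncated
log-normal distributions whose geometric means sit on the published
physiologic centres and whose truncation limits are the published ranges —
TBS 538 µmol (92–1904), plasma pool 1.02 µmol (0.345–2.62), dietary intake
4.07 µmol/d (2.34–16.8, i.e. 658–4862 µg RAE/d), `L(6,5)` 30.1/d
(20.1–39.9), fast-pool coefficients `L(7,5)` 31.9/d (5.40–60.9) and
`L(5,7)` 1.67/d (0.401–3.75). The log-SD of each distribution is set so
~99% of its mass lies inside the range, and the location parameter is
solved numerically so the post-truncation geometric mean equals the target
exactly. Values are assigned by stratified quantiles (one draw per
equal-probability slice, slices independently permuted across parameters),
so each child's value is still a draw from the stated distribution while
the cohort geometric means land on the published centres for every seed.

Dependent quantities come from the steady state and are therefore
consistent by construction: `L(10,6) = absorption × intake / TBS` and
`L(5,6) = L(6,5)·M(5)/TBS − L(10,6)`, with `M(7) = L(7,5)·M(5)/L(5,7)`.
When a derived value would leave its published range, the responsible free
parameter is redrawn from its distribution restricted to the feasible
interval (intake for the disposal coefficient; `L(6,5)` then `M(5)` for
the mobilisation coefficient; `L(5,7)` then `L(7,5)` for the fast-pool
mass; the hepatic turnover for the sojourn-time window 0.364–1.08 d).
This induces a moderate positive association between plasma pool and
stores — which is also what keeps the published `L(5,6)` range tight and
is physiologically sensible.

Two choices deserve explicit justification:

* **Delay time.** The first field sample is drawn 6 h (0.25 d) after
  dosing, and the geometric-mean composite requires a positive plasma
  tracer fraction from every child at every contributing time. The total
  pre-plasma lag is `DT3`, so the generator assigns `DT3` a geometric mean
  of 0.18 d truncated to [0.09, 0.24] d, placing every child's lag safely
  inside the first sample. The rest of the published mean sojourn time
  (0.522 d) is carried by the hepatic turnover `1/L(5,4)`
  (geometric mean ≈ 0.30 d) and the fast pre-delay chain
  (`L(2,1) = L(3,2) ≈ 50/d`).
* **Absorption and body weight.** Absorption is uniform on [0.70, 0.90]
  (fits hold it at the 0.80 midpoint); body weight is uniform on
  [8.5, 20.5] kg, which makes the quoted liver vitamin A concentration
  bounds (0.28–2.5 µmol/g, with liver 3% of body weight holding 80% of
  stores) attainable. Weights affect nothing else.

A `low_intake_10` preset provides 10 children with low stores
(54–114 µmol) and low-to-moderate intakes (234–585 µg RAE/d) for
sensitivity work with the full-cohort protocols.

What the generator does *not* emulate: analytical (assay) error — the
composites of protocols 1 and 2 are error-free by construction, and the
only noise in protocol 3 is between-child heterogeneity; growth,
inflammation, or intake variation over the 56-d study; and correlation
structures beyond those induced by steady-state consistency. Passing
validation here therefore shows that the design recovers truth under ideal
sampling and assay conditions, not that it is robust to measurement error.

## 3. Protocols and composite data sets

* **Protocol 1:** all 50 children at 36 times from 6 h to 56 d (the 11
  reduced times plus a grid dense through the absorptive peak and the
  terminal phase).
* **Protocol 2:** all 50 children at the 11 field times (6, 9, 12 h and
  1, 2, 4, 7, 11, 16, 22, 28 d).
* **Protocol 3:** the super-child design — all 50 children at 4 d, and 5
  children at each of the 10 remaining reduced times. Randomization deals
  a seeded permutation of the children into consecutive blocks of five,
  guaranteeing the exact 5-per-time layout; five independent scenarios are
  generated.

Each composite value is the geometric mean (antilog of the mean log) of
the contributing children's plasma tracer fractions.

## 4. Population fitting

The composite curve is fit by weighted nonlinear least squares,
minimising `Σ [(obs − model) / (fsd × obs)]²` with Levenberg–Marquardt in
log-parameter space (positivity by construction). Weights use the observed
values (`weight_on = "observed"`, switchable), with fractional SD 0.01 for
the full-cohort protocols and 0.05 (0.01 at the 4-d anchor) for the sparse
scenarios. Observations that are exactly zero carry no information under
fractional-SD weighting and are excluded. After convergence the population
steady state is solved at the cohort geometric-mean plasma pool, giving
the model-predicted TBS, dietary input, disposal rate and mean sojourn
time; parameter fractional SDs come from the Gauss–Newton approximation to
the Hessian at the optimum.

Identifiability received particular care:

* **Physiologic bounds.** The transfer coefficients are bounded to the
  known physiologic ranges (the delay to [0.05, 1] d). Unbounded, a
  sparse composite lets the fast pool drift implausibly slow so that the
  terminal slope is absorbed into a pool transient and the disposal
  coefficient collapses to zero, which inflates TBS; with two structurally
  symmetric extravascular pools the optimizer can even swap their roles.
* **Role ordering.** The storage pool is identified as the slower pool:
  candidate parameter vectors with `L(5,7) ≤ L(5,6) + L(10,6)` are
  rejected inside the objective.
* **Multistart.** Starting points are a log-space Latin hypercube over the
  physiologic ranges (default 8) plus the mid-range point; full-variant
  fits additionally presolve with the simplified model and lift its
  optimum into a full-model start (the pre-delay chain seeded at its
  typical fast turnover). The best weighted sum of squares wins.
* **Dietary-intake constraint.** For sparse super-child fits the disposal
  coefficient is, by default, not fitted freely but eliminated through the
  steady-state relation `absorption × intake = L(10,6) × M(6)` at the
  population geometric-mean intake — two samples per child cannot identify
  the terminal slope reliably, and the field design records dietary intake
  for exactly this purpose. `run_config(constrain_scenarios = FALSE)`
  restores free fitting.

**Model-order selection.** `select_pools()` fits both the one- and
two-pool variants and computes the nested-model F statistic
`[(WSS₁−WSS₂)/(p₂−p₁)] / [WSS₂/(N−p₂)]`. In field mode the extra pool must
improve the fit significantly (P < 0.05). In validation mode — when the
known group TBS is available — added complexity must improve the TBS
prediction: the variant whose predicted TBS is closer to the known value
is retained and the F statistic is recorded alongside. Because the
physiologic bounds mean the two-pool model does not strictly nest the
one-pool model, a negative WSS improvement is clamped to zero (F = 0,
P = 1).

## 5. RID coefficients and individual prediction

From any model (a child's own, or a fitted population model) the
time-variant coefficients are `Fa(t) = F(6)(t)` (tracer fraction in
stores) and `S(t) = [F(5)/M(5)] / [F(6)/M(6)]`; their product reduces
algebraically to `Fa×S = M(6)·F(5)(t)/M(5)`, an identity the tests assert
to 1e-12. Predicting a child with their *own* coefficients returns their
assigned stores exactly (to 1e-9) at every time past the lag — the
module's strongest oracle, asserted for all 50 children at all 11 reduced
times. Population prediction applies one fitted `Fa×S` to every child's
own specific activity; `rid_evaluate()` scores the percentage of children
within 25/50/75% of assigned, the ratio statistics, the least-squares
regression of predicted on assigned (slope, intercept and R² are all
reported since an anchored regression was a live design option), and the
Spearman rank correlation (t-approximation for n > 12, the exact
small-sample algorithm below that). The coefficient of variation of the
per-child `Fa×S` over time uses the arithmetic mean and SD; its minimum
over the reduced schedule falls at or after 7 d, which is why the 7-d
evaluation outperforms the 4-d one.

## 6. Numerical choices

* Matrix exponentials use an eigendecomposition fast path, falling back to
  the Padé algorithm (`Matrix::expm`) when the reconstruction error
  exceeds 1e-9 relative (repeated eigenvalues, e.g. equal chain rates).
* The adaptive-integrator route uses `lsoda` at `rtol 1e-11 / atol 1e-14`,
  started at the delay exit so no solver step straddles the discontinuity.
* Optimizer convergence tolerances are 1e-12 (relative) with up to 400
  iterations per start; multistart ties in weighted sum of squares resolve
  to the first-found optimum, and candidate vectors producing non-finite
  predictions score a large constant residual.
* Seeds: every stochastic stage (cohort assignment, scenario
  randomization, multistart draws) derives a substream from one master
  seed, kept below 2³¹; cohort generation restores the caller's RNG state.

## 7. Problem sizes and runtime

The validation operates at the study's natural size: 50 children, 36- and
11-point composites, five scenarios, eight multistarts per fit. A full
pipeline run (`run_all()`) takes well under a minute on one CPU; the
package test suite, including the end-to-end acceptance checks, runs in
about a minute.

## 8. Known limitations

* Group TBS recovery from the full-cohort composites is typically within
  ~1% but depends on the cohort realization: the geometric-mean curve of a
  heterogeneous cohort is not exactly a single-model curve, and its
  back-solved TBS can sit a few percent off the group geometric mean on
  some seeds.
* The sparse super-child scenarios remain noisy even with the intake
  constraint: single-scenario TBS deviations of 10–15% are normal, and
  the 4-d individual within-25% coverage is very sensitive to where the
  fitted composite coefficient lands relative to the right-skewed
  per-child `Fa×S` distribution (the two-pool children spread widely at
  4 d; by 7 d the pools have equilibrated and coverage improves markedly).
* Validation-mode model selection uses the known truth (deliberately,
  following the study design); field-mode selection by F-test alone is
  expected to be more conservative.
* No measurement error is modelled anywhere; see §2.
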