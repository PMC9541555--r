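---
title: "Delayed-effect population PK-PD of intravenous dabigatran"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed-effect population PK-PD of intravenous dabigatran}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dabicoag)
```

## The problem

Dabigatran inhibits thrombin directly and reversibly, so its
anticoagulant effect tracks drug concentration much more closely than
warfarin's does — yet whole-blood coagulation readouts still lag plasma
concentration by a short interval, because drug must reach its effect
site (or, in an alternative reading, because the measured response is
produced through a mediator with finite turnover). Quantifying that
concentration–response relationship, including the lag, is the purpose of
this package: it models a single-dose intravenous study in rabbits in
which plasma dabigatran (mg/L), the activated clotting time (ACT,
seconds) and the thromboelastometric reaction time (R, minutes) are
sampled at baseline and eight post-dose times over seven hours.

Because the original animal data are not publicly deposited, the package
pairs the analysis machinery with a first-class synthetic-cohort
generator: the shipped reference parameter values act as generating
truths, and recovering them from seeded simulated cohorts is the
package's acceptance surface.

## Structural models

**Disposition.** A linear two-compartment model parameterized by
clearances and volumes: elimination clearance CL, intercompartmental
clearance Q, central volume V1, peripheral volume V2. For a bolus dose
the plasma concentration is the bi-exponential
$C_p(t) = C_1 e^{-\alpha t} + C_2 e^{-\beta t}$ with hybrid rate
constants derived from the micro-constants $k_{10} = CL/V1$,
$k_{12} = Q/V1$, $k_{21} = Q/V2$. The closed form is used everywhere
(estimation loops included); a stiff ODE integration replaces it only
when the two hybrid constants coincide to within $10^{-8}$ relative
(ill-conditioned closed form) and for zero-order infusion input the
superposition form of the impulse response is used. Analytic solutions
are validated against an independent high-accuracy integrator to
$10^{-6}$ relative in the tests, and compartment amounts satisfy mass
balance (central + peripheral + eliminated = dose) to the same
tolerance.

**Size standardization.** All structural PK parameters are standardized
to a 70 kg reference by theory-based allometry,
$P_i = P_{std}\,(W_i/70)^{EXP}$ with $EXP = 0.75$ for the two clearances
and $1$ for the two volumes. The exponents are fixed constants, never
estimated. Standardization changes only the scale of the parameters —
individual predictions are identical — but makes the rabbit estimates
directly comparable with adult human values.

**Delayed response.** Both coagulation readouts follow a sigmoid Emax
model driven by a *delayed* concentration $X$:

$$E(t) = E_0 + \frac{E_{max}\, X(t)^N}{C_{50}^N + X(t)^N},
\qquad \frac{dX}{dt} = k\,(C_p - X),\quad X(0) = 0,\quad
k = \ln 2 / t_{1/2}.$$

Two interpretations of the delay are supported. In the
*effect-compartment* reading, $X$ is the effect-site concentration $Ce$,
$k$ is the equilibration rate keo, and the half-time is reported as
T1/2keo. In the *turnover* reading, $X$ is a mediator ("Cofact")
produced from plasma drug with first-order rate kin, and the half-time
is reported as TNOVER. The mediator equation adopted here —
$d\,\mathrm{Cofact}/dt = k_{in}(C_p - \mathrm{Cofact})$ with
Cofact(0) = 0 — is the minimal structure consistent with reporting the
turnover delay as $\ln 2/k_{in}$ and with the observation that the two
mechanisms give near-identical fits; the classical indirect-response
form ($k_{in} - k_{out} R$ with drug inhibition of production) is a
different model and is deliberately **not** implemented. A consequence,
verified bit-for-bit in the tests, is that the two mechanisms produce
identical predictions whenever $k_{in} = k_{eo}$ and the midpoint
concentrations agree; fitting both to the same data yields the same
objective, so the package cannot (and does not claim to) separate them
by likelihood — the choice between them is pharmacological.

For a sum-of-exponentials $C_p$ the delay equation has the analytic
solution $X(t) = k \sum_m C_m (e^{-\lambda_m t} - e^{-k t})/(k -
\lambda_m)$, with the confluent limit $C_m k t e^{-kt}$ substituted when
$|k - \lambda_m| \le 10^{-8} k$. A zero eigenvalue (constant plasma
concentration) is handled by the same formula and reproduces the
textbook half-time property $X(t_{1/2}) = C_p/2$ exactly.

**Dosing arithmetic.** The intravenous solution is prepared from a
per-mg recipe (0.060 ml of 0.075 M HCl plus 0.200 ml of 20%
N,N-dimethylacetamide per mg), scaled linearly: a 4 kg animal at
15 mg/kg receives 60 mg in 15.6 ml. The ~15 s manual injection is
modelled as an instantaneous bolus by default — the first sample is at
5 min, where the distinction is negligible — with a configurable
zero-order infusion available.

## Statistical model and estimation

Between-subject variability is multiplicative log-normal:
$P_i = P_{std}\,(W_i/70)^{EXP} e^{\eta_i}$,
$\eta_i \sim N(0, \omega^2)$, applied to CL, Q, V1, V2 and, on the PD
side, to $C_{50}$ and the delay half-time. Reported CV% values are
interpreted as $\omega = CV/100$ directly on the log scale (the standard
small-CV convention). Residual error combines additive and proportional
components per channel, $y = f(1 + \epsilon_p) + \epsilon_a$, so the
observation SD is $\sqrt{\sigma_a^2 + \sigma_p^2 f^2}$, evaluated at the
subject's conditional prediction (eta–epsilon interaction).

The marginal likelihood is approximated by the Laplace method: for each
subject the joint deviance is minimized over $\eta$ (quasi-Newton,
warm-started across outer iterations from the previous conditional
modes), and the curvature term uses the Gauss–Newton approximation
$J^\top V^{-1} J + \Omega^{-1}$ with $J = \partial f/\partial \eta$ by
finite differences — the same linearization family as FOCE-I. This
matches NONMEM-class accuracy at desk scale but is not a bit-for-bit
reimplementation of any particular tool; on a one-random-effect toy
problem the objective agrees with adaptive Gauss–Hermite quadrature
(15 nodes) to well under 0.5 units, which the test suite checks.

All positive quantities (structural parameters, $\omega$'s, residual
SDs) are estimated on the log scale; $\omega$ is floored at $10^{-4}$
and residual SDs at $10^{-6}$ to avoid collapse. The outer optimizer is
restarted from its own optimum until successive optima agree to a
relative $10^{-3}$ on every parameter — the "three significant digits"
rule — and only then is the fit flagged converged. The objective is
$-2\log L$ including constants, so differences between nested fits on
the same data are the usual χ² statistics: an extra parameter is kept
only when the objective drops by more than 3.84 (α = 0.05, strict
inequality).

**Sequential PD fitting.** PD parameters are estimated with the
population PK quantities (structural, variability, residual) fixed at
the PK fit's values, while the concentration observations remain in the
dataset so the subject-level PK random effects are re-estimated jointly
with the PD parameters — the "PPP&D" flavour of sequential estimation,
chosen over fixing individual empirical Bayes estimates because it
propagates PK uncertainty into the PD conditional modes at modest cost.
$E_0$ and $E_{max}$ are fixed by default (100 s / 899 s for ACT,
0.4 min / 34 min for R), mirroring the reference analysis in which the
baseline and maximum are not identifiable from a single high dose;
releasing them is an option.

**Starting values.** By default the PK fit self-starts from a
noncompartmental skim (dose/Cmax, dose/AUC) refined by a naive-pooled
log-scale least-squares fit; the PD fit self-starts from a pooled
response fit over a grid of delay half-times using population PK
predictions. Simulation studies may override with perturbed truths.

**Uncertainty.** Standard errors come from the inverse finite-difference
Hessian of the outer objective; because parameters are log-scaled, the
log-SE is reported directly as SE% and the 95% CI is
$\hat\theta\,e^{\pm 1.96\,SE_{log}}$. A seeded nonparametric bootstrap
(resampling subjects) is the automatic fallback when the Hessian is not
positive definite — which does happen for variance components near their
floor in small cohorts.

## The synthetic cohort

`default_cohort()` reproduces the study conditions: 10 subjects with
weights uniform on 4–4.5 kg, one 15 mg/kg bolus, sampling at 0, 5, 15,
30, 60, 120, 180, 300, 420 min, three channels. Generating values are
the shipped reference estimates: CL 0.135 L/min/70 kg (BSV 24.7%),
Q 0.33 (7.8%), V1 12.3 L/70 kg (12.3%), V2 30.1 (10%); ACT
effect-compartment response Ce50 20.1 mg/L, N 0.66, T1/2keo 1.4 min;
reaction-time response Ce50 65.3 mg/L, N 0.80, T1/2keo 2.04 min; PD BSV
0.7% on C50 and 16.2% on the half-time. Concentration residual error is
1.31 mg/L + 0.9%; reaction time 0.116 min + 10.3%.

Two generator choices deserve comment. First, the ACT residual error:
the reference effect-compartment column pairs a 22.5 s additive
component with a 135% proportional one, which cannot be a plausible
generating magnitude (it would drown the entire signal); the simulator
therefore uses the 8.5% proportional magnitude reported for the
turnover fit together with the 22.5 s additive term, and the extreme
value remains reachable through the configuration. Second, negative
simulated observations (possible for the 0.4 min reaction-time baseline
under additive noise) are redrawn up to 100 times and then clipped to a
small positive floor — a pragmatic rule that keeps channels positive
without materially biasing means, verified by a mean-preservation check
in the tests.

What the generator does *not* emulate: assay quantification limits,
device saturation, sampling-time deviations, dropout, or model
misspecification of any kind. Passing recovery tests therefore
demonstrates that the estimation machinery is consistent under the
assumed model at the study's design and noise level — not that the model
is correct for real rabbits.

## Identifiability caveats

The ACT equilibration half-time (1.4 min) is short relative to the first
post-dose sample (5 min ≈ 3.6 delay half-lives): its information comes
from small differences between the plasma and delayed profiles during
the distribution phase, and under the reference noise magnitudes some
simulated cohorts produce a marginal likelihood that is nearly flat in
the delay — occasionally preferring a near-zero half-time outright. This
is a property of the design, not of the optimizer (multi-started fits
find the same optimum), and it is the reason the delay half-time carries
the widest recovery tolerance in the acceptance checks. The reaction
time, with its 2 min half-time and smaller relative noise, is better
behaved.

## Visual predictive checks

`run_vpc()` simulates replicate cohorts (default 500) from the fitted
model at the original design, and compares the observed 10th/50th/90th
percentiles per nominal-time bin with the simulation distribution of the
same percentiles (95% confidence band from the 2.5–97.5 percentiles
across replicates). Prediction correction rescales each value by
median(PRED in bin)/PRED, removing dose- and weight-driven differences;
with the balanced design, binning is by exact nominal times, and a
constant PRED within a bin makes the correction the identity. The
self-consistency property — data simulated from the fitted model keep
the observed median inside the band in at least 7 of 9 bins — and the
converse detectability of a ten-fold mis-specified delay in the early
bins are both exercised in the tests.

## Problem sizes used in the test suite

Deterministic model checks run on randomized parameter sets at full
tolerance. Estimation checks use deliberately compact problems chosen to
exercise every code path while keeping the default suite quick: 3–6
subject cohorts for exactness and dominance checks, a 4-subject
one-compartment toy for the optimizer-level properties (quadrature
agreement, order/unit invariance, SE consistency, and a 50-replicate
null study of the 3.84 selection rule), and one full 10-subject cohort
for the end-to-end recovery checks. The replicate-bias property is
reported at these reduced sizes in the tests; the full-size
single-cohort recovery is the acceptance surface.

## Known limitations

* Diagonal random-effect covariance only; no correlation between
  $\eta$'s, no inter-occasion variability.
* The Laplace/Gauss–Newton objective is an approximation; no SAEM or
  MCMC alternative is provided.
* The turnover mechanism is the minimal first-order-mediator reading
  described above, not the classical indirect-response model.
* No protein-binding, metabolite, renal-function or oral-absorption
  submodels, and no reversal-agent kinetics.
* Standard errors assume the asymptotic regime; with 10 subjects the
  bootstrap fallback is the more defensible summary for variance
  components.
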