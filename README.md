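# dabicoag

Population pharmacokinetic–pharmacodynamic modelling of intravenous
dabigatran anticoagulation.

Dabigatran is a direct thrombin inhibitor of interest as a heparin
alternative for cardiopulmonary bypass. Before human dosing studies, its
concentration–anticoagulation relationship can be characterized in an
intact animal model: rabbits given a single intravenous dose, with serial
measurement of the plasma concentration and two point-of-care whole-blood
coagulation readouts — the activated clotting time (ACT, seconds) and the
thromboelastometric reaction time (R, minutes). `dabicoag` implements the
full analysis chain for such a study, for pharmacometricians and
quantitative pharmacologists:

* **Structural model.** Two-compartment intravenous disposition
  parameterized as clearances and volumes (CL, Q, V1, V2), with
  theory-based allometric standardization to a 70 kg reference,
  `P_i = P_std · (W_i / W_std)^EXP` (EXP = 0.75 for clearances, 1 for
  volumes), so small-animal estimates are directly comparable with adult
  human values.
* **Delayed response.** A sigmoid Emax model,
  `E = E0 + Emax · Ce^N / (Ce50^N + Ce^N)`, driven by a delayed
  concentration that follows `dCe/dt = k (Cp − Ce)` with
  `k = ln 2 / t_1/2`. The delay is interpreted either as effect-site
  equilibration (keo) or as mediator turnover (kin); the two mechanisms
  share these dynamics and differ in interpretation and reporting.
* **Estimation.** Nonlinear mixed-effects by an approximate marginal
  maximum likelihood (Laplace approximation with a Gauss–Newton curvature
  term), log-normal between-subject variability, combined
  additive + proportional residual error per channel, and sequential
  PK-then-PD fitting in which subject-level PK random effects are
  re-estimated jointly with the PD parameters.
* **Model comparison and diagnostics.** Nested-model selection by the
  χ²(1) objective-function criterion (drop > 3.84), asymptotic or
  bootstrap standard errors, and prediction-corrected visual predictive
  checks (pcVPC).
* **Synthetic cohorts.** A seeded simulator reproducing the single-dose
  study design (10 subjects, 4–4.5 kg, 15 mg/kg IV bolus, sampling at
  baseline and 5–420 min, three observation channels) for
  simulation–estimation work; the shipped reference parameter values act
  as generating truths.

## Worked example

Simulate a cohort at the study design from the reference values, then
recover the generating parameters:

```r
library(dabicoag)

cohort  <- default_cohort(seed = 1)   # 10 subjects, 15 mg/kg IV bolus
dataset <- simulate_cohort(cohort)    # 10 dose rows + 260 observations

pk <- fit_pk(dataset, control = list(se = FALSE))
pk
#> Population PK fit
#> Estimates (standardized scale):
#>      CL       Q      V1      V2
#>  0.1520  0.3417 11.7400 30.1900
#> Between-subject variability (CV%):
#>     cl      q     v1     v2
#> 35.050  4.263  6.216  5.024
#> Residual error (conc): additive 1.161, proportional 0.003635
#> Objective (-2LL): 307.812  converged: TRUE  evaluations: 1077
```

The standardized clearance (0.152 L/min/70 kg), central volume
(11.7 L/70 kg), intercompartmental clearance (0.34 L/min/70 kg) and
peripheral volume (30.2 L/70 kg) recover the generating values 0.135,
12.3, 0.33 and 30.1 to well within the sampling uncertainty of a
10-subject cohort. The sequential PD fit then estimates the
concentration–response for the activated clotting time:

```r
act <- fit_pd(dataset, pk, readout = "act", control = list(se = FALSE))
act
#> Sequential PD fit (act, effect compartment)
#> Estimates (standardized scale):
#>    Ce50       N T1/2keo     keo
#> 20.4900  0.6611  1.4490  0.4785
#> Between-subject variability (CV%):
#>    c50 t_half
#>   2.94  40.87
#> Residual error (act): additive 32.21, proportional 0.02939
#> Objective (-2LL): 1205.712  converged: TRUE  evaluations: 808
```

Here `Ce50` (20.5 mg/L) is the effect-site concentration producing half
the maximal ACT prolongation (generating value 20.1 mg/L), `N` the Hill
coefficient (0.66), and `T1/2keo` the plasma–effect-site equilibration
half-time (1.45 min vs the generating 1.40 min — onset of anticoagulation
is essentially as fast as distribution allows). A
prediction-corrected VPC confirms the fit:

```r
v <- run_vpc(dataset, act, channel = "act", n_sim = 500, seed = 2)
plot(v, file = "vpc_act.pdf")
```

`run_pipeline(default_config(seed = 1), "run1")` executes the whole chain
(simulate → PK fit → four sequential PD fits → mechanism comparisons →
VPCs) and writes every artifact with its seeds and checksums.

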