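---
title: "Plasma-CSF pharmacokinetics of meropenem: model, simulation and estimation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasma-CSF pharmacokinetics of meropenem: model, simulation and estimation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meropk)
```

## The model and its assumptions

`meropk` implements a three-compartment linear disposition model for
meropenem in postneurosurgical meningitis patients: a central compartment
(plasma, volume `V1`), a small CSF compartment (`V2`, fixed at 0.13 L),
and a peripheral distribution compartment (`V3`). Drug enters the central
compartment by zero-order infusion. Three features distinguish it from a
plain mammillary model:

* **Asymmetric plasma-CSF exchange.** The central-to-CSF flux uses
  clearance `Q1 * PC` while the return flux uses `Q1`, i.e.
  `K12 = Q1 * PC / V1` and `K21 = Q1 / V2`. The dimensionless multiplier
  `PC` (typical value 0.172) is the CSF penetration factor: at
  equilibrium without drainage the CSF concentration is `PC` times the
  plasma concentration. Both fluxes are kept exactly as the model defines
  them; the asymmetry is the model, not an error to correct.
* **Drainage-driven CSF elimination.** Therapeutic CSF drainage removes
  drug at clearance `CL2 = drainage (L/day) / 24` in L/h, so
  `k20 = CL2 / V2`. Mass leaving the CSF compartment through drainage is
  eliminated, and the corresponding flux is debited from the system
  (full mass balance).
* **No covariates.** Clearance is not scaled by renal function or any
  other covariate; the original covariate screening retained none. The
  Cockcroft-Gault helper exists only to generate realistic covariate
  tables in synthetic datasets.

Elsewhere the model is deliberately ordinary: linear elimination
(`k10 = CL1/V1`), no protein-binding kinetics (binding enters only as a
constant 2% correction when evaluating plasma PK/PD targets), and no
saturable transport.

### The two readings of the drainage term

The drainage quantity "volume per day divided by 24" is dimensionally a
flow (L/h). Interpreting it as a clearance (`CL2`, the default here) is
the only reading under which the companion definitions
`K12 = Q1*PC/V1, K21 = Q1/V2` stay dimensionally consistent, and it is
the reading used everywhere in this package. The literal alternative —
treating the number as the rate constant `k20` itself, so that
`CL2 = k20 * V2` is 0.13 times smaller — is retained behind
`drainage_as_rate_constant = TRUE` in `pk_params()` and `pta()`, because
the choice materially changes CSF exposure at high drainage rates and a
sensitivity report should quantify that rather than bury it. The
acceptance script prints every CSF quantity under both readings.

## Exact simulation

For piecewise-constant inputs the system `dx/dt = Ax + b` is solved
exactly: within each infusion-on or infusion-off segment,
`x(t) = x_inf + e^(At) (x0 - x_inf)` with `x_inf = -A^(-1) b`. The matrix
exponential comes from an eigendecomposition of the 3x3 rate matrix; when
that decomposition is unusable (for example the closed system with all
clearances zero, which tests mass conservation), the code falls back to a
Pade matrix exponential (`Matrix::expm`) on an augmented 4x4 system.
Because the exchange topology is a tree with strictly positive
intercompartmental clearances, `A` is diagonally symmetrizable and its
eigenvalues are real; the fitting fast path (below) exploits this with a
closed-form symmetric 3x3 eigensolver, vectorized across subjects. The
generic propagator remains the reference implementation, and both paths
are cross-checked against adaptive ODE integration (`deSolve::lsoda`,
tolerance 1e-10) in the test suite at relative tolerance 1e-6.

Steady state is computed analytically as the periodic fixed point
`x* = Phi(tau) x* + g(tau)`, where `Phi` is the one-interval propagator
and `g` the single-dose response from a drug-free state; the linear solve
replaces burn-in dosing. Brute-force simulation of 30 consecutive doses
is retained in the tests as an oracle (agreement below 0.01%). With
`CL1 = 0` the fixed point does not exist and `steady_state_amounts()`
says so rather than returning noise.

Concentration profiles are evaluated on 1000 points per dosing interval.
This makes the fT>MIC resolution 0.1% of the interval, an order of
magnitude below any decision threshold used here; no root-refinement of
the MIC crossing time is attempted. "Above MIC" is a strict inequality —
immaterial for continuous distributions, fixed for determinism. For PTA
the grid uses the 1000 left endpoints of equal subintervals so that the
periodic endpoint is not double-counted; exported profiles include both
endpoints, which also provides the fixed-point invariance check.

## Virtual patients and the residual error

Between-subject variability is log-normal, `P_i = TV * exp(eta)`,
`eta ~ N(0, omega^2)` with `omega^2 = log(1 + CV^2)` — exact for a
log-normal, so the published CV is reproduced exactly rather than
approximated by `omega = CV`. BSV applies to V1 (13.2%), V2 (37.4%), CL1
(22.4%), Q1 (84.4%) and PC (39.4%); V3 and Q2 are fixed; the eta's are
uncorrelated (no correlations were reported). V2's variability is sampled
even though its typical value is fixed: the variability is part of the
published table, and fixing a typical value is not the same as denying
its variance. The observation model is arithmetic proportional error,
`y = c (1 + eps)`, `eps ~ N(0, 0.349^2)`, truncated at zero. Residual
error is applied only when generating synthetic observations and in
predictive checks — PTA is computed on the error-free individual
profiles, since the target concerns the patient's true concentration, not
an assay replicate.

## PTA machinery

A PTA value is the fraction of virtual patients whose free concentration
exceeds the MIC for at least the target fraction of the steady-state
interval (free fraction 0.98 in plasma, 1 in CSF). One cohort of 1000
patients is sampled per run and reused across every MIC, target, regimen,
infusion duration and drainage rate. This is variance reduction, but it
also makes two properties structural: PTA is exactly non-increasing in
MIC, and comparisons across scenarios are paired. Drainage is a scenario
axis (0/50/150/250 mL/day applied to the whole cohort), mirroring the
original simulation design rather than drainage observed per patient.
Continuous infusion of "dose q8h" means the total daily dose at constant
rate (2 g q8h becomes 250 mg/h), the clinical convention.

One nuance the package surfaces deliberately: "longer infusion gives
higher PTA" holds in the trough-limited regime, where attainment is set
by sustained exposure. Exactly at the capacity edge — MIC near the
continuous-infusion plateau — a finite infusion's higher within-infusion
plateau can attain a sub-100% target that continuous infusion misses, so
continuous infusion is not asserted to be globally maximal in the tests,
only superior to the shortest infusion.

The recommendation logic scores every non-continuous scenario with
drainage at or below the 150 mL/day cap by its worst-case CSF breakpoint
at PTA floor 0.90 (50% target, then the 100% target, then the plasma
breakpoint as tie-breaks, then the shorter infusion); the drainage grid
point 50 mL/day operationalizes "limited drainage", with 150 mL/day also
reported, because the original design simulated a discrete grid.

## The synthetic trial generator

`generate_study()` emulates the structure of the clinical study and is
the package's source of test data: 82 patients split 42/19/21 across
1 g q8h, 1 g q6h and 2 g q8h (all infused at 1 g/h), paired plasma and
CSF samples after the fourth dose, and two nominal-time schedules
(40/42 split): mid-infusion, 10 min, 2 h and 4 h after the end of
infusion; or end of infusion, 1 h and 3 h after it, and immediately
before the next dose. "During infusion" is sampled at the infusion
midpoint — the protocol does not pin the moment down, and the midpoint is
the unbiased choice. The four preceding doses are simulated explicitly
from a drug-free state rather than assumed at steady state, because
sampling "after the fourth dose" is not yet steady state for the slow CSF
compartment. Covariates are truncated normals with the published moments
(drainage 126 +/- 81 mL/day on [0, 350]; age 43.4 +/- 13.1 y on [19, 77];
weight 65.2 +/- 11.6 kg; 50 of 82 male), and serum creatinine is
back-solved through Cockcroft-Gault from a creatinine-clearance
distribution with the published moments — so the covariate table is
internally consistent even though no covariate enters the model.

What the generator does not emulate: dropouts and regimen switches, the
handful of concentrations the original analysis excluded (an optional
completely-at-random `missing_frac` exists but defaults to 0, since the
original missingness mechanism is unstated), assay error structure beyond
proportional noise, deviations from nominal sampling times (optional
Gaussian jitter, off by default), and any covariate effect on PK. Passing
tests on these data therefore demonstrate internal consistency of model,
simulator and estimator — not that the model is right for new clinical
data.

## Estimation: a staged naive-pooled fit

The original analysis used FOCE-I mixed-effects estimation. That engine
is a product of its own and is intentionally not reimplemented; this
package's estimator exists to demonstrate parameter recovery at the
trial's design and to drive the bootstrap and predictive-check
machinery. It is naive-pooled: one parameter vector for all subjects,
per-subject CSF clearance fixed by the known drainage covariate, `V2`
fixed at 0.13 L, positivity enforced by optimizing log-parameters
(Nelder-Mead with restarts; multi-start at 0.5x, 1x and 2x the initial
values; best optimum kept; deterministic given data and starts).

The default fit is staged, and the reason is bias arithmetic rather than
taste. Pooling data that contain BSV inflates the apparent residual CV to
~65%, and the two obvious one-shot likelihoods then fail in opposite
ways. Proportional Gaussian ML on the concentration scale carries a
`2*sum(log f)` term that rewards shrinking predictions — at 65% CV this
biased V1 and CL1 upward by roughly 23% and 12% in replicate recovery
runs. Log-transform-both-sides ML removes that term, but the arithmetic
error model `y = c(1+eps)` has `E[log(1+eps)] < 0` (about -6.5% at 34.9%
CV), which LTBS absorbs as a scale shift into V1 and CL1. The staged
default therefore fits each matrix with the form whose estimating
equation is unbiased for what that matrix must deliver:

1. **Plasma stage** (V1, V3, CL1, Q2): iteratively reweighted least
   squares with proportional weights frozen at the previous iterate.
   Its estimating equation is mean-unbiased under `E[y] = c`, which the
   arithmetic error model satisfies exactly.
2. **CSF stage** (Q1, PC): least squares on the log scale. CSF
   concentrations carry the 84.4% CV of Q1; on-scale mean-targeting
   would recover the *arithmetic mean* of a log-normal quantity
   (`exp(omega^2/2)`, about +31% at that CV), whereas the log scale
   targets the median patient — and the log-normal median is the typical
   value.

Two sweeps make the stages mutually consistent. Both one-shot
likelihoods remain available (`method = "joint"` with
`error = "lognormal"` or `"proportional"`). The optional per-subject
two-stage mode sometimes paired with naive pooling is omitted: with
eight observations and six parameters per subject under this sparse
design it is ill-posed.

Even the staged estimator is approximate where the mixed-effects engine
would not be: recovery runs in the test suite show Q1 and PC individually
recovered only to within roughly +/-30% (their product is far better
determined), because separating the transfer clearance from the
penetration multiplier rests on the within-interval shape of four noisy
CSF points per subject. The recovery acceptance test prints the full bias
table rather than hiding the weakly identified pair, and the pooled
"sigma" reported by the fit conflates residual error with BSV by
construction — it is expected to exceed 34.9% on realistic data and is
not comparable to the published residual estimate.

Uncertainty comes from a nonparametric bootstrap (subjects resampled with
replacement, refits started from the point estimate, percentile
intervals; failed refits dropped and counted). The visual predictive
check simulates replicate datasets at the observed design — new etas and
new residual errors per replicate — and compares observed 5th/50th/95th
percentile curves with the simulation bands per matrix, binned by time
after the sampled dose.

## Problem sizes and numerical defaults

Chosen once as the package's standard desk-scale settings: PTA cohorts of
1000 (the original simulation size) with 1000 grid points per interval;
recovery studies of 20 replicate trials of 82 patients; bootstrap
defaults of 1000 with 50 used by the demonstration workflow; VPC defaults
of 1000 replicates with 100 used in tests; Nelder-Mead capped at 1500
iterations per round with relative tolerance 1e-12. The end-to-end demo
(`run_demo()`) runs generate, fit, bootstrap, VPC and a reduced PTA
factorial, and is byte-reproducible for a fixed seed; every artifact
embeds the package version, a configuration checksum and the seed, and
nothing is overwritten without `force = TRUE`.

## Known limitations

* The estimator is not a mixed-effects engine: no empirical Bayes
  estimates, no shrinkage diagnostics, no covariate search, and BSV
  magnitudes are inputs rather than outputs.
* Linear PK throughout; no saturable CSF transport, no protein-binding
  kinetics, no renal-function scaling. Extrapolation beyond the studied
  population (e.g. severe renal impairment) is outside the model's
  support.
* Drainage enters as a constant per-scenario rate; real drainage is
  intermittent and clinician-adjusted.
* The PK/PD breakpoint logic evaluates discrete MIC dilutions and
  discrete drainage grid points, as the original simulations did;
  intermediate values are not interpolated.
* Concentrations of zero (possible under the truncated error model)
  carry no information under multiplicative likelihoods and are excluded
  from log-scale fitting.
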