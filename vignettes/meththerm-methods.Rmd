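---
title: "Methods: model, inference and synthetic data in meththerm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, inference and synthetic data in meththerm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meththerm)
```

## The scientific problem

Methamphetamine disturbs body temperature in a strongly dose-dependent
way: low intraperitoneal doses (~1 mg/kg) evoke mild immediate
hyperthermia, intermediate doses (~5 mg/kg) a *delayed* response, and high
doses (~10 mg/kg) immediate, robust hyperthermia. Pretreatment with the
OX1R antagonist SB-334867 modifies these responses differentially —
suppressing responses to stress and low doses while exaggerating early
responses to intermediate and high doses. Because every injection also
evokes a stress transient of its own, the early parts of the temperature
curves cannot be compared directly across groups. `meththerm` implements
the data-assimilation alternative: fit a mechanistic circuit model to the
group curves and perform statistics on its parameters.

## Model components and assumptions

**Pharmacokinetics.** Two well-mixed compartments (peritoneum, blood) with
first-order transfer and elimination give the bi-exponential concentration
curve; time is in minutes, concentration carries the dose unit (mg/kg).
The absorption constant is `tau_u` (default 8.25 min) and the elimination
constant `tau_d` (57.5 min). Single administration only; no
inter-individual variability. Two numerical points deserve note:

* the closed form is singular at `tau_u = tau_d`; within a relative 1e-6
  the implementation switches to the limiting form
  `D (t/tau_u) exp(-t/tau_u)`, avoiding catastrophic cancellation;
* the bi-exponential *shape* is symmetric under swapping the two
  constants, but the normalization of the closed form is not — swapping
  rescales the curve by `tau_u/tau_d`. The package interprets `tau_u` as
  absorption throughout, consistent with mass balance in the compartment
  system (eliminated mass plus mass still in the body equals the dose, a
  property the tests verify).

**Stress.** Each injection contributes a unit-jump exponential transient
with decay `tau_s` (10 min), treated as fixed rather than fitted. Both
injections use the same fitted amplitude `w_S`, including the injection
that delivers the antagonist itself. The antagonist has no
pharmacokinetics of its own: one parameter vector per pretreatment dose
represents its (constant) effect over the whole recording.

**Circuit.** Instantaneous rate units with activation
`sigma(x) = (1 + tanh x)/2`; no spiking dynamics, no anatomical
commitment. The drug-sensitive populations are Exc (low threshold), Inhib
(intermediate) and HD (high threshold); Exc and Inhib compete linearly on
the medullary relay, and HD feeds the premotor output directly. The fixed
weights and basal excitabilities (projections 9.89, 6.38, 5.66 °C; basal
offsets −0.357, −1.335, −3.69; premotor offset −3.35 °C) are the published
constants and are never refit.

**Baseline recentring.** With the fixed constants verbatim, the resting
premotor drive is ≈ −0.51 °C, i.e. a resting temperature half a degree
below `T0`, whereas observed baselines sit flat at `T0` and analyses are
of changes from baseline. By default the package therefore subtracts the
resting drive (equivalently, recalibrates the premotor offset) so that the
output is exactly zero at rest; `circuit.raw_gamma_spn` in the
configuration (or `recenter = FALSE`) restores the verbatim offset. The
recentring reference is always computed with *intact* inhibition, so
inhibition-failure scenarios expose the resting consequence of silencing
the inhibitory population instead of being re-zeroed around it. The
premotor drive is deliberately not rectified: negative drive represents
below-baseline temperature, which the tonic-excitation argument (about
3 °C of potential hypothermia were the tonic excitatory pathway blocked)
requires to be representable.

**Variants.** Whether antagonist pretreatment raises the HD drug
sensitivity (`w_HD`, base variant) or lowers the HD basal inhibitory tone
(`gamma_HD` variant) is empirically indistinguishable — matched at the
half-activation point, the two parametrizations produce activation curves
agreeing to better than 0.01 activity units — so both are provided and
neither is asserted correct. The `extended` variant routes the inhibitory
tone on HD through the Inhib population with weight `w_Inh_HD`; that
weight is not constrained by published values and defaults to 5.0, strong
enough that HD stays silent at intermediate doses under vehicle
parameters. The inhibition-failure cap is a hard ceiling on the Inhib
activity (a bound on maximal activity, not a rescaling); a cap of 1
reproduces the uncapped model bit-for-bit.

**Thermodynamics.** A single first-order equation with time constant
`tau_T` (89.2 min) around baseline `T0` (37 °C) collapses all effector
pathways (brown adipose tissue, muscle, vasoconstriction) into the one
premotor output.

## Numerical integration

The temperature equation is linear and non-stiff, so the classical RK4
step reduces to a scalar linear recursion in `T - T0`, which is evaluated
as a recursive filter — a full trajectory costs a handful of vectorized
operations. The drive, however, *jumps* at each injection (the stress
transient rises instantaneously), which would degrade RK4 to first order
if integrated across; integration is therefore split into segments at the
injection times, with the drive sampled one-sided at segment starts.
With the default step of 0.1 min, refining the step tenfold changes
trajectories by ~1e-9 °C, and analytic solutions (constant drive, baseline
fixed point) are matched to 1e-6 °C or better. Integration starts at
−50 min (the start of the observation window) from `T = T0`; under
recentring the pre-injection solution is exactly constant, so the start
time does not influence the response. Output is linearly interpolated onto
the requested grid.

## Inference

The posterior over the sampled parameters is the Gaussian likelihood of
the group means with the *group standard deviations* (not standard errors
of the mean) as weights, on the 2-minute grid from −50 to 180 min
(116 points per group), with an improper flat prior on the support
(sensitivities and time constants positive; stress amplitude and basal
tones unconstrained). All treatment groups sharing a pretreatment dose are
fit jointly; pretreatment doses are fit independently. Group SDs are
floored at 0.05 °C to avoid singular weights — negligible against
telemetry noise. Using SDs rather than SEMs makes the posterior
deliberately conservative (wider by roughly the square root of the group
size); the "standard error" of a parameter is the posterior standard
deviation of its ensemble, the only reading under which z-testing ensemble
means is coherent.

The sampler is a plain random-walk Metropolis–Hastings chain with
symmetric Gaussian proposals. Proposal scales adapt in blocks of 100 steps
during burn-in toward ~30% acceptance and are frozen afterwards, so
detailed balance holds for every retained sample; a warning is emitted if
the post-burn-in acceptance rate leaves [0.1, 0.6]. Defaults are 50,000
steps, 10,000 burn-in, thinning 10, seed 42; the test-suite and the
acceptance script use 3,000–20,000-step chains, sizes at which the
posterior summaries of these low-dimensional, well-conditioned posteriors
are stable. Chains are exactly reproducible under a fixed seed.

## The synthetic-data generator

The generator emulates the structure of the telemetry experiment: two
series with pretreatment (vehicle / 10 / 30 mg/kg antagonist) at −30 min
and treatment (saline / 1 / 5 / 10 mg/kg drug) at 0 min, 6–8 animals per
group (default 7), samples every 2 min from −50 to 180 min, baseline
37 °C. Noise has three components: iid Gaussian innovations (SD 0.3 °C)
driving an AR(1) process (coefficient 0.5 — telemetric residuals are
smooth, so serially correlated noise is the realistic default), plus a
constant per-animal baseline offset (SD 0.2 °C). Each animal is
re-referenced to its own pre-injection baseline by default
(`baseline_correct = TRUE`), exactly as telemetry analyses report changes
from baseline; without this, the per-animal offsets shift whole group
curves coherently, which a model with its resting temperature pinned at
`T0` must absorb into biased parameter estimates (the stress amplitude is
the most exposed). Setting the AR coefficient and offset SD to zero and
disabling the re-referencing yields the *exactly-matched iid mode* in
which the fitting likelihood is the true data-generating model; the strict
recovery checks use that mode, while default-noise fits quantify
robustness to the (deliberate) misspecification.

The default truth vectors for the three pretreatment scenarios are

```{r truths}
scenario_truths()
```

chosen once — they are configuration, not published values — so that the
reported qualitative pharmacology holds: `w_Exc` and `w_Inh` fall with
antagonist dose, `w_HD` rises (disinhibition), `w_S` falls from vehicle
with little difference between the antagonist doses, the half-activation
concentrations order Exc < Inhib < HD under vehicle, the intermediate dose
responds later than the low dose, and a 3 mg/kg dose produces no major
response with intact inhibition. What the generator does *not* emulate:
circadian drift, inter-animal variance structure beyond the stated
mean/SD summaries, activity-driven temperature fluctuations, or any
per-animal pharmacokinetic variability. Passing recovery tests on these
data therefore demonstrate the correctness and calibration of the
inference machinery, not that real telemetry satisfies the model.

## Known limitations

* The absorption constant is only weakly identified from a single
  intermediate-dose group: the delayed-response phenomenology means early
  temperature dynamics are dominated by the stress transients and the
  near-cancellation of the excitatory and inhibitory drives, so the data
  carry little information about how fast the drug is absorbed. Its
  single-group posterior is correspondingly wide and right-skewed, and
  posterior means scatter across tens of percent between noise
  realizations. Elimination, stress and temperature constants are much
  better determined.
* The likelihood treats time points as independent; with the default
  AR(1) noise this is misspecified by design (see above).
* Real-data reproduction of the published fitted curves is out of scope:
  the fitted weight values behind those figures are not printed, so the
  package asserts orderings and mechanisms, not their numeric values.
* No marginal-likelihood machinery is provided; the variant comparison
  rests on the half-activation matching argument, not on Bayes factors.

## Interface

The exported functions and this vignette are the package's interface;
analyses are scripted in R (see the README for a worked example), and no
shell entry point is shipped. Configuration files (YAML, see
`load_config()`) cover the pharmacokinetic, circuit, thermodynamic,
design, noise and sampler sections with the defaults described above.
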