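---
title: "Models and methods in petdosim"
author: "petdosim maintainers"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdosim)
```

petdosim implements the quantitative chain of a preclinical
zirconium-89 immuno-PET study in rabbits: framed time–activity curves
(TACs) with decay correction and standardized uptake values (SUV),
single-tissue-compartment (1TCM) perfusion estimation from oxygen-15
water, noncompartmental plasma pharmacokinetics of the radiolabelled
antibody, ex vivo biodistribution and autoradiograph quantification,
and rabbit-to-human residence-time extrapolation with MIRD-style organ
doses and ICRP-103 effective dose. A seedable synthetic-data module
generates ground-truth inputs for every stage, so each estimator can be
validated against known parameters. This vignette documents the models,
the defaults and the numerical choices, and what the synthetic
validation does and does not demonstrate.

## Radionuclides, decay correction and SUV

Activity measured a time $t$ after injection is referred back to
injection time by the factor $2^{t/T_{1/2}}$. The zirconium-89
half-life is taken as 3.3 d = 79.2 h by default, the rounded value used
in the study's own decay arithmetic, so that downstream quantities
(most visibly the physical residence-time bound $T_{1/2}/\ln 2$ =
114.3 h) reproduce that arithmetic; the physical 78.41 h can be passed
explicitly (`zr89(78.41)`). Oxygen-15 uses 122.24 s. No
branching-ratio correction is applied for the 76.6% positron-free
decay of Zr-89: calibrated scanners and gamma counters already report
activity, and the source data give no indication such a correction was
applied; the choice is deliberate and documented here.

SUV is $C/(A_0/W)$ with the tissue concentration $C$ in kBq/mL, the
injected activity $A_0$ in kBq and the body weight $W$ in grams,
assuming 1 g/mL tissue density (configurable). SUV requires
decay-corrected input; every TAC carries an explicit
`decay_corrected` flag and mixing corrected with uncorrected data is a
hard error, never silent.

Framed data are reduced to one representative time per frame. The
default is the frame midpoint; a decay-weighted mean time (the
activity-weighted mean of $e^{-\lambda t}$ within the frame) is
available for long frames of short-lived nuclides.

## The one-tissue compartment model

For freely diffusible oxygen-15 water the tissue curve follows

$$\frac{dC_t}{dt} = K_1\,C_a(t) - k_2\,C_t(t), \qquad
C_t(t) = K_1 \int_0^t C_a(s)\,e^{-k_2(t-s)}\,ds,$$

where $C_a$ is the image-derived arterial input and $K_1$
(mL blood/mL tissue/min) is reported as perfusion, with no
extraction-fraction or partition-coefficient correction; the partition
coefficient is only available as the derived ratio $K_1/k_2$. No
blood-volume term and no dispersion correction are applied — the
water analysis this mirrors reported the plain 1TCM fit — and the
current release does not expose optional terms for them; this is a
known limitation rather than a config switch.

**Numerics.** The input TAC is interpreted as piecewise-linear between
its frame points (zero prepended at $t=0$, last value held constant
beyond the final frame). On a uniform grid (0.1 s by default) the
convolution of a piecewise-linear input with $e^{-k_2 t}$ has a closed
form per step, so the model curve is computed by an exact first-order
recurrence (`stats::filter`, recursive) rather than quadrature;
$k_2 = 0$ reduces analytically to a running integral. Model frame
values are duration-averages of the gridded curve by default (what
framed PET measures), with midpoint evaluation behind
`frame_value = "midpoint"`. Against an independent stiff-ODE
integration (`deSolve::lsoda`, rtol $10^{-10}$) the maximal deviation
over the perfusion regime $K_1 \in [0.5, 6]$ is below $10^{-6}$
relative. Features narrower than the grid step (sub-0.1-s input
transients) are the one known error source; real frame schedules are
three orders of magnitude coarser.

**Fitting.** Weighted least squares with weights proportional to frame
duration (longer frames carry more counts; uniform weights available).
Optimization is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`,
bounds $0 \le K_1, k_2 \le 20$) from 5 log-spaced starts between 0.2
and 8; the reported optimum is the best of all starts by weighted
residual sum of squares, ties broken toward lower $k_2$. An input
delay of 0 is assumed by default (an image-derived input minimizes
transit delay); `fit_delay = TRUE` grid-searches ±10 s in 1-s steps.
An all-zero tissue curve short-circuits to $K_1 = 0$ and is flagged
degenerate; non-convergence is flagged and warned, never silently
reported as converged.

When fitting synthetic TACs that were generated at frame midpoints,
the fit is run with `frame_value = "midpoint"` so generator and fitter
share the same frame representation; otherwise the representation
mismatch alone would bias parameters by more than the fit tolerance.

## Synthetic data: what it emulates

All generators are pure functions of a `sim_config` (seed included):
identical configs give bitwise-identical output, and the global RNG
stream is left untouched.

* **Arterial input.** A gamma-variate bolus plus a two-exponential
  washout whose rise is coupled to bolus arrival, so the curve is zero
  before arrival, peaks once within the first minute and decays
  multi-exponentially. The form has a closed-form time integral used
  as an oracle in tests. Defaults: arrival 10 s, peak 20 s at
  350 kBq/mL — the early-peak regime of a venous bolus in a ~2.5-kg
  rabbit injected with 20 MBq of radiowater, sampled on the 6-min
  schedule 15 × 4 s, 4 × 10 s, 4 × 20 s, 3 × 60 s.
* **Tissue TACs.** The 1TCM convolution of the input with per-region
  truths. Defaults anchor the recovery studies to the reported
  cortical perfusion regime: obstructed cortex $K_1 = 2.00$,
  contralateral 5.57, healthy 5.25 mL/mL/min, with
  $k_2 = K_1/0.94$ (water partition coefficient 0.94 mL/mL).
* **Noise.** Zero-mean Gaussian with
  $SD = CV \cdot C \cdot \sqrt{d_{ref}/d}$, i.e. variance inversely
  proportional to frame duration; CV 5% at the reference duration,
  which defaults to the schedule's shortest frame so that the stated
  CV applies to the noisiest frames. Negative values are truncated at
  zero.
* **Organ biokinetics.** Fraction of injected activity
  $f_o(t) = u_o(1 - e^{-k_{up}t})\,e^{-\lambda_{bio}t}\,e^{-\lambda_{phys}t}$,
  physical decay included (the form dosimetry consumes). Default
  uptake fractions (liver 0.35 ≫ spleen 0.03 > kidneys 0.02, plus
  lungs, red marrow, muscle) reproduce the hepatic dominance and the
  liver > spleen > kidney ordering of an intact IgG4 antibody, with
  uptake over a few hours ($k_{up}$ = 0.5/h) and slow biological
  washout (biological half-life 500 h). Fraction sums are validated
  against unity at every time.
* **Plasma.** Decay-corrected biexponential
  $C(t) = (A_0/V_c)(f_1 e^{-\lambda_1 t} + f_2 e^{-\lambda_2 t})$ with
  $V_c$ = 100 mL, fractions 0.3/0.7 and rates 0.5 and 0.075 per hour,
  giving an analytic total clearance of 10.1 mL/h — the reported
  clearance regime for the obstructed group. Whole blood is 0.6 times
  plasma, constant in time. The intact fraction declines
  monoexponentially from 97% at 0.37/d, passing near the reported
  97% at 4 h and 33% at 3 d. Samples default to the study's
  blood-draw schedule (1 min to 7 d).

The generators emulate the *statistical structure* of the study, not
the animals: there is no partial-volume effect, no motion, no
reconstruction correlation between frames, no inter-animal kinetic
heterogeneity beyond what a test draws explicitly, and organ curves
are smooth parametric forms. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated noise
model, not field performance on scanner data.

## Plasma pharmacokinetics

Noncompartmental analysis uses the linear-up/log-down trapezoid —
standard for declining radiotracer curves and exact on exponentially
declining segments. The leading sliver from injection to the first
sample (1 min) is closed with a constant-concentration rectangle. The
terminal rate constant comes from a log-linear fit of the last 3
points (configurable); $AUC_{0\to\infty} = AUC_{0\to last} +
C_{last}/\lambda_z$ and $CL = A_0/AUC_{0\to\infty}$ in mL/h, with
activity units cancelling. A non-declining terminal phase refuses
extrapolation and flags the result rather than reporting a negative
tail. Clearance is computed on total plasma radioactivity (matching
how the study reports it); when intact percentages are supplied an
intact-corrected clearance (plasma activity × intact fraction) is
reported alongside, since which variant a reader wants depends on
whether the question is about the tracer or the intact antibody.
Percentages are carried on the 0–100 scale throughout.

The intact-fraction model $f(t) = f_0 e^{-rt}$ (rate per day) is fit
by least squares on the log scale: exact on noise-free
monoexponential data, scale-free in $f_0$, and rate-invariant under
rescaling — the properties the tests assert.

With the 7-d blood-draw schedule, a fast plasma component of
half-life ~1.4 h is not fully resolved between the 4-h and 24-h
draws; the NCA-versus-closed-form oracle is therefore checked on a
sampling grid dense enough to resolve it (added draws between 6 and
32 h), which tests the method rather than the schedule.

## Biodistribution and statistics

Ex vivo SUV decay-corrects the assayed activity to injection, divides
by wet weight and normalizes by $A_0/W$. Autoradiograph regions are
background-subtracted (negative net signal clamps to zero with a
warning), corrected by the time-averaged decay factor over the
exposure window $2^{-t_0/T_{1/2}}(1-e^{-\lambda T})/(\lambda T)$, and
normalized to the injected dose (PSL/mm² per MBq).

Group comparisons use the independent-samples t test, Student pooled
two-sided by default (the common spreadsheet default; Welch behind
`variant = "welch"`), $p < 0.05$ flagged significant, no
multiple-testing correction — matching the statistical treatment this
pipeline mirrors. A summary-statistic variant supports comparisons
against published means ± SDs. On the published clearance summaries
(10.4 ± 2.1 vs 17 ± 2.1 mL/h, n = 3) the pooled t is 3.85 with df 4
and p ≈ 0.018; the source reports p = 0.030 for this comparison,
plausibly reflecting rounding of the printed summaries — the
discrepancy is documented, not reconciled.

## Dosimetry

Residence times (normalized numbers of disintegrations) are
$\tau = \int_0^\infty f(t)\,dt$ over a NOT-decay-corrected fraction
series: linear-up/log-down over the observed range — so a purely
physically decaying series integrates exactly — plus a
$f_{last}/\lambda_{phys}$ tail assuming no biological loss beyond the
last sample (conservative). Decay-corrected input is rejected.

Rabbit-to-human extrapolation uses relative organ mass:
$f_h = f_r\,(m_{o,h}/m_{TB,h})/(m_{o,r}/m_{TB,r})$, the standard
reading of mass-based interspecies scaling; a per-kilogram
(concentration-preserving) alternative sits behind
`method = "per_kg"`. If scaling pushes the per-time organ sum above
1, all fractions at that time are renormalized proportionally and the
event is reported.

The total-body residence time defaults to the no-excretion physical
bound $T_{1/2}/\ln 2$; urinary loss is minor for an intact antibody
over 7 d, and no excretion model (bladder voiding, GI transit) is
applied. The remainder of the body is total minus the organ sum and
enters the MIRD sum $D(t) = \sum_s \tau_s S(t \leftarrow s)$ as a
source with its own S row. S values are *input data* (long-format
CSV): replicating a phantom library is out of scope, so the shipped
70-kg table and the organ-mass tables are synthetic, literature-style
placeholders, clearly labelled as such in their filenames and
headers — organ-level dose output with these inputs is illustrative
only, while the formalism (linearity, conservation, normalization) is
what the tests certify.

Effective dose applies the ICRP-103 tissue weighting factors (0.12
red marrow/colon/lung/stomach/breast/remainder, 0.08 gonads, 0.04
bladder/oesophagus/liver/thyroid, 0.01 bone surface/brain/salivary
glands/skin; they sum to 1, validated). With radiation weighting
factor 1 for photons and electrons, mGy/MBq equals mSv/MBq
numerically. Organs supplied but not individually weighted form the
remainder pool (arithmetic mean), which also stands in for named
tissues without an assessed dose. Administered-dose projections round
to 2 significant figures for reporting: 0.702 mSv/MBq × 37 MBq →
26 mSv.

## Problem sizes and determinism

The validation suite uses the study's own frame schedules (26 frames
for water, 12 for the antibody), 200 noisy replicates for the
perfusion recovery study, exhaustive 12-choose-6 permutation for the
t-test oracle, and 5 seeded repeats for conservation properties —
sizes at which every check is exact or tightly bounded while the full
suite stays interactive. All randomness flows from explicit seeds;
repeated pipeline runs with one seed produce byte-identical JSON, and
every report embeds the package version, the seed, a config hash and
the nuclide constants used.

## Known limitations

* No blood-volume or dispersion term in the 1TCM; voxelwise
  (parametric) fitting and basis-function methods are out of scope.
* NCA only for plasma kinetics; no compartmental antibody PK.
* Dose output depends entirely on user-supplied S values and organ
  masses; the shipped tables are synthetic placeholders.
* The synthetic generators are smooth parametric emulations; they do
  not model image reconstruction, partial volume, or inter-subject
  kinetic variability.
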