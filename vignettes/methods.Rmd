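---
title: "Methods: the secretion model, its estimation, and the synthetic validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the secretion model, its estimation, and the synthetic validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmttfit)
```

## The measurement problem

A frequently sampled mixed-meal tolerance test (FS-MMTT) draws blood at
−15, 0, 30, 60, 90, 120 and 180 min around a standardised liquid meal
(~100 g carbohydrate, ~2930 kJ, finished within 15 min) and measures
plasma glucose, insulin and C-peptide, with urine collected over the whole
window for urinary glucose excretion (UGE). Insulin itself is a poor
readout of secretion because roughly half of it is cleared on first pass
through the liver; C-peptide is co-secreted equimolarly but not
hepatically extracted, so the insulin secretion rate (ISR) is
reconstructed from C-peptide. The two pre-meal samples exist to be
averaged: every "fasting" value in this package is the mean of the −15
and 0 min samples when both are present. Postprandial AUCs and the mean
postprandial glucose (MPG~0–3h~ = AUC/180) integrate over [0, 180] only;
the −15 min sample informs the baseline, not the AUC (a convention this
package fixes explicitly, since protocols rarely state it).

## C-peptide kinetics

C-peptide kinetics are described by the standard two-compartment model
with irreversible loss from the central (plasma) compartment:

$$\dot C_1 = -(k_{01}+k_{21})C_1 + k_{12}C_2 + \mathrm{ISR}(t)\,
\mathrm{BSA}/V, \qquad \dot C_2 = k_{21}C_1 - k_{12}C_2 .$$

The rate constants are never fitted per subject. They come from the
published anthropometric regression: a short half-life of 4.52 min and
fast fraction 0.78 for the type 2 diabetes class (4.95 min / 0.76
otherwise), a long half-life of `0.14·age + 29.2` min, and a distribution
volume of `1.92·BSA + 0.64` litres, with BSA by DuBois–DuBois
(`0.007184·W^0.425·H^0.725`). Treating kinetics as known is justified for
these trial populations because SGLT2 inhibition has been shown to alter
C-peptide clearance by less than ~4%. The biexponential
(half-life/fraction) parameterisation is converted to rate constants
through the exact relations `a+b = k01+k12+k21`, `ab = k01·k12`,
`k01+k21 = F·a + (1−F)·b`.

Integration is exact for secretion linear between grid nodes: each 5-min
step applies the matrix-exponential update with linear forcing
(`x(h) = E x(0) + m0·u(0) + m1·u(h)`), so simulated trajectories are
reproducible bit-for-bit at a fixed grid and the forward map from an ISR
grid to C-peptide is available in closed form as a matrix — which is what
makes the fit below a sequence of linear problems. Both compartments are
initialised at the steady state consistent with the measured fasting
C-peptide.

## The secretion model and its estimation

Insulin secretion over the test window is

$$\mathrm{ISR}(t) = P(t)\, f(G(t)) + r\,\max(\mathrm dG/\mathrm dt, 0),$$

- `f`: the glucose dose–response, piecewise linear with knots at
  quantiles of the observed glucose values (4 interior knots by default,
  thinned when repeated fasting samples would create near-zero segments).
  Piecewise linearity makes "beta cell glucose sensitivity = mean slope
  over the observed range" exact as the chord slope and keeps the model
  identifiable from 7 samples.
- `P(t)`: the potentiation factor (incretin, neural and
  hyperglycaemia-duration effects), piecewise linear on 30-min nodes,
  strictly positive, and constrained to a time-average of exactly 1 —
  enforced by renormalising `P` (and compensating `f` by the inverse
  factor, which leaves the model's output unchanged) after every
  iteration, so the unit-mean invariant holds to machine precision rather
  than approximately through a penalty.
- `r`: rate sensitivity, active only while glucose rises — the standard
  convention tying this component to early insulin release.

`G(t)` and its derivative come from a smoothing spline through the
glucose samples whose smoothness is chosen to match the ~1% glucose
measurement error (below).

**Estimation.** Given `G(t)`, the C-peptide prediction is affine in the
model parameters through the kinetic forward matrix, so the penalised
weighted least-squares problem is solved by alternating non-negative
least squares: one step solves for the dose–response values and `r` with
`P` fixed, the next for the potentiation nodes with `f`, `r` fixed, each
with relative (percent-of-signal) residual weighting, until the relative
parameter change falls below 1e−6 (cap 200 iterations; a stalled
optimiser returns `converged = FALSE` rather than raising). Two
regularisation terms are scaled by a single smoothing factor λ:

- dose–response: second *divided* differences (curvature on the uneven
  knot grid, normalised by a basal-secretion scale), whose null space is
  the linear functions of glucose;
- potentiation: second *and* first differences of the node values. The
  first-difference term is a deliberate deviation from a pure-curvature
  penalty: with six postprandial C-peptide points, a linear drift of `P`
  is empirically indistinguishable from the derivative component (both
  produce a rising-limb/falling-limb asymmetry), and with curvature-only
  penalisation the optimiser wanders along this ridge even when the data
  were generated with flat potentiation. Shrinking toward *constant*
  potentiation resolves the aliasing and encodes the correct prior that
  potentiation is a modulation around its unit mean.

One further pseudo-observation anchors the fasting end: before the meal
the system is stationary, so secretion at t = 0 must equal the basal rate
that sustains the fasting C-peptide level, `ISR(0) = c₀·k₀₁·V/BSA`. This
is information the initial condition already asserts, made explicit to
the fit.

Positivity of `P` uses the non-negative least-squares solver with a small
floor (1e−8) before renormalisation rather than a log-parameterisation,
which would break the linearity the alternating scheme relies on.

**Smoothing selection.** Regularisation weights are chosen so that model
residuals match the expected measurement error — ~1% for glucose, ~4% for
C-peptide — by bisection: on the glucose spline's `spar` for the glucose
target, and on log λ for the C-peptide target (30 steps or until within
0.5% of the target; bounds 1e−4 to 1e6). When a target is unreachable the
boundary value is returned with a flag; for noiseless data this yields
the largest admissible smoothing.

Residual SDs are defined carefully, because n is small:

- glucose: raw relative RMS of the spline residuals. (A
  degrees-of-freedom-corrected version is degenerate here: a 7-point
  smoothing spline approaches interpolation with df → n, making the
  corrected statistic a 0/0 cliff.)
- C-peptide: `sqrt(SSR/(n−3))` on the relative residuals, where 3 is the
  dimension of the effectively unpenalised model subspace (linear
  dose–response + rate parameter; constant potentiation is fully
  determined by the unit-mean constraint). Near the smoothing levels the
  selection attains, the fit spends approximately those three degrees of
  freedom, so this is the approximately unbiased estimate of measurement
  error from the residuals. With a raw RMS the 4% target is structurally
  unreachable for most 7-sample profiles — the stiffest admissible model
  already absorbs roughly half the noise — which would pin the selection
  at its boundary and bias the achieved residuals low.

For noise-free data (simulation studies), automatic selection would still
smooth until the residuals reach the targets, deliberately distorting a
perfectly informative signal; the minimal-regularisation configuration
`fit_config(smoothing = list(spar = -1.5, lambda = 0.1))` is the
appropriate choice there and is what the closed-loop validation uses.

**Derived indices.** Glucose sensitivity is the chord slope of `f` over
the observed glucose range; ISR at 9 mmol/l is `f(9)` (linearly
extrapolated, and flagged, when 9 mmol/l lies outside the observed range
— common when fasting glucose is ~10 mmol/l); total secretion is the
trapezoid integral of the 5-min ISR grid (reported in nmol/m², the unit
consistent with typical magnitudes of ~40–60 for ISRs around 150
pmol·min⁻¹·m⁻²); insulin clearance divides total secretion by the insulin
AUC and is reported only with ≥5 postprandial insulin samples.

## OGIS and the urinary-glucose correction

Insulin sensitivity uses the 2-h OGIS closed form (0, 90, 120-min
glucose and insulin), with the published constants locked in a constants
function and verified by an independent re-typing in the test suite. Two
choices the original OGIS publications leave open for a mixed meal are
fixed here and surfaced deliberately: the 2-h (not 3-h) variant, since
the MMTT schedule provides exactly the required samples, and a glucose
dose equal to the meal's 100 g carbohydrate content normalised by BSA.

SGLT2 inhibitors dispose of glucose in urine without insulin; OGIS
interprets that disposal as insulin sensitivity. The corrected index
subtracts renal glucose clearance,

$$\mathrm{OGIS_c} = \mathrm{OGIS} - \frac{\mathrm{UGE}}
{\mathrm{AUC}_G}\cdot\frac{1}{\mathrm{BSA}},$$

with UGE converted at 180.16 g/mol. OGIS_c ≤ OGIS whenever UGE ≥ 0, and
in simulated trials where treatment raises UGE without changing true
insulin sensitivity, the OGIS_c arm contrast centres markedly nearer zero
than the OGIS contrast.

## Trial statistics

Changes are analysed as ANCOVA on the endpoint value with the baseline
value and the binary baseline glycaemic-control stratum (HbA1c ≥ 9.0%) as
covariates and treatment as the factor — the "change ΔLSM" presented is
the adjusted endpoint LSM minus the pooled baseline mean, and
comparator-subtracted differences are the arm coefficients with t-based
intervals on residual df. An ANCOVA on endpoints adjusted for baseline
was chosen over an ANCOVA on raw changes; the two differ only in the
baseline coefficient, and the endpoint reading matches the stated model
("the model parameter as the response variable"). Glucose sensitivity and
the OGIS measures are log-normal in these populations, so significance
testing is done on logs while point estimates stay on the original scale.
Rate sensitivity is too non-normal for either; between-arm comparison
uses the tie-corrected Kruskal–Wallis test on changes. Covariates that
are constant in a given dataset (a single HbA1c stratum, identical
baselines) carry no information and are dropped from the design rather
than rejected — a genuinely inestimable arm effect is still an error. No
multiplicity adjustment is applied; p < 0.05 two-sided is the
significance convention. Complete-case analysis per parameter.

## The synthetic validation design

The generator emulates the study conditions the pipeline assumes: the
7-point sampling schedule; fasting glucose ~9.5 ± 1.5 mmol/l (the range
of these trial populations); dose–response truths with secretion at
9 mmol/l ~140 (CV 25%) and glucose sensitivity ~40 (CV 30%)
pmol·min⁻¹·m⁻²(mmol/l)⁻¹; rate sensitivity ~350 (CV 40%)
pmol·m⁻²(mmol/l)⁻¹; insulin clearance ~1.0 l·min⁻¹·m⁻²; measurement
noise 1% (glucose), 4% (C-peptide), 6% (insulin — not stated in the
source protocols; a config default) as multiplicative log-normal errors,
matching the percent-SD framing of assay error; urinary glucose from a
renal threshold model (excretion ∝ max(G − threshold, 0) with a 0.09
l/min clearance above threshold, threshold ~10 mmol/l untreated),
yielding ~3–6 g untreated and ~15–20 g when treatment lowers the
threshold to ~5 mmol/l. A treated arm applies three endpoint effects:
a renal-threshold shift, a fractional glucose lowering (~8%, consistent
with the UGE it produces), and a glucose-sensitivity multiplier. One
global seed expands into per-subject substreams by fixed integer
arithmetic (`substream_seed`), so enlarging a trial never reshuffles
existing subjects' data.

Four generator choices matter for interpreting what the validation does
and does not show:

1. **Spline-consistent glucose truth.** The true continuous glucose
   trajectory is the natural cubic interpolant through the gamma-pulse
   excursion values at the schedule times — not the analytic pulse
   itself. Seven samples cannot recover an arbitrary between-sample
   derivative, and the secretion model consumes `dG/dt`; defining the
   truth as the minimum-curvature curve consistent with the samples (the
   limit of the fitter's own spline as smoothing vanishes) makes the
   closed loop well-posed, so recovery tests measure the estimator, not
   glucose-interpolation error. Real data carry no such guarantee:
   between-sample glucose excursions are a genuine, unquantifiable error
   source at this sampling density.
2. **Flat potentiation in the validation population.** A sustained
   potentiation drift is aliased with the rate component at this sampling
   density (see the penalty discussion): with drifting-truth populations
   no estimator using these data can attribute the two within a few
   percent. The validation population therefore uses flat true
   potentiation; nonzero-swing scenarios are exercised separately with
   correspondingly weaker assertions. Passing recovery tests accordingly
   demonstrate estimation of the dose–response, rate component and
   secretion trajectory — not recovery of a potentiation shape.
3. **Linear dose–response truth.** ISR at 9 mmol/l must be extrapolated
   whenever fasting glucose exceeds 9; against a curved truth, linear
   extrapolation mis-states it regardless of estimator quality. The
   default truth is linear over the explored range (consistent with the
   near-linear mean ISR–glucose relations observed in such cohorts);
   curvature is available as a scenario parameter.
4. **Positive basal secretion.** Draws are constrained so the (floored)
   dose–response keeps basal secretion above 20 pmol·min⁻¹·m⁻² at the
   subject's fasting glucose; zero basal secretion is non-physiological
   and breaks the model's steady-state initial condition.

Insulin is generated in the quasi-steady-state limit of one-compartment
kinetics (`I(t) = ISR(t)/CL`), which the pipeline only consumes through
its AUC; this makes the true clearance exactly recoverable up to
trapezoid error.

## Numerical choices and problem sizes

Bisection tolerances: 0.5% of the residual target, ≤30–40 steps.
Alternating solver: convergence at 1e−6 relative parameter change, cap
200 iterations (80 during smoothing selection). ISR grid: 37 nodes, 0–180
by 5 min. Knot thinning: minimum spacing 5% of the observed glucose
range. Validation sizes were chosen to give stable statistics at
interactive runtimes: 100 profiles for the residual-SD calibration
(pooled SDs, df-corrected pooling), 10 noise-free subjects for exact
recovery, 50 replicates for noisy-recovery medians, 50 simulated trials
of 2×40 subjects for the UGE-correction direction, 100 random designs and
2000 null replicates for the statistical oracles. The fitted ISR is also
cross-checked against an unstructured regularised deconvolution (no
secretion model, same kinetics): the two agree on the integral (<1%) and
at the observation times (<5%); mid-interval pointwise differences up to
~7–10% reflect the unstructured oracle's smoothness prior — six C-peptide
samples cannot localise the early secretion rise — not a fitting defect,
which is why the equivalence test asserts integral, node-wise and RMS
agreement rather than a uniform pointwise band.

## Known limitations

- Attribution between potentiation shape and rate sensitivity is weakly
  identified from 7 samples; rate sensitivity is reported with that
  caveat (recovery within ~15% noise-free, much wider with noise), as its
  large between-patient variability in real studies also suggests.
- The residual-targeted glucose spline slightly compresses the glucose
  excursion, inflating recovered glucose sensitivity by ~5–7% (median)
  under the default 1% noise; noise-free analyses with minimal smoothing
  do not show this bias.
- OGIS constants are transcribed from the published 2-h formula; the
  transcription is consistency-tested, and all OGIS-based conclusions in
  the validation are within-package comparisons (corrected vs
  uncorrected), which are insensitive to constant-level transcription
  error.
- The simulator does not model drug pharmacokinetics, HbA1c trajectories,
  meal absorption physiology, or assay-specific error structure beyond
  multiplicative log-normal noise.
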