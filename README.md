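# mmttfit

Model-based analysis of beta cell function and insulin sensitivity from
frequently sampled mixed-meal tolerance tests (FS-MMTT) in type 2
diabetes — the kind of 3-hour, 7-sample meal test used to assess how
glucose-lowering drugs (in particular SGLT2 inhibitors, which act by
raising urinary glucose excretion) change insulin secretion and
insulin sensitivity between a baseline and an endpoint visit.

## What it computes

**Insulin secretion model.** Plasma C-peptide is linked to the insulin
secretion rate (ISR) through standard two-compartment kinetics with
population rate constants from the anthropometric regression (diabetic
class). Secretion is modelled as

    ISR(t) = P(t) · f(G(t)) + r · max(dG/dt, 0)

where `f` is a piecewise-linear dose–response relating ISR
(pmol·min⁻¹·m⁻²) to absolute glucose, `P(t)` is a positive potentiation
factor constrained to average exactly 1 over the test, and `r` (rate
sensitivity, pmol·m⁻²·(mmol/l)⁻¹) scales the response to rising glucose.
Parameters are estimated from glucose and C-peptide by regularised
(penalised, non-negative) least squares; the smoothing factors are
selected by bisection so the model residual SDs match the expected
measurement error (~1% glucose, ~4% C-peptide). Derived indices:

- beta cell glucose sensitivity — mean (chord) slope of `f` over the
  observed glucose range;
- ISR at 9 mmol/l glucose;
- rate sensitivity;
- total insulin secretion — integral of the 5-min ISR grid over 0–180 min
  (nmol/m²);
- insulin clearance — total secretion / plasma insulin AUC, computed only
  when ≥5 insulin samples are available (l·min⁻¹·m⁻²).

**Insulin sensitivity.** The 2-h OGIS index (ml·min⁻¹·m⁻²) from the 0/90/
120-min samples, plus a urinary-glucose correction: OGIS_c = OGIS − renal
glucose clearance (UGE ÷ glucose AUC, per m²). Without the correction,
glucose lost in urine is counted as insulin-mediated disposal and inflates
apparent insulin-sensitivity improvements under SGLT2 inhibition.

**Trial statistics.** Between-arm comparison of baseline→endpoint changes
by ANCOVA (endpoint ~ baseline + HbA1c stratum + treatment;
least-squares means, comparator-subtracted differences, t-based CIs;
log-scale significance testing for glucose sensitivity and the OGIS
measures) and Kruskal–Wallis for the heavily non-normal rate sensitivity.

**Synthetic trials.** A forward simulator generates complete FS-MMTT
datasets (glucose excursions, C-peptide via the kinetic model, insulin
consistent with a true clearance, urinary glucose from a renal-threshold
model, multiplicative log-normal measurement noise) with known per-subject
truths, so every stage of the pipeline is validated closed-loop.

## Worked example

```r
library(mmttfit)

## one simulated subject-visit, analysed end to end
tr   <- subject_truth()                       # ground truth
prof <- simulate_subject(tr, trial_config(), seed = 42)
beta_cell_indices(prof)
#>   glucose_sensitivity isr_at_9 rate_sensitivity total_secretion
#> 1               44.68   149.08           251.79           47.11
#>   insulin_clearance  ogis ogis_c mpg_0_3h
#> 1              1.05 290.8 284.53    11.83

## a two-arm trial: treated arm lowers the renal threshold (raising UGE),
## lowers glucose and raises glucose sensitivity
cfg     <- trial_config(n_per_arm = 15, seed = 7)
trial   <- simulate_trial(cfg)
indices <- analyze_trial(trial$profiles)
compare_arms(indices, comparator_arm = "placebo",
             parameters = c("glucose_sensitivity", "isr_at_9",
                            "ogis", "ogis_c", "uge_0_3h"))
#>             parameter     arm lsm_diff   sem   ci_lo ci_hi  p_value   test transform
#> 1 glucose_sensitivity treated     7.57 2.264   2.929 12.22 1.16e-02 ancova       log
#> 2            isr_at_9 treated   -10.20 9.444 -29.582  9.17 2.89e-01 ancova       raw
#> 3                ogis treated    12.19 5.535   0.831 23.54 3.78e-02 ancova       log
#> 4              ogis_c treated    -5.08 5.491 -16.348  6.19 4.76e-01 ancova       log
#> 5            uge_0_3h treated    10.98 0.387  10.185 11.77 1.24e-21 ancova       raw
```

Reading the output: the treated arm excretes ~11 g more urinary glucose
over the test, its glucose sensitivity rises by ~7.6
pmol·min⁻¹·m⁻²·(mmol/l)⁻¹ versus placebo (p = 0.01), and the apparent
OGIS improvement (+12 ml·min⁻¹·m⁻², p = 0.04) shrinks to a
non-significant −5 after the urinary-glucose correction — the correction
removing exactly the insulin-independent component the drug mechanism
adds.

Real data are read with `read_mmtt_csv()` (long-format samples CSV plus a
subject-visit metadata CSV; units mmol/l, pmol/l, nmol/l, grams) and
results written with `write_results()` (tidy per-subject-visit CSV + JSON
run manifest).

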