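# lumiphase

Circadian phase analysis of bioluminescence reporter rhythms.

Tissue explants from luciferase clock-reporter animals (e.g. PER2::LUC liver
slices) report clock-gene expression as a damped, drifting sine wave of
light. The scientific questions such recordings answer are about *phase*:
at what point in its cycle was a culture treated, how many hours did the
treatment shift the rhythm, how does the shift depend on the treatment phase
(the phase-response curve, PRC) and on dose, and which of several candidate
*Zeitgeber* hormones actually resets the clock. lumiphase implements that
analysis end to end for experimentalists in chronobiology:

- **Detrending** by subtraction of a centered 24-h running average.
- **Rhythm descriptors**: troughs, peaks defined as the midpoint between two
  consecutive troughs, period as the mean inter-peak interval over 2–3
  cycles, and least-squares damped-sine fits
  *A e^(−λt) cos(2π(t − t_peak)/τ)*.
- **The degree convention**: ascending zero crossing = 0°/360°, peak = 90°;
  a treatment at time *T_p* after the preceding fitted peak *P_bt* maps to
  *φ = ((T_p − P_bt)/τ)·360 + 90*, wrapped into [0°, 360°).
- **Phase shifts** from extrapolated peak times of sine fits before and
  after the treatment (delays negative, advances positive), wrapped to the
  nearest cycle.
- **PRC estimation** by OLS harmonic regression of individual slice shifts
  on {1, sin φ, cos φ, sin 2φ, cos 2φ}, with the phase of maximal delay.
- **Dose-response tables** (mean ± SEM, n) with one-way ANOVA and
  Bonferroni-adjusted comparisons against vehicle; Mann–Whitney and two-way
  ANOVA with Bonferroni post-tests for other designs.
- **Efficiency-corrected ΔΔCт** relative quantification for qPCR induction
  and circadian profiles, with the two standard normalization conventions.
- A **synthetic-data generator** producing seeded PER2::LUC-like cohorts
  whose ground-truth resetting behaviour (two-harmonic PRC × Hill
  dose-response per peptide) is known, so the whole pipeline is testable
  without external data. Packaged calibrations encode the
  proglucagon-derived peptide screen: oxyntomodulin (OXM) with a maximal
  delay of −8 h at 180°, glucagon (GCG) −3 h at high dose only,
  GLP-1/GLP-2/GRPP null, dexamethasone (DEX) biphasic.

See `vignettes/rhythm-analysis-methods.Rmd` for the model, the estimators
and every tunable parameter.

## Worked example

Simulate the OXM dose-response cohort (six doses 0.5–450 nM × 5 replicates
plus 5 PBS controls, treatments at 180–200° of the PER2::LUC cycle, 5%
amplitude noise), estimate every phase shift, and build the dose table:

```r
library(lumiphase)

traces <- generate_cohort(dose_response_cohort_spec("OXM"), seed = 1)
traces[["OXM_450nM_r1"]]
#> <lumi_trace> OXM_450nM_r1: 721 samples, 0.0-120.0 h (dt = 0.167 h)
#>   event: OXM 450 nM at 50.06 h

phase_shift(traces[["OXM_450nM_r1"]])
#> <phase_shift_estimate> OXM_450nM_r1: -8.019 h at 181.3 deg (OXM, 450 nM)

shifts <- estimate_shifts(traces)
dose_response(shifts)
#> Dose-response table (shifts in h; delays negative); vehicle: PBS
#>  peptide dose_nM mean_shift_h     sem n p_adj_vs_vehicle stars
#>      PBS     0.0     -0.04125 0.01920 5               NA
#>      OXM     0.5     -0.73115 0.05322 5        2.460e-05   ***
#>      OXM     1.5     -1.84488 0.05414 5        4.589e-14   ***
#>      OXM     4.5     -3.71827 0.05993 5        3.327e-22   ***
#>      OXM    15.0     -5.81102 0.08090 5        1.403e-27   ***
#>      OXM    45.0     -7.15985 0.14571 5        4.142e-30   ***
#>      OXM   450.0     -7.67371 0.11725 5        5.967e-31   ***
#>
#> One-way ANOVA across dose groups (incl. vehicle):
#>  peptide    F df1 df2         p
#>      OXM 1313   6  28 5.802e-33
```

Reading the output: one slice treated with 450 nM OXM at 181.3° was delayed
by 8.02 h; across the cohort the mean delay grows with dose toward the
calibrated −8 h maximum, every dose differs from PBS after Bonferroni
adjustment, and the vehicle controls sit at zero. A phase-response curve
works the same way from a phase-spread cohort:

```r
prc_traces <- generate_cohort(prc_cohort_spec("OXM"), seed = 1)
prc <- fit_prc(estimate_shifts(prc_traces))
prc_extremum(prc)   # phase and size of the maximal delay, ~180 deg / ~-8 h
plot(prc)
```

`run_pipeline()` chains simulate → detrend → fit → shift → PRC →
dose-response → qPCR as one seeded run writing per-stage CSVs, a JSON
summary and a log; `inst/scripts/lumiphase` wraps it (and each stage) as
shell subcommands. All times are hours, phases degrees in [0, 360), delays
negative.

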