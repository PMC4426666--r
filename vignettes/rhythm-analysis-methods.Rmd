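---
title: "Methods: circadian phase analysis of luminescence reporter rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian phase analysis of luminescence reporter rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumiphase)
```

## The measurement and its model

Organotypic tissue explants from luciferase clock-reporter animals (e.g.
PER2::LUC liver slices) emit light in proportion to clock-gene expression.
Recorded in a luminometer, the signal closely follows a sine wave riding on a
slowly decaying baseline, with the oscillation amplitude itself damping as
the explanted tissue desynchronises and consumes substrate. lumiphase models
one trace as

$$L(t) = b_0 e^{-kt} + A\,e^{-\lambda t}
  \cos\!\left(\frac{2\pi (t - t_{peak})}{\tau}\right) + \varepsilon,$$

with period $\tau$ (hours), amplitude $A$ (counts/s), damping rate $\lambda$
(1/h), baseline $b_0 e^{-kt}$, and i.i.d. Gaussian noise $\varepsilon$. A
treatment with a resetting agent (a *Zeitgeber*, e.g. a peptide hormone
applied to the medium) is modelled as an instantaneous phase shift of the
cosine, optionally with an amplitude-dampening factor; the package does not
model the transient relaxation of the molecular oscillator, because the
analysis targets net shifts measured cycles after the event.

## Analysis pipeline

**Detrending.** `baseline_subtract()` removes the running mean over a
centered 24-h window — one full circadian cycle, so the oscillation averages
out of the window while the baseline passes through. At the trace ends the
window shrinks symmetrically rather than dropping samples; this keeps early
pre-treatment cycles usable, at the price of a known bias zone within half a
window of each end (see *Numerical choices*).

**Extrema.** `find_troughs()` smooths with a centered moving median (2 h by
default), takes strict local minima that are also the minimum of their
±12 h neighbourhood, and refines each to sub-grid precision with a local
least-squares parabola on the unsmoothed values. Peaks are *defined* as the
midpoint of two consecutive troughs (`peaks_from_troughs()`), a convention
that is robust to the peak asymmetry a decaying envelope induces.
`estimate_period()` averages the first 2–3 inter-peak intervals (3 when
available).

**Sine fitting.** `fit_sine()` fits $A e^{-\lambda (t - t_0)}
\cos(2\pi(t - t_{peak})/\tau)$ by least squares. For fixed $(\tau, \lambda)$
the amplitude and phase enter linearly and are profiled out, so the
optimiser (bounded L-BFGS-B, $\tau \in [16, 32]$ h, $\lambda \ge 0$) works
in two dimensions, initialised from the extrema-based period. $\lambda = 0$
recovers a plain sine; fits may also be requested undamped. The damping term
is on by default because explant rhythms visibly damp; on undamped data the
estimate collapses to the boundary at no cost.

A detail that matters for accuracy: when the input is a detrended trace, the
model regressors are passed through the *same* truncated-window running-mean
subtraction that produced the data, and two detrended low-order polynomial
columns absorb what the filter leaves of the baseline. Without this, the
shrinking-window edges bias the fitted period by several parts per thousand
and propagate hours-level errors into extrapolated peaks. With it, the
zero-noise pipeline recovers injected shifts to better than 0.05 h.

**Phase convention.** Positions in the cycle are expressed in degrees: the
ascending zero crossing of the fitted sine is 0°/360° and the peak is 90°.
A treatment at time $T_p$ is assigned

$$\phi = \frac{T_p - P_{bt}}{\tau} \times 360 + 90 \pmod{360},$$

where $P_{bt}$ is the last fitted peak at or before the treatment. Only
division by the period $\tau$ yields 360° per cycle and reproduces the
convention's anchor values (90° at the peak, 0°/360° at the ascending
crossing, wrap by −360 above 360°), so that is what
`treatment_phase_degrees()` implements. $P_{bt}$ is taken from the
pre-treatment sine-fit extrapolation rather than raw extrema, because the
shift procedure is fit-based and raw extrema are unreliable near the event.

**Phase shifts.** `phase_shift()` compares extrapolated peak times from sine
fits before and after the treatment: the shift is the extrapolated
pre-treatment peak nearest the first fitted post-treatment peak minus that
peak, wrapped into $(-\tau/2, \tau/2]$. Delays are negative, advances
positive, throughout the package. The pre-treatment window ends at the
event; the post-treatment window starts at the first detected trough after
it, skipping the acute transient (treatments acutely induce *Per*
transcription, which distorts the first hours of the response). Each segment
is detrended separately so the running mean never straddles the event — a
shifted oscillation leaking into the pre-treatment baseline would otherwise
bias both fits. Wrapping makes shifts of $s$ and $s \pm \tau$
indistinguishable; at the effect sizes relevant here (up to 8 h on a ~24-h
cycle) this is unambiguous.

**Phase-response curve.** `fit_prc()` regresses individual per-slice shifts
on a first- and second-order harmonic basis of the treatment phase,
$\{1, \sin\phi, \cos\phi, \sin 2\phi, \cos 2\phi\}$, by unweighted OLS —
individual slices, not group means, carry the information, and fit-quality
weighting is deliberately off by default. Predictions on a 1° grid are
360°-periodic by construction; `prc_extremum()` reports the phase of
maximal delay, flagging curves whose total span is under 0.2 h (about 1% of
a cycle) as flat.

**Group statistics.** `dose_response()` summarises shifts per peptide × dose
(mean ± SEM, n), runs a one-way ANOVA across dose groups including vehicle,
and compares each dose against vehicle with pooled-error t tests under
Bonferroni adjustment (stars at 0.05/0.01/0.001). `compare_groups()`
provides Mann–Whitney tests for simple two-group comparisons and two-way
ANOVA with Bonferroni post-tests for factorial designs. Bonferroni (rather
than Holm or FDR) is used to match standard practice in this assay
literature; adjusted p values are capped at 1.

**qPCR quantification.** `relative_expression()` implements the
efficiency-corrected ΔΔCт ratio
$E_{t}^{Cq_{cal,t} - Cq_{s,t}} / E_{r}^{Cq_{cal,r} - Cq_{s,r}}$ with
per-primer efficiencies in (1, 2], collapsing technical replicates by mean
Cq first (standard practice; with all efficiencies 2 this is the classic
$2^{-\Delta\Delta Cq}$). `normalize_profile()` offers the two presentation
conventions: circadian profiles divided by their grand mean (profile mean
1), induction time courses divided by the untreated 0-min group.

## The synthetic-data generator

`simulate_trace()` draws traces from the model above; `generate_cohort()`
builds treated cohorts in which every trace knows its ground truth. Each
peptide's resetting behaviour is a `treatment_response`: a two-harmonic
phase-response curve $PRC(\phi)$ (hours) times a Hill dose factor
$d^{n}/(d^{n} + EC_{50}^{n})$. The packaged calibrations encode the
qualitative pharmacology of the proglucagon-derived peptide screen:

| peptide | PRC shape | EC50, Hill | notes |
|---|---|---|---|
| OXM | min −8 h at 180°, ~0 at 0°, −1 h at 270° | 5 nM, 1 | potent at low dose; post-treatment amplitude ×0.8 |
| GCG | same shape scaled to −3 h | 80 nM, 2 | effective only at high dose |
| DEX | −3 sin 2φ: delays 0–90°, advances 100–180°, ~0 at 270° | 5 µM, 1 | used at 100 µM |
| GLP-1, GLP-2, GRPP, PBS | all-zero | — | null controls |

Hill parameters were chosen once so that 450 nM is ≥95% of the maximal
effect and 0.5 nM ≤15% for the active peptides. Defaults elsewhere: period
24 h, amplitude 100 counts/s, damping 0.01/h, baseline 500 counts/s decaying
at 0.01/h, noise SD 5 counts/s (5% of amplitude), sampling every 10 min
(typical luminometer cadence), 120-h recordings. No absolute luminescence
scale or noise magnitude is canonical for this assay, so these are exposed
configuration, not constants.

`dose_response_cohort_spec()` reproduces the dose-response design (six doses
0.5–450 nM × 5 replicates + 5 vehicle controls = 7 groups of 5, treatments
at 180–200°); `prc_cohort_spec()` spreads 48 treatments over the full cycle
at a near-saturating dose, on 144-h recordings so that even the latest
treatment leaves two full cycles after the event. Treatment phases are
stratified across the requested window (replicate *i* uniform on the *i*-th
subdivision) so small cohorts still cover it, and treatment times are placed
from the true oscillator phase, leaving at least two cycles on each side.
The qPCR generator converts fold-change profiles to Cq via the primer
efficiencies and adds Gaussian Cq noise; its packaged induction panel mimics
transient *Per1* (peak at 60 min, near baseline by 120 min) and sustained
*Per2* induction with a flat *Bmal1* and β-actin reference.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: transient relaxation dynamics after resetting
(shifts are instantaneous), pharmacokinetic clearance of the agent,
slice-to-slice period and amplitude heterogeneity, non-Gaussian photon
counting noise, temperature artefacts, and multi-oscillator
desynchronisation within a slice. Estimator accuracy on real recordings
should be expected to be worse than the synthetic recovery figures.

## Numerical choices

- **Edge handling.** The running mean uses shrinking centered windows rather
  than dropping edges. Consequences are handled rather than ignored:
  trough candidates within half a detrending window of a trace end are
  discarded when at least two interior troughs remain, and the sine fit
  filters its regressors identically to the data (above).
- **Trough ties** are broken by the deeper minimum, then the earlier time;
  the minimum trough separation defaults to 12 h (half a cycle).
- **Degenerate inputs.** Constant traces raise "insufficient cycles";
  all-identical ANOVA groups report F = 0 with p = 1 rather than 0/0;
  all-zero shift sets give a flat-flagged PRC with undefined R².
- **Optimiser.** Three period starts (extrema estimate ±2 h, clipped to the
  plausibility band); non-convergent fits are flagged, never silently
  accepted. Windows shorter than two plausible cycles are rejected.
- **Shift wrapping** into $(-\tau/2, \tau/2]$ uses the pre-treatment period.
- **Seeding.** One seed per run; per-trace and per-stage substreams are
  drawn deterministically from it, so identical configurations are
  byte-identical, including the pipeline's JSON summary.

## Problem sizes

The shipped tests and the acceptance script run cohorts of 35 traces (dose
designs), 48 traces (PRC design), 100 replicate traces for the
shift-estimator bias check, and 20 seeded replications of the three
null-peptide cohorts for the specificity check — sizes at which the
Monte-Carlo error of the checked quantities is comfortably below the
asserted tolerances.

## Known limitations

- The treatment-phase formula needs a well-defined pre-treatment peak; at
  least two pre-treatment cycles are required, so very early treatments are
  rejected rather than guessed.
- Period estimation is extrema- or fit-based by design; spectral methods
  (Lomb–Scargle, wavelets) are out of scope.
- Shifts beyond half a period alias under wrapping.
- The two-way ANOVA post-tests assume a crossed, non-empty design and at
  least 3 observations per cell.
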