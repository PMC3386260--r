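---
title: "Quantifying behavior-coupled modulation of SCN multiunit activity"
author: "scncoupling developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavior-coupled modulation of SCN multiunit activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scncoupling)
```

## The scientific problem

The suprachiasmatic nucleus (SCN) is the hypothalamic master circadian
pacemaker. Its pooled extracellular spike rate (multiunit activity, MUA)
oscillates with a ~24 h rhythm: high during the subjective day — the rest
phase of a nocturnal rodent — and low during the subjective night, in
antiphase with the animal's behavioral activity rhythm. On top of that slow
rhythm, spontaneous behavior acts back on the pacemaker: when a mouse starts
grooming, moving about, or walking, SCN firing drops abruptly, stays
suppressed for as long as the behavior lasts, and then recovers slowly —
over many minutes — along an approximately exponential time course. Mild
external disturbance of a resting animal produces the opposite response, a
brief excitation transient. Because behavior is concentrated in the night,
this feedback deepens the night trough of the SCN rhythm and thereby
*increases* the amplitude of the pacemaker's electrical output.

`scncoupling` turns that analysis into a reusable, tested pipeline. Its
inputs are the three recorded streams of such an experiment:

* spike counts in uniform 2-s bins (`mua.tsv`),
* a passive-infrared (PIR) motion signal in the same bins (`pir.tsv`),
* a video-scored ethogram at 1-s resolution with the nine behavior
  categories digging, drinking, eating, grooming, lying, moving, rearing,
  sitting, walking (`ethogram.tsv`).

Because raw recordings of this kind are not publicly deposited, the package
carries a first-class synthetic-data generator with known ground truth, so
every estimator can be validated by parameter recovery.

## The core statistic

For each behavior bout preceded by at least 2 min of quiescence (lying or
sitting), the pipeline computes

* the **baseline** `B`: mean firing rate over the 2 min immediately before
  bout onset;
* the **suppressed level** `S`: mean rate from bout onset to bout offset;
* the **circadian amplitude** `A`: peak minus trough of the smoothed MUA
  rhythm, taken from the cycle containing the event (the recording mean is
  the fallback for events outside complete cycles);
* the **suppression magnitude** `M = 100 (B - S) / A`, in percent of the
  circadian amplitude.

`M` is dimensionless and invariant to rescaling the whole recording, which
makes it comparable across animals and electrodes.

The smoothing step follows the field's criterion rather than a fixed kernel:
a centered moving average on 10-s rebinned counts whose bandwidth is the
*smallest* value on the grid 0.5, 1, ..., 6 h for which every complete cycle
(lights-off to lights-off, or CT12 to CT12) contains exactly one local
maximum and one local minimum. Two numerical choices make this criterion
robust on finite, noisy data:

* extrema are counted after prominence filtering (swings below 5% of the
  smoothed range are noise wiggles, not extrema), and
* peak/trough *levels* are the mean of the smoothed trace over the
  contiguous plateau around the cycle's global extremum (capped at ±30 min).
  A pointwise max/min of a noisy curve is biased outward by extreme-value
  selection; plateau averaging removes that bias while leaving the extremum
  *times* untouched.

If no bandwidth satisfies the criterion the fit is reported as arrhythmic
and the amplitude (hence `M`) is undefined — a deliberate, explicit failure
mode rather than a silent fallback.

## Event detection

The calibration study hand-selected "clear suppressions"; a pipeline needs
an explicit rule. Ours is: a quiescence-preceded bout is a suppression event
when the drift-corrected drop exceeds `z = 3` Poisson standard errors *and*
the magnitude reaches `m_min = 10` percent of the amplitude. Both knobs are
exposed. Three refinements matter in practice:

* **Drift correction.** A bout riding the dusk downslope of the circadian
  rhythm loses rate for reasons that have nothing to do with coupling. The
  detector therefore compares the observed drop against the change predicted
  by a phase-folded clean-rhythm profile (the average of all
  non-event-masked 10-s bins at the same circadian phase, in 5-min phase
  bins). The *reported* magnitude stays in its standard uncorrected form.
* **Masked rhythm fit.** Behaviorally active bins plus a 25-min post-bout
  margin (five recovery time constants) are excluded from the smoothing fit,
  so suppressions and their tails do not drag the trough — and hence inflate
  the amplitude denominator.
* **Baseline hygiene.** Bouts separated by less than 2 min of quiescence
  merge into one event; a bout starting within 15 min (~3 recovery
  constants) of the previous offset reuses the previous baseline instead of
  a recovery-contaminated window.

With these rules the detector's false-positive rate on uncoupled synthetic
recordings is below 0.5% per bout (it measured 0 in 1052 null bouts in the
test suite), which in turn calibrates the per-animal responsiveness test: an
animal is *responsive* when its fraction of detected suppressions exceeds
the null rate by a one-sided binomial test at the 99% level, given at least
20 evaluated bouts.

## Recovery kinetics

After bout offset the deficit decays exponentially. Two statistics are
reported per event:

* **return-to-baseline time**: the first time after offset at which the
  10-s-rebinned rate stays within `B ± 2` Poisson SEs (of a 10-s bin) for 6
  consecutive bins;
* **recovery time constant** τ: a log-linear fit of `log(B - rate)` against
  time over the decay segment — the leading bins whose deficit still exceeds
  3 Poisson SEs. Fitting in log space over the above-noise prefix avoids the
  strong upward bias that whole-window least squares picks up from
  circadian drift in the tail.

## Excitation transients

For each logged disturbance time, an excitation event is declared when the
10-s rate exceeds `B + 3 SE` within 30 s; its duration is the time spent
above the band, and it is post-classified as *undershoot* when the rate
subsequently falls below `B - 3 SE` for two consecutive bins (one bin alone
would misfire on ~0.1% noise), else *return*. Disturbances that fall inside
an ongoing suppression are flagged and excluded.

## Subpopulation decomposition

When per-spike amplitudes are available, a 100-s quiescent baseline window
before a bout defines an amplitude histogram. Thresholds are placed at the
empirical `i/k` quantiles of the above-noise baseline amplitudes — midway
between the adjacent order statistics — producing `k` contiguous,
non-overlapping windows with equal baseline counts (within one spike).
Spikes at a boundary belong to the upper window. Counting spikes per window
per time bin conserves the total above-noise count exactly, and the
per-window magnitudes (each window uses its `A/k` share of the amplitude)
feed a heterogeneity test: the response is *heterogeneous* when the largest
window contrast exceeds twice its pooled Poisson SE. The default `k = 2`
mirrors the two-population decomposition of the calibration study, with
18 Hz per window during an example baseline.

## Behavior-conditioned profiles and amplitude scenarios

Labeling every 10-s bin *active* (any PIR signal) or *inactive* and
smoothing each subset separately (each masking the other's bins) yields two
circadian curves. On coupled recordings the active curve runs below the
inactive one. Two bounding scenarios follow directly:

* night-concentrated activity: amplitude `peak(inactive) - trough(active)`,
* day-concentrated activity: amplitude `peak(active) - trough(inactive)`.

For a phase-uniform absolute suppression `s` these equal `A0 + s` and
`A0 - s`, so they always sum to `2 A0` — an algebraic identity the test
suite checks. Group statistics (per-type ANOVA with Bonferroni pairwise
tests, day/night comparison with the animal as a blocking factor when at
least two animals are present, per-circadian-hour summaries) complete the
analysis; the one-way ANOVA is computed from explicit sums of squares and is
cross-checked in the tests against `stats::lm` and a permutation null.

## What the generator emulates — and what it does not

The generator is the package's study-condition statement. Its defaults are:

| parameter | default | meaning |
|---|---|---|
| `period_h`, `regime` | 24 h, LD12:12 | lighting only affects phase labels |
| `peak_rate` / `trough_rate` | 400 / 160 Hz | day/night MUA plateaus; `A` = 240 Hz |
| `depth_table` | grooming 0.32, moving 0.43, walking 0.59 | mean suppression depth as a fraction of `A`, by initiating behavior |
| `depth_sd` | 0.03 | per-event Gaussian depth variability |
| `day/night_depth_scale` | 1.052 / 0.963 | multiplicative phase scaling so day events average 47% and night events 43% |
| `tau_rec_min` | 5 min | exponential recovery constant (return time ≈ 3 τ) |
| `duration_mixture` | 0.20 / 0.65 / 0.15 | bout classes <1 min, 1–25 min, >25 min |
| `nocturnality` | 0.85 | fraction of bout time in subjective night |
| `pir_miss_prob` | 0.3 | PIR misses 30% of truly active bins; no false positives |
| `cohort` | 9 of 14 coupled; 4 of 5 others light-responsive (flag only) | |
| `duration_h` | 288 h | 12 days ≈ 95 events per initiating type, so per-type means carry ~0.3-point SEMs |

The circadian waveform is a smoothed trapezoid (sigmoidal 2-h transitions)
rather than a sinusoid: plateau-like day levels make per-cycle peaks and
troughs well defined. Within-class bout durations are uniform on 10–60 s,
log-uniform on 1–25 min, and uniform on 25–45 min. Night inter-bout gaps are
uniform on 17–40 min; the mean day gap is derived from `nocturnality`.
Spike counts are Poisson given the modulated rate; the amplitude stream
draws each spike's subpopulation (equal baseline rates, suppression confined
to the responsive one) and a Gaussian amplitude per subpopulation.

The rate scale deserves a note. The recovery-time estimator's band is a
noise quantity, so the mean return time depends on the deficit-to-noise
ratio `D / SE ≈ depth · A / sqrt(B / 10)`: the plateaus were chosen (once,
a priori) so that with τ = 5 min the simulated mean return lands on the
~15-min scale reported in vivo, while keeping the night plateau above the
deepest night suppression so the non-negativity floor never truncates an
injected event. Lower overall rates leave every magnitude unchanged (M is
scale-free) but shorten the measured return time.

Two generator parameters are jointly over-constrained by the calibration
targets: the per-type depth table (32/43/59) and the day/night scaling
(47/43). With 85% of bouts at night, the night scale (0.963) multiplies most
events, so recovered per-type means sit ~1–2 points below the table values;
both sets of targets still fall within their stated tolerances. We kept the
two calibrations as specified rather than inventing a compromise.

What the generator does *not* emulate: biophysical neuron models, light
responses (light-responsiveness is a flag only), stress/arousal mechanisms,
PIR false positives, electrode drift, non-stationary periods, or
non-Poisson overdispersion. Passing parameter-recovery tests therefore shows
the estimators are correct under these statistical conditions, not that real
recordings satisfy them — on real data, overdispersion would widen the
detector's effective error rates, and period drift would smear the
phase-folded drift reference.

## Degenerate inputs and tie-breaks

* `peak_rate == trough_rate` gives a constant trace; the rhythm fit reports
  *arrhythmic* and everything downstream that needs `A` refuses to run.
* Flat plateaus in noiseless traces: extremum position is the plateau
  midpoint.
* The 1–25 min duration class is closed at 25 min; `<1 min` is [0, 60) s.
* A 2-s bin counts as behaviorally active when non-quiescent behavior covers
  at least 1 s of it.
* Event windows use bin-center membership, matching the one-bin resolution
  at which a step change can be localized.
* `nocturnality = 1` trims bouts at the day boundary so no bout second falls
  in subjective day.

## Reproducibility

Every stochastic component draws from a child seed derived from the master
seed by a fixed offset (`child_seed()`), so a configuration plus seed
reproduces a recording bit-identically, cohort animals are independent, and
changing one component's draw order cannot silently shift another's. The
`run_simulate()` / `run_analyze()` wrappers write manifests with input/output
digests; re-running an analysis on the same inputs reproduces the same
digests.

Problem sizes used by the bundled recovery runs (`recover_*()` and
`scripts/acceptance.R`): 12 days for the per-type run, 10 days with 35–60 min
gaps for the recovery-kinetics run (every event then has a clean 30-min
tail), 11 days at `nocturnality = 0.5` for the day/night run (mirroring the
near-equal day/night observation counts of the calibration data), 14 × 2
days for the cohort, and chunked 27-day recordings until 10,000 bouts for
the duration mixture. These sizes put Monte-Carlo SEMs well inside the
tolerances they are compared against.
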