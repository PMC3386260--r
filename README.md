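# scncoupling

Quantifying how behavioral activity acutely modulates the electrical output
of the suprachiasmatic nucleus (SCN), the master circadian pacemaker.

In vivo multiunit activity (MUA) recorded from the SCN of a freely moving
nocturnal rodent oscillates with the circadian cycle — high in the
subjective day (rest phase), low in the subjective night — in antiphase
with the animal's behavior. Superimposed on that rhythm, spontaneous
behavior feeds back on the pacemaker: at the onset of grooming, moving or
walking the firing rate drops abruptly, stays suppressed for the duration
of the bout, and recovers exponentially over many minutes, while mild
disturbance of a resting animal evokes a brief excitation instead. Because
behavior concentrates in the night, this feedback deepens the circadian
trough and *boosts* the amplitude of the SCN rhythm.

`scncoupling` implements the full analysis for such experiments, for
chronobiologists and neurophysiologists working with binned spike counts,
passive-infrared (PIR) activity signals, and video-scored ethograms:

* **Rhythm**: smoothing by the lowest-bandwidth single-peak/single-trough
  criterion, per-cycle peak/trough levels, circadian amplitude
  `A = peak − trough`, ZT/CT phase mapping.
* **Suppression events**: for each behavior bout preceded by ≥ 2 min
  quiescence, baseline `B` (last 2 min before onset), suppressed mean `S`,
  and the magnitude

  `M = 100 · (B − S) / A`  (percent of circadian amplitude),

  with drift-corrected Poisson detection (`z = 3`, `M ≥ 10%`), duration
  classes (<1 min / 1–25 min / >25 min), return-to-baseline times,
  exponential recovery constants, and a calibrated per-animal
  responsiveness test.
* **Excitations**: disturbance-evoked transients with latency, duration and
  undershoot classification.
* **Subpopulations**: equal-count spike-amplitude threshold windows from a
  100-s baseline and per-window suppression contrasts.
* **Profiles**: behavior-conditioned circadian curves and the two bounding
  amplitude scenarios (night-concentrated vs day-concentrated activity),
  plus per-type ANOVA, day/night and per-hour statistics.
* **Synthetic data**: a ground-truth generator (circadian trapezoid rate,
  behavior schedule, coupling with exponential recovery, Poisson spikes,
  lossy PIR channel, two-subpopulation amplitude stream, 14-animal cohort)
  so every estimator is validated by parameter recovery.

## Worked example

```r
library(scncoupling)

cfg <- sim_config(duration_h = 96, seed = 42)   # 4 simulated days
sim <- simulate_recording(cfg, seed = 42)
sim
#> <scn_sim> 96.0 h, 172800 MUA bins, 77 bouts, coupled

res <- analyze_recording(sim, recovery = TRUE)
res$fit
#> <rhythm_fit> bandwidth 0.5 h, 3 complete cycle(s), mean amplitude 242.21 Hz

ev <- res$events
magnitude_by_type(ev)$by_type
#>   initiating mean_pct sem_pct  n
#> 1   grooming     31.2   0.806 25
#> 2     moving     40.4   1.131 22
#> 3    walking     56.6   0.745 30

ok <- !is.na(ev$return_min) & !ev$censored
mean(ev$return_min[ok])
#> [1] 13.0  # minutes to return to baseline (n = 43 clean tails)

prof <- conditioned_profiles(sim$mua, sim$pir)
amplitude_scenarios(prof)
#> night-active 363 Hz (138% of baseline amplitude)
#> day-active   199 Hz (76%)
```

Reading: the smoothed rhythm has a 242-Hz circadian amplitude (the
generator's true value is 240 Hz). Suppression magnitude grades with the
intensity of the initiating behavior — grooming ~31%, moving ~40%, walking
~57% of the circadian amplitude (ANOVA across types F(2,74) = 231,
p < 1e-30) — and firing needs ~13 min to return to baseline after a bout.
The amplitude scenarios quantify the feedback loop: activity concentrated
at night enlarges the effective rhythm amplitude to 138% of its
behavior-free value, while the same activity placed in the day would shrink
it to 76%.

File-based workflows use the same pipeline:

```r
run_simulate(cfg, "simdir", seed = 42)   # mua.tsv, pir.tsv, ethogram.tsv, ...
run_analyze("simdir", "outdir")          # events_suppression.tsv, stats.json, ...
```

or from a shell via the thin wrapper
`Rscript inst/cli/scn-coupling.R simulate|analyze ...`.

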