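period_h: 24.0
regime: LD12:12
duration_h: 48.0
peak_rate: 400.0
trough_rate: 160.0
mua_bin_s: 2.0
etho_bin_s: 1.0
depth_table:
  grooming: 0.32
  moving: 0.43
  walking: 0.59
depth_sd: 0.03
day_depth_scale: 1.0522388
night_depth_scale: 0.9626866
tau_rec_min: 5.0
duration_mixture:
- 0.2
- 0.65
- 0.15
nocturnality: 0.85
gap_night_min_s: 1020.0
gap_night_max_s: 2400.0
sustain_prob: 0.5
pir_miss_prob: 0.3
excitation:
  increment_frac: 0.4
  dur_min_s: 10.0
  dur_max_s: 200.0
  undershoot: no
cohort:
  n_animals: 14.0
  n_responsive: 9.0
  n_light_responsive_nonbehavioral: 4.0
cohort_duration_h: 48.0
amp_dists:
  noise_sigma: 1.0
  threshold: 3.0
  nonresponsive:
    mean: 4.5
    sd: 0.6
  responsive:
    mean: 9.0
    sd: 1.2
seed: 1
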