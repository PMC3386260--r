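# Small shared fixtures. Everything is generated in code; durations are kept
# short so the default test run stays fast.

# a 2-day default-parameter config
quick_config <- function(...) {
  sim_config(duration_h = 48, seed = 101L, ...)
}

# cached 2-day coupled recording + analysis, built once per test run
cached_sim <- local({
  env <- new.env()
  function() {
    if (is.null(env$sim)) {
      env$sim <- simulate_recording(quick_config(), seed = 101L)
      env$res <- analyze_recording(env$sim)
    }
    list(sim = env$sim, res = env$res)
  }
})

# noiseless sinusoidal counts series: period 24 h, mean `mid`, half-range
# `amp` Hz, peak at ZT6
sine_counts <- function(days = 2, bin_s = 10, mid = 50, amp = 20,
                        peak_h = 6) {
  t <- seq(0, days * 86400 - bin_s, by = bin_s) + bin_s / 2
  rate <- mid + amp * cos(2 * pi * (t / 3600 - peak_h) / 24)
  binned_series(rate * bin_s, bin_s = bin_s, channel = "mua")
}

# an ethogram with a single bout of `behavior` inside quiescence
single_bout_etho <- function(onset, offset, total, behavior = "walking") {
  ethogram(c(0, onset, offset), c(onset, offset, total),
           c("lying", behavior, "lying"))
}
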