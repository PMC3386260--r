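test_that("baseline rate is the mean over the last two minutes before the event", {
  s <- binned_series(rep(40, 300), 2, channel = "mua")  # constant 20 Hz
  expect_equal(baseline_rate(s, 400), 20)
  alt <- binned_series(rep(c(20, 60), 150), 2, channel = "mua")  # 10/30 Hz
  expect_equal(baseline_rate(alt, 400), 20)
  expect_error(baseline_rate(s, 60), "before the event")
})

test_that("magnitude formula and scale invariance", {
  expect_equal(suppression_magnitude(30, 18, 25), 48)
  expect_equal(suppression_magnitude(20, 20, 25), 0)
  expect_error(suppression_magnitude(30, 18, 0), "positive")
  # M is invariant to rescaling the whole trace by a positive constant
  for (c in c(0.5, 2, 7.3)) {
    expect_equal(suppression_magnitude(30 * c, 18 * c, 25 * c),
                 suppression_magnitude(30, 18, 25))
  }
})

test_that("duration classes use the stated boundaries", {
  expect_equal(classify_duration(c(10, 59)), c("<1 min", "<1 min"))
  expect_equal(classify_duration(60), "1-25 min")
  expect_equal(classify_duration(1500), "1-25 min")  # 25 min exactly
  expect_equal(classify_duration(1501), ">25 min")
})

test_that("an injected step suppression is detected with onset at the bout bounds", {
  # clean trace at 100 Hz, amplitude denominator from a sinusoidal fit proxy:
  # build a rhythmic recording, then carve a 50%-of-amplitude step by hand
  cfg <- sim_config(duration_h = 48, depth_sd = 0, sustain_prob = 0,
                    seed = 33L)
  rate <- simulate_circadian_rate(cfg)
  onset <- 30 * 3600; offset <- onset + 600  # bout at ZT6 (subjective day)
  sch <- list(etho = single_bout_etho(onset, offset, 48 * 3600),
              bouts = data.frame(onset_s = onset, offset_s = offset,
                                 duration_s = 600, initiating = "walking",
                                 class = "1-25 min"))
  cfg2 <- cfg; cfg2$depth_table <- c(walking = 0.5)
  cfg2$day_depth_scale <- 1
  coup <- apply_coupling(rate, sch, config = cfg2, seed = 1L)
  mua <- sample_spikes(coup$rate, 2, seed = 2L)
  fit <- smooth_mua(mua, light_schedule(),
                    exclude_mask = event_exclusion_mask(sch$etho, 0,
                                                        length(mua$values), 2))
  ev <- detect_suppressions(mua, sch$etho, fit)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, onset)
  expect_equal(ev$offset_s, offset)
  expect_equal(ev$magnitude_pct, 50, tolerance = 0.1)  # +/- a few points
  expect_true(ev$is_day)
})

test_that("a 10-s bout with depth 0.6 at day phase is detected", {
  cfg <- sim_config(duration_h = 48, depth_sd = 0, sustain_prob = 0)
  rate <- simulate_circadian_rate(cfg)
  onset <- 30 * 3600 + 6 * 3600 * 0 + 6 * 3600  # 36 h = ZT12... keep day:
  onset <- 28 * 3600  # ZT4, subjective day
  sch <- list(etho = single_bout_etho(onset, onset + 10, 48 * 3600),
              bouts = data.frame(onset_s = onset, offset_s = onset + 10,
                                 duration_s = 10, initiating = "walking",
                                 class = "<1 min"))
  cfg2 <- cfg; cfg2$depth_table <- c(walking = 0.6); cfg2$day_depth_scale <- 1
  coup <- apply_coupling(rate, sch, config = cfg2, seed = 1L)
  mua <- sample_spikes(coup$rate, 2, seed = 5L)
  fit <- smooth_mua(mua, light_schedule(),
                    exclude_mask = event_exclusion_mask(sch$etho, 0,
                                                        length(mua$values), 2))
  ev <- detect_suppressions(mua, sch$etho, fit)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_class, "<1 min")
})

test_that("zero-coupling bouts yield (almost) no detections", {
  sim <- simulate_recording(sim_config(duration_h = 96, seed = 55L),
                            seed = 55L, coupled = FALSE)
  res <- analyze_recording(sim)
  expect_gt(res$n_bouts_tested, 50)
  expect_lte(nrow(res$events) / res$n_bouts_tested, 0.02)
})

test_that("return time matches the closed form on a noiseless exponential recovery", {
  # constant baseline B = 100 Hz, deficit D exp(-t/tau), tau = 5 min;
  # with the band at 5% of D the return time is tau * ln(20) ~ 15 min
  B <- 100; D <- 40; tau_s <- 300
  bin_s <- 2
  offset <- 1200
  t <- seq(bin_s / 2, 7200, by = bin_s)
  rate <- rep(B, length(t))
  post <- t >= offset
  rate[post] <- B - D * exp(-(t[post] - offset) / tau_s)
  s <- binned_series(rate * bin_s, bin_s, channel = "mua")
  rec <- recovery_time(s, offset, B, max_window_s = 6000,
                       band_hz = 0.05 * D)
  expect_equal(rec$return_min, 300 * log(20) / 60, tolerance = 0.15)
  expect_false(rec$censored)
  expect_equal(rec$tau_min, 5, tolerance = 0.15)
  # instant return: no recovery tail at all
  s2 <- binned_series(rep(B * bin_s, length(t)), bin_s, channel = "mua")
  rec2 <- recovery_time(s2, offset, B, band_hz = 0.05 * D)
  expect_lte(rec2$return_min, 10 / 60)
  # baseline never re-attained: censored flag
  s3 <- binned_series(rep((B - D) * bin_s, length(t)), bin_s,
                      channel = "mua")
  rec3 <- recovery_time(s3, offset, B, band_hz = 0.05 * D)
  expect_true(rec3$censored)
})

test_that("estimated magnitudes track injected depth monotonically and near-unbiased", {
  depths <- seq(0.1, 0.9, by = 0.1)
  cfg <- sim_config(duration_h = 48, depth_sd = 0, sustain_prob = 0)
  rate <- simulate_circadian_rate(cfg)
  m_hat <- vapply(seq_along(depths), function(i) {
    onset <- 30 * 3600
    sch <- list(etho = single_bout_etho(onset, onset + 300, 48 * 3600),
                bouts = data.frame(onset_s = onset, offset_s = onset + 300,
                                   duration_s = 300, initiating = "walking",
                                   class = "1-25 min"))
    cfgi <- cfg; cfgi$depth_table <- c(walking = depths[i])
    cfgi$day_depth_scale <- 1
    coup <- apply_coupling(rate, sch, config = cfgi, seed = 1L)
    mua <- sample_spikes(coup$rate, 2, seed = 100L + i)
    fit <- smooth_mua(mua, light_schedule(),
                      exclude_mask = event_exclusion_mask(sch$etho, 0,
                                                          length(mua$values),
                                                          2))
    ev <- detect_suppressions(mua, sch$etho, fit, m_min = 4)
    if (nrow(ev)) ev$magnitude_pct else NA_real_
  }, numeric(1))
  expect_true(all(!is.na(m_hat)))
  expect_gt(cor(depths, m_hat, method = "spearman"), 0.95)
  # unbiased within ~2 points for 5-min events
  expect_lt(max(abs(m_hat - 100 * depths)), 2.5)
})

test_that("excitation transients are detected with duration and undershoot class", {
  cfg <- sim_config(duration_h = 48, seed = 77L,
                    excitation = list(increment_frac = 0.4, dur_min_s = 60,
                                      dur_max_s = 60, undershoot = FALSE))
  rate <- simulate_circadian_rate(cfg)
  sch <- list(etho = ethogram(0, 48 * 3600, "lying"),
              bouts = data.frame(onset_s = numeric(0), offset_s = numeric(0),
                                 duration_s = numeric(0),
                                 initiating = character(0),
                                 class = character(0)))
  dist_t <- c(26 * 3600, 30 * 3600)
  coup <- apply_coupling(rate, sch, disturbance_times = dist_t, config = cfg,
                         seed = 1L)
  mua <- sample_spikes(coup$rate, 2, seed = 3L)
  fit <- smooth_mua(mua, light_schedule())
  ex <- detect_excitations(mua, dist_t, fit)
  expect_true(all(ex$detected))
  expect_equal(ex$duration_s, c(60, 60), tolerance = 10 / 60 + 0.2)
  expect_true(all(ex$post_class == "return"))
  # with the undershoot flag the transient is followed by a suppression
  cfg$excitation$undershoot <- TRUE
  coup2 <- apply_coupling(rate, sch, disturbance_times = dist_t,
                          config = cfg, seed = 1L)
  mua2 <- sample_spikes(coup2$rate, 2, seed = 3L)
  ex2 <- detect_excitations(mua2, dist_t, fit)
  expect_true(all(ex2$post_class == "undershoot"))
  # null disturbances: essentially no detections
  ex0 <- detect_excitations(mua, c(40 * 3600, 41 * 3600, 42 * 3600), fit)
  expect_lte(sum(ex0$detected), 1)
})

test_that("responsiveness classifier follows the binomial null calibration", {
  expect_equal(classify_animal_responsiveness(30, 40), "responsive")
  expect_equal(classify_animal_responsiveness(0, 40), "non-responsive")
  expect_equal(classify_animal_responsiveness(1, 40), "non-responsive")
  expect_equal(classify_animal_responsiveness(5, 10), "indeterminate")
  # depth-robust: halved depth table still detects nearly every bout
  cfg <- sim_config(duration_h = 48, seed = 91L)
  cfg$depth_table <- cfg$depth_table / 2
  sim <- simulate_recording(cfg, seed = 91L)
  res <- analyze_recording(sim)
  expect_equal(classify_animal_responsiveness(nrow(res$events),
                                              res$n_bouts_tested),
               "responsive")
})
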