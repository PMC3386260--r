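test_that("circadian rate trace has the configured plateaus and is deterministic", {
  cfg <- sim_config(peak_rate = 35, trough_rate = 8, duration_h = 48)
  r <- simulate_circadian_rate(cfg)
  expect_equal(max(r), 35, tolerance = 0.01)
  expect_equal(min(r), 8, tolerance = 0.01)
  expect_identical(r, simulate_circadian_rate(cfg))
  # degenerate rhythm: peak == trough gives a constant trace
  flat <- simulate_circadian_rate(sim_config(peak_rate = 20, trough_rate = 20,
                                             duration_h = 24))
  expect_equal(range(flat), c(20, 20))
  expect_error(simulate_circadian_rate(cfg, duration_h = -1), "duration")
})

test_that("rate is high in subjective day and low in subjective night", {
  cfg <- sim_config(peak_rate = 35, trough_rate = 8, duration_h = 24)
  r <- simulate_circadian_rate(cfg)
  tc <- (seq_along(r) - 0.5) * cfg$mua_bin_s
  ph <- (tc / 3600) %% 24
  expect_gt(min(r[is_subjective_day(tc) & abs(ph - 6) < 3]), 34)
  expect_lt(max(r[!is_subjective_day(tc) & abs(ph - 18) < 3]), 9)
})

test_that("behavior schedule honours the duration mixture and quiescence precondition", {
  cfg <- sim_config(duration_h = 24 * 40, seed = 1L)
  sch <- simulate_behavior_schedule(cfg, seed = 1L)
  b <- sch$bouts
  expect_gt(nrow(b), 500)
  fr <- table(factor(b$class, c("<1 min", "1-25 min", ">25 min"))) / nrow(b)
  expect_equal(unname(as.numeric(fr)), c(0.20, 0.65, 0.15), tolerance = 0.12)
  # non-overlap and >= 2 min pre-bout quiescence
  expect_true(all(b$onset_s[-1L] - b$offset_s[-nrow(b)] >= 120))
  # night bias close to the configured nocturnality
  night_frac <- sum(b$duration_s[!is_subjective_day(b$onset_s)]) /
    sum(b$duration_s)
  expect_equal(night_frac, 0.85, tolerance = 0.08)
})

test_that("schedule is reproducible under a fixed seed and all-night under nocturnality 1", {
  cfg <- quick_config()
  a <- simulate_behavior_schedule(cfg, seed = 3L)
  b <- simulate_behavior_schedule(cfg, seed = 3L)
  expect_identical(a, b)
  cfg1 <- quick_config(nocturnality = 1)
  sch <- simulate_behavior_schedule(cfg1, seed = 3L)
  sec <- unlist(mapply(function(s, e) s:(e - 1), sch$bouts$onset_s,
                       sch$bouts$offset_s, SIMPLIFY = FALSE))
  expect_true(all(!is_subjective_day(sec)))
})

test_that("coupling injects depth x amplitude at onset and an exponential tail", {
  cfg <- sim_config(peak_rate = 35, trough_rate = 8, duration_h = 24,
                    depth_sd = 0, sustain_prob = 0,
                    depth_table = c(walking = 0.59))
  rate <- simulate_circadian_rate(cfg)
  # one walking bout in mid-day: depth 0.59 scaled by the day factor
  sch <- list(etho = single_bout_etho(6 * 3600, 6 * 3600 + 600, 86400),
              bouts = data.frame(onset_s = 6 * 3600, offset_s = 6 * 3600 + 600,
                                 duration_s = 600, initiating = "walking",
                                 class = "1-25 min"))
  coup <- apply_coupling(rate, sch, config = cfg, seed = 1L)
  A <- 27
  drop_expected <- 0.59 * cfg$day_depth_scale * A
  i_in <- which((seq_along(rate) - 0.5) * 2 > 6 * 3600 + 2 &
                  (seq_along(rate) - 0.5) * 2 < 6 * 3600 + 598)
  expect_equal(max(rate[i_in] - coup$rate[i_in]), drop_expected,
               tolerance = 1e-6)
  # deficit at tau minutes past offset is D / e (exponential law)
  tc <- (seq_along(rate) - 0.5) * 2
  i_tau <- which.min(abs(tc - (6 * 3600 + 600 + cfg$tau_rec_min * 60)))
  expect_equal(coup$deficit[i_tau], drop_expected * exp(-1), tolerance = 0.01)
  # conservation: untouched bins are unmodified
  before <- tc < 6 * 3600
  expect_identical(coup$rate[before], rate[before])
})

test_that("within-bout escalation steps the depth down at the more intense behavior", {
  cfg <- sim_config(peak_rate = 35, trough_rate = 8, duration_h = 24,
                    depth_sd = 0)
  rate <- simulate_circadian_rate(cfg)
  # moving -> eating (sustains) -> walking (escalates), mid-day
  s <- 6 * 3600
  etho <- ethogram(c(0, s, s + 200, s + 400, s + 600),
                   c(s, s + 200, s + 400, s + 600, 86400),
                   c("lying", "moving", "eating", "walking", "lying"))
  sch <- list(etho = etho,
              bouts = data.frame(onset_s = s, offset_s = s + 600,
                                 duration_s = 600, initiating = "moving",
                                 class = "1-25 min"))
  coup <- apply_coupling(rate, sch, config = cfg, seed = 1L)
  tc <- (seq_along(rate) - 0.5) * 2
  d_moving <- mean(coup$deficit[tc > s + 20 & tc < s + 180])
  d_eating <- mean(coup$deficit[tc > s + 220 & tc < s + 380])
  d_walking <- mean(coup$deficit[tc > s + 420 & tc < s + 580])
  expect_equal(d_eating, d_moving, tolerance = 1e-9)   # eating only sustains
  expect_gt(d_walking, d_moving)                       # walking deepens
  expect_equal(d_walking / d_moving, 0.59 / 0.43, tolerance = 1e-6)
})

test_that("spike sampling is Poisson: mean and dispersion", {
  counts <- sample_spikes(rep(20, 1e5), bin_s = 2, seed = 4L)
  m <- mean(counts$values)
  expect_equal(m, 40, tolerance = 0.01)  # 40 +/- 0.4 at 1e5 bins
  expect_gt(var(counts$values) / m, 0.97)
  expect_lt(var(counts$values) / m, 1.03)
  expect_identical(sample_spikes(rep(20, 10), 2, seed = 4L)$values,
                   sample_spikes(rep(20, 10), 2, seed = 4L)$values)
  expect_true(all(sample_spikes(rep(0, 100), 2, seed = 1L)$values == 0))
  expect_error(sample_spikes(c(1, -1), 2, seed = 1L), "non-negative")
})

test_that("PIR channel misses active bins at the configured rate and never false-alarms", {
  cfg <- quick_config(pir_miss_prob = 0.3)
  # one long active block covering 10^4 2-s bins
  etho <- ethogram(c(0, 1000, 21000), c(1000, 21000, 22000),
                   c("lying", "walking", "sitting"))
  pir <- simulate_pir(etho, cfg, seed = 9L, n_bins = 11000)
  active <- activity_indicator(etho, 0, 11000, 2)
  expect_true(all(pir$values[!active] == 0))
  expect_equal(mean(pir$values[active]), 0.7, tolerance = 0.03)
  # boundary settings
  p0 <- simulate_pir(etho, quick_config(pir_miss_prob = 0), seed = 9L,
                     n_bins = 11000)
  expect_identical(p0$values, as.numeric(active))
  p1 <- simulate_pir(etho, quick_config(pir_miss_prob = 1), seed = 9L,
                     n_bins = 11000)
  expect_true(all(p1$values == 0))
})

test_that("simulated counts are in antiphase with behavioral activity", {
  x <- cached_sim()
  sim <- x$sim
  active <- activity_indicator(sim$etho, 0, length(sim$mua$values), 2)
  sm <- stats::filter(sim$mua$values, rep(1 / 901, 901), sides = 2)
  keep <- !is.na(sm)
  expect_lt(cor(as.numeric(sm[keep]), as.numeric(active[keep])), -0.3)
})

test_that("whole-recording simulation is deterministic and conserves clean segments", {
  cfg <- quick_config()
  a <- simulate_recording(cfg, seed = 11L)
  b <- simulate_recording(cfg, seed = 11L)
  expect_identical(a$mua$values, b$mua$values)
  expect_identical(a$pir$values, b$pir$values)
  expect_identical(a$etho, b$etho)
  # conservation: rate equals the clean trace away from bouts/tails
  touched <- a$deficit > 0
  expect_identical(a$rate_true[!touched], a$rate_clean[!touched])
})

test_that("cohort has the configured number of coupled animals and flags", {
  cfg <- quick_config(cohort_duration_h = 24)
  coh <- simulate_cohort(cfg, seed = 2L)
  expect_length(coh$animals, 14)
  has_events <- vapply(coh$animals,
                       function(a) any(a$bouts$depth > 0), logical(1))
  expect_equal(sum(has_events), 9)
  expect_equal(sum(coh$flags$light_responsive), 4)
  expect_true(all(!coh$flags$responsive[coh$flags$light_responsive]))
  coh0 <- simulate_cohort(quick_config(
    cohort_duration_h = 24,
    cohort = list(n_animals = 3, n_responsive = 0,
                  n_light_responsive_nonbehavioral = 0)), seed = 2L)
  expect_true(all(!vapply(coh0$animals, function(a) any(a$bouts$depth > 0),
                          logical(1))))
})
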