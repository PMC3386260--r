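test_that("one-way ANOVA matches the hand-computed textbook oracle", {
  # {2,4,6} vs {10,12,14}: SSB = 96, SSW = 16, df = (1,4), F = 24
  a <- anova_oneway(c(2, 4, 6, 10, 12, 14), rep(c("a", "b"), each = 3))
  expect_equal(a$F, 24)
  expect_equal(a$df1, 1); expect_equal(a$df2, 4)
  expect_equal(a$ss_between, 96); expect_equal(a$ss_within, 16)
  # degenerate: identical groups with zero variance
  expect_equal(anova_oneway(rep(5, 6), rep(c("a", "b"), 3))$p, 1)
  # distinct means, zero within-variance: F -> Inf, p -> 0 convention
  d <- anova_oneway(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3))
  expect_equal(d$F, Inf); expect_equal(d$p, 0)
  # three equal-mean groups: F ~ 0 is not forced, but p is large
  e <- anova_oneway(c(1, 2, 3, 1, 2, 3, 1, 2, 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(e$F, 0); expect_equal(e$p, 1)
})

test_that("ANOVA agrees with stats::lm and with a permutation null on small tables", {
  set.seed(3)
  x <- rnorm(18, mean = rep(c(0, 0.5, 1.5), each = 6))
  g <- rep(c("a", "b", "c"), each = 6)
  mine <- anova_oneway(x, g)
  ref <- anova(stats::lm(x ~ g))
  expect_equal(mine$F, ref$`F value`[1])
  expect_equal(mine$p, ref$`Pr(>F)`[1])
  # permutation F-null agreement within Monte-Carlo error
  set.seed(4)
  perm <- replicate(2000, anova_oneway(sample(x), g)$F)
  p_perm <- mean(perm >= mine$F)
  expect_lt(abs(p_perm - mine$p), 0.03 + 2 * sqrt(mine$p * (1 - mine$p) / 2000))
})

test_that("magnitude_by_type reports per-type means with Bonferroni pairwise flags", {
  set.seed(5)
  ev <- data.frame(
    initiating = rep(c("grooming", "moving", "walking"), each = 40),
    magnitude_pct = rnorm(120, rep(c(32, 43, 59), each = 40), 6))
  mt <- magnitude_by_type(ev)
  expect_equal(mt$by_type$initiating, c("grooming", "moving", "walking"))
  expect_equal(mt$by_type$mean_pct, c(32, 43, 59), tolerance = 0.15)
  expect_lt(mt$anova$p, 0.01)
  expect_true(all(mt$pairwise$significant))
  # a type with n < 2 is excluded with a warning
  ev2 <- rbind(ev, data.frame(initiating = "digging", magnitude_pct = 50))
  expect_warning(magnitude_by_type(ev2), "digging")
})

test_that("day/night statistics report (mean, SEM, n) and a sensible verdict", {
  set.seed(6)
  ev <- data.frame(
    magnitude_pct = c(rnorm(260, 47, 8), rnorm(230, 43, 8)),
    is_day = rep(c(TRUE, FALSE), c(260, 230)))
  dn <- day_night_stats(ev)
  expect_equal(unname(dn$day["n"]), 260)
  expect_equal(unname(dn$night["n"]), 230)
  expect_equal(unname(dn$day["mean"]), 47, tolerance = 0.05)
  expect_gt(unname(dn$day["mean"]), unname(dn$night["mean"]))
  expect_true(dn$significant)
  expect_match(dn$method, "one-way")
  # identical populations: non-significant
  set.seed(7)
  same <- data.frame(magnitude_pct = rnorm(100, 45, 5),
                     is_day = rep(c(TRUE, FALSE), 50))
  expect_gt(day_night_stats(same)$p, 0.05)
  # blocking on animal kicks in with >= 2 animals
  ev$animal <- rep(1:2, length.out = nrow(ev))
  expect_match(day_night_stats(ev)$method, "two-way")
  expect_error(day_night_stats(ev[ev$is_day, ]), "one phase class")
})

test_that("per-hour profile uses [h, h+1) bins and reports empty hours as n = 0", {
  ev <- data.frame(phase_h = 0:23 + 0.5, magnitude_pct = rep(40, 24))
  ph <- per_hour_profile(ev)
  expect_equal(nrow(ph), 24)
  expect_true(all(ph$n == 1))
  ev2 <- data.frame(phase_h = rep(14.2, 7), magnitude_pct = rep(40, 7))
  ph2 <- per_hour_profile(ev2)
  expect_equal(ph2$n[ph2$hour == 14], 7)
  expect_equal(sum(ph2$n), 7)
})

test_that("conditioned profiles partition bins and sit lower when active (coupled data)", {
  x <- cached_sim()
  sim <- x$sim
  prof <- suppressWarnings(conditioned_profiles(sim$mua, sim$pir))
  expect_equal(sum(prof$active) + sum(!prof$active), length(prof$rate_hz))
  sc <- amplitude_scenarios(prof)
  # behaviorally active trace is suppressed -> night-active scenario gains
  expect_gt(sc$night_active_hz, sc$day_active_hz)
  expect_gt(sc$night_active_pct, 100)
  expect_lt(sc$day_active_pct, 100)
})

test_that("uncoupled recordings show indistinguishable conditioned curves", {
  # balanced day/night activity so both subsets cover both phases well
  sim <- simulate_recording(sim_config(duration_h = 96, seed = 71L,
                                       nocturnality = 0.5),
                            seed = 71L, coupled = FALSE)
  prof <- suppressWarnings(conditioned_profiles(sim$mua, sim$pir))
  sc <- amplitude_scenarios(prof)
  # both scenarios equal the baseline amplitude within a few percent
  expect_equal(sc$night_active_pct, 100, tolerance = 0.05)
  expect_equal(sc$day_active_pct, 100, tolerance = 0.05)
  # active and inactive levels agree on the flat night plateau (no coupling)
  night <- prof$phase_h >= 15 & prof$phase_h < 21
  ma <- mean(prof$rate_hz[night & prof$active])
  mi <- mean(prof$rate_hz[night & !prof$active])
  se <- sqrt(var(prof$rate_hz[night]) / sum(night & prof$active) +
               var(prof$rate_hz[night]) / sum(night & !prof$active))
  expect_lt(abs(ma - mi), 3 * se)
})

test_that("amplitude scenarios obey the algebraic identity on constructed curves", {
  # uniform absolute suppression s of the active curve:
  # night-active = A0 + s, day-active = A0 - s, so their sum is 2 A0
  mkfit <- function(peak, trough) {
    structure(list(rhythmic = TRUE,
                   cycles = data.frame(peak_hz = peak, trough_hz = trough)),
              class = "rhythm_fit")
  }
  A0 <- 27; s <- 5
  prof <- structure(list(fit_inactive = mkfit(35, 8),
                         fit_active = mkfit(35 - s, 8 - s)),
                    class = "conditioned_profile")
  sc <- amplitude_scenarios(prof)
  expect_equal(sc$night_active_hz, A0 + s)
  expect_equal(sc$day_active_hz, A0 - s)
  expect_equal(sc$night_active_hz + sc$day_active_hz, 2 * A0)
  # s = 0: both scenarios equal the baseline amplitude
  prof0 <- structure(list(fit_inactive = mkfit(35, 8),
                          fit_active = mkfit(35, 8)),
                     class = "conditioned_profile")
  sc0 <- amplitude_scenarios(prof0)
  expect_equal(sc0$night_active_hz, A0)
  expect_equal(sc0$day_active_hz, A0)
})

test_that("all-inactive recordings leave the active subset empty", {
  sim <- simulate_recording(sim_config(duration_h = 36, seed = 81L,
                                       pir_miss_prob = 1), seed = 81L)
  expect_warning(conditioned_profiles(sim$mua, sim$pir), "coverage")
  prof <- suppressWarnings(conditioned_profiles(sim$mua, sim$pir))
  expect_equal(sum(prof$active), 0)
  expect_null(prof$fit_active)
  expect_error(amplitude_scenarios(prof), "missing")
})
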