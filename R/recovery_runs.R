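#' Headline parameter-recovery runs
#'
#' These helpers reproduce the package's calibration experiments: each one
#' simulates a synthetic recording under the default (or a documented
#' variant) configuration, runs the full analysis pipeline, and returns the
#' summary statistic of interest. They are used by the bundled recovery
#' script (`scripts/acceptance.R`) and by the test suite, so both always
#' execute the same code path.
#'
#' `recover_type_magnitudes()`: per-initiating-behavior mean suppression
#' magnitude under the default coupled recording.
#'
#' `recover_recovery_time()`: mean return-to-baseline time over well-separated
#' events (wider inter-bout gaps so each event has a clean 30-min tail).
#'
#' `recover_day_night()`: day/night mean magnitudes under the balanced
#' day/night scenario (nocturnality 0.5, mirroring the near-equal day and
#' night observation counts of the calibration study).
#'
#' `recover_cohort_responsiveness()`: percentage of cohort animals classified
#' behavior-responsive.
#'
#' `recover_duration_mixture()`: duration-class fractions of detected events
#' over at least `n_bouts` simulated bouts (simulated in chunks).
#'
#' @param seed integer seed.
#' @param duration_h recording length (hours) where applicable.
#' @param n_bouts minimum number of bouts for the duration-mixture run.
#' @return a named list of summary statistics (see each description).
#' @name recovery_runs
NULL

#' @rdname recovery_runs
#' @export
recover_type_magnitudes <- function(seed = 7L, duration_h = 288) {
  cfg <- sim_config(duration_h = duration_h, seed = seed)
  sim <- simulate_recording(cfg, seed = seed)
  res <- analyze_recording(sim)
  ev <- res$events
  means <- tapply(ev$magnitude_pct, ev$initiating, mean)
  ns <- tapply(ev$magnitude_pct, ev$initiating, length)
  list(mean = means, n = ns, events = ev)
}

#' @rdname recovery_runs
#' @export
recover_recovery_time <- function(seed = 13L, duration_h = 240) {
  cfg <- sim_config(duration_h = duration_h, seed = seed,
                    gap_night_min_s = 2100, gap_night_max_s = 3600)
  sim <- simulate_recording(cfg, seed = seed)
  res <- analyze_recording(sim, recovery = TRUE)
  ev <- res$events
  ok <- !is.na(ev$return_min) & !ev$censored
  list(mean_return_min = mean(ev$return_min[ok]), n = sum(ok),
       sd_return_min = stats::sd(ev$return_min[ok]),
       mean_tau_min = mean(ev$tau_min[ok], na.rm = TRUE))
}

#' @rdname recovery_runs
#' @export
recover_day_night <- function(seed = 17L, duration_h = 264) {
  cfg <- sim_config(duration_h = duration_h, nocturnality = 0.5, seed = seed)
  sim <- simulate_recording(cfg, seed = seed)
  res <- analyze_recording(sim)
  ev <- res$events
  list(day_mean = mean(ev$magnitude_pct[ev$is_day]),
       night_mean = mean(ev$magnitude_pct[!ev$is_day]),
       n_day = sum(ev$is_day), n_night = sum(!ev$is_day))
}

#' @rdname recovery_runs
#' @export
recover_cohort_responsiveness <- function(seed = 11L) {
  cfg <- sim_config(seed = seed)
  coh <- simulate_cohort(cfg, seed = seed)
  verdicts <- vapply(coh$animals, function(a) {
    res <- analyze_recording(a)
    classify_animal_responsiveness(nrow(res$events), res$n_bouts_tested)
  }, character(1))
  list(verdicts = verdicts, truth = coh$flags$responsive,
       n_responsive = sum(verdicts == "responsive"),
       pct_responsive = 100 * mean(verdicts == "responsive"))
}

#' @rdname recovery_runs
#' @export
recover_duration_mixture <- function(seed = 23L, n_bouts = 10000,
                                     chunk_h = 648) {
  classes <- character(0)
  total_bouts <- 0L
  chunk <- 0L
  while (total_bouts < n_bouts) {
    chunk <- chunk + 1L
    cfg <- sim_config(duration_h = chunk_h, seed = child_seed(seed, 200L + chunk))
    sim <- simulate_recording(cfg, seed = cfg$seed)
    res <- analyze_recording(sim)
    classes <- c(classes, res$events$duration_class)
    total_bouts <- total_bouts + nrow(sim$bouts)
  }
  fr <- table(factor(classes, levels = c("<1 min", "1-25 min", ">25 min")))
  list(fractions_pct = 100 * as.numeric(fr) / length(classes),
       labels = names(fr), n_bouts = total_bouts, n_events = length(classes))
}
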