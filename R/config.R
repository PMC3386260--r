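#' Simulation configuration for synthetic SCN recordings
#'
#' Builds and validates the parameter set that drives the synthetic-recording
#' generator. Defaults reproduce the study conditions the package is
#' calibrated against: a plateau-like circadian multiunit activity (MUA)
#' rhythm in antiphase with nocturnal behavior, behavior bouts whose
#' initiating type sets the suppression depth (as a fraction of the circadian
#' amplitude), immediate-onset suppression with slow exponential recovery,
#' brief excitation transients after induced disturbances, an imperfect PIR
#' observation channel, and two spike-amplitude subpopulations of which only
#' one is behavior-responsive.
#'
#' @param period_h circadian period in hours.
#' @param regime lighting regime label: `"LD12:12"`, `"DD"` or `"LL"`. The
#'   regime only affects phase labeling (ZT vs CT); the generative model is
#'   identical.
#' @param duration_h total simulated recording length in hours.
#' @param peak_rate,trough_rate day-plateau and night-plateau firing rates in
#'   Hz. Their difference is the circadian amplitude `A`. Defaults are chosen
#'   so that, together with Poisson counting noise and the default recovery
#'   time constant, simulated recoveries return to baseline on the ~15 min
#'   scale observed in vivo.
#' @param mua_bin_s MUA spike-count bin width in seconds.
#' @param etho_bin_s ethogram resolution in seconds.
#' @param depth_table named numeric vector mapping each *initiating* behavior
#'   type to its mean suppression depth as a fraction of amplitude.
#' @param depth_sd per-event Gaussian SD of the depth draw (fraction).
#' @param day_depth_scale,night_depth_scale multiplicative scaling of the
#'   depth mean for events starting in subjective day / night. Defaults are
#'   calibrated so that mean event magnitude is 47% (day) and 43% (night)
#'   given the default depth table.
#' @param tau_rec_min exponential recovery time constant after bout offset,
#'   minutes.
#' @param duration_mixture probabilities of the three bout-duration classes
#'   `<1 min`, `1-25 min`, `>25 min` (must sum to 1).
#' @param nocturnality target fraction of bout time falling in subjective
#'   night.
#' @param gap_night_min_s,gap_night_max_s range of the uniform inter-bout gap
#'   at night, seconds. The mean day gap is derived from `nocturnality`.
#' @param sustain_prob probability that a bout's tail is filled with
#'   sustaining behaviors (eating/rearing/drinking) that hold, but do not
#'   deepen, the suppression.
#' @param pir_miss_prob probability that a truly active 2-s bin produces no
#'   PIR signal.
#' @param excitation list with `increment_frac` (peak increment as a fraction
#'   of amplitude), `dur_min_s`, `dur_max_s` (log-uniform duration range) and
#'   `undershoot` (logical: follow the transient with a suppression).
#' @param cohort list with `n_animals`, `n_responsive`,
#'   `n_light_responsive_nonbehavioral`.
#' @param cohort_duration_h per-animal recording length used by
#'   [simulate_cohort()].
#' @param amp_dists spike-amplitude model: list with `noise_sigma`,
#'   `threshold` (noise floor) and per-subpopulation normal parameters
#'   `nonresponsive` and `responsive` (named `mean`, `sd`).
#' @param seed master seed; per-component child seeds are derived from it by
#'   fixed offsets (see [child_seed()]).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(duration_h = 48)
#' cfg$peak_rate - cfg$trough_rate  # circadian amplitude in Hz
sim_config <- function(period_h = 24,
                       regime = c("LD12:12", "DD", "LL"),
                       duration_h = 288,
                       peak_rate = 400,
                       trough_rate = 160,
                       mua_bin_s = 2,
                       etho_bin_s = 1,
                       depth_table = c(grooming = 0.32, moving = 0.43, walking = 0.59),
                       depth_sd = 0.03,
                       day_depth_scale = 47 / (100 * mean(c(0.32, 0.43, 0.59))),
                       night_depth_scale = 43 / (100 * mean(c(0.32, 0.43, 0.59))),
                       tau_rec_min = 5.0,
                       duration_mixture = c(0.20, 0.65, 0.15),
                       nocturnality = 0.85,
                       gap_night_min_s = 1020,
                       gap_night_max_s = 2400,
                       sustain_prob = 0.5,
                       pir_miss_prob = 0.3,
                       excitation = list(increment_frac = 0.4, dur_min_s = 10,
                                         dur_max_s = 200, undershoot = FALSE),
                       cohort = list(n_animals = 14, n_responsive = 9,
                                     n_light_responsive_nonbehavioral = 4),
                       cohort_duration_h = 48,
                       amp_dists = list(noise_sigma = 1, threshold = 3,
                                        nonresponsive = c(mean = 4.5, sd = 0.6),
                                        responsive = c(mean = 9, sd = 1.2)),
                       seed = 1L) {
  regime <- match.arg(regime)
  cfg <- list(period_h = period_h, regime = regime, duration_h = duration_h,
              peak_rate = peak_rate, trough_rate = trough_rate,
              mua_bin_s = mua_bin_s, etho_bin_s = etho_bin_s,
              depth_table = depth_table, depth_sd = depth_sd,
              day_depth_scale = day_depth_scale,
              night_depth_scale = night_depth_scale,
              tau_rec_min = tau_rec_min,
              duration_mixture = duration_mixture,
              nocturnality = nocturnality,
              gap_night_min_s = gap_night_min_s,
              gap_night_max_s = gap_night_max_s,
              sustain_prob = sustain_prob,
              pir_miss_prob = pir_miss_prob,
              excitation = excitation, cohort = cohort,
              cohort_duration_h = cohort_duration_h,
              amp_dists = amp_dists, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants of a [sim_config()] object and stops with
#' a field-addressed message on the first violation.
#'
#' @param cfg a `sim_config` object (or a bare list with the same fields).
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(cfg$period_h) || cfg$period_h <= 0)
    stop_field("period_h", "must be a positive number of hours")
  if (!is.numeric(cfg$duration_h) || cfg$duration_h <= 0)
    stop_field("duration_h", "must be a positive number of hours")
  if (cfg$trough_rate < 0 || cfg$peak_rate < 0)
    stop_field("peak_rate/trough_rate", "rates must be non-negative")
  if (cfg$peak_rate < cfg$trough_rate)
    stop_field("peak_rate", "must be >= trough_rate")
  if (cfg$mua_bin_s <= 0) stop_field("mua_bin_s", "must be positive")
  if (is.null(names(cfg$depth_table)) || any(!nzchar(names(cfg$depth_table))))
    stop_field("depth_table", "must be a named vector of behavior depths")
  if (any(cfg$depth_table < 0 | cfg$depth_table > 1))
    stop_field("depth_table", "all depths must lie in [0, 1]")
  bad <- setdiff(names(cfg$depth_table), initiating_behaviors())
  if (length(bad))
    stop_field("depth_table", paste("unknown initiating behavior:",
                                    paste(bad, collapse = ", ")))
  if (cfg$depth_sd < 0) stop_field("depth_sd", "must be non-negative")
  if (length(cfg$duration_mixture) != 3L ||
      abs(sum(cfg$duration_mixture) - 1) > 1e-8 ||
      any(cfg$duration_mixture < 0))
    stop_field("duration_mixture",
               "must be 3 non-negative probabilities summing to 1")
  if (cfg$nocturnality < 0 || cfg$nocturnality > 1)
    stop_field("nocturnality", "must lie in [0, 1]")
  if (cfg$pir_miss_prob < 0 || cfg$pir_miss_prob > 1)
    stop_field("pir_miss_prob", "must lie in [0, 1]")
  if (cfg$tau_rec_min <= 0) stop_field("tau_rec_min", "must be positive")
  if (cfg$gap_night_min_s <= 0 || cfg$gap_night_max_s < cfg$gap_night_min_s)
    stop_field("gap_night_min_s/gap_night_max_s", "need 0 < min <= max")
  co <- cfg$cohort
  if (co$n_responsive > co$n_animals)
    stop_field("cohort", "n_responsive must be <= n_animals")
  if (co$n_light_responsive_nonbehavioral > co$n_animals - co$n_responsive)
    stop_field("cohort",
               "n_light_responsive_nonbehavioral must fit among non-responsive animals")
  invisible(cfg)
}

#' Behavior label sets
#'
#' The nine scored behavior categories, split by role: quiescent postures,
#' behaviors that can initiate a suppression, and behaviors that sustain an
#' ongoing suppression without deepening it.
#'
#' @return character vectors of labels.
#' @export
behavior_labels <- function() {
  c("digging", "drinking", "eating", "grooming", "lying", "moving",
    "rearing", "sitting", "walking")
}

#' @rdname behavior_labels
#' @export
quiescent_behaviors <- function() c("lying", "sitting")

#' @rdname behavior_labels
#' @export
initiating_behaviors <- function() c("grooming", "moving", "walking")

#' @rdname behavior_labels
#' @export
sustaining_behaviors <- function() c("eating", "rearing", "drinking")

#' Derive a child seed from a master seed
#'
#' Each stochastic component of the generator uses its own seed, derived from
#' the master seed by a fixed, documented offset so that runs are reproducible
#' and component streams are decoupled.
#'
#' @param seed master seed (integer).
#' @param stream integer stream offset (component id).
#' @return an integer seed below 2^31.
#' @export
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + stream) %% 2147483647)
}

#' Light schedule descriptor
#'
#' Describes the lighting regime used to map recording time (seconds from
#' recording start) to circadian phase. By convention, time 0 of the
#' recording is ZT0 (lights on) under LD, or CT0 under constant conditions.
#'
#' @param regime `"LD"`, `"DD"` or `"LL"` (the `"LD12:12"` spelling is
#'   accepted).
#' @param period_h circadian period in hours.
#' @param reference_s recording time (s) corresponding to phase 0.
#' @return an object of class `light_schedule`.
#' @export
light_schedule <- function(regime = "LD", period_h = 24, reference_s = 0) {
  regime <- if (grepl("^LD", regime)) "LD" else regime
  if (!regime %in% c("LD", "DD", "LL"))
    stop("regime must be one of LD, DD, LL", call. = FALSE)
  if (period_h <= 0) stop("period_h must be positive", call. = FALSE)
  structure(list(regime = regime, period_h = period_h,
                 reference_s = reference_s),
            class = "light_schedule")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  regime %s, period %g h, duration %g h\n",
              x$regime, x$period_h, x$duration_h))
  cat(sprintf("  rates: peak %g Hz, trough %g Hz (amplitude %g Hz)\n",
              x$peak_rate, x$trough_rate, x$peak_rate - x$trough_rate))
  cat(sprintf("  depths: %s (sd %g)\n",
              paste(sprintf("%s %.2f", names(x$depth_table), x$depth_table),
                    collapse = ", "), x$depth_sd))
  cat(sprintf("  tau_rec %g min, nocturnality %g, pir_miss %g, seed %d\n",
              x$tau_rec_min, x$nocturnality, x$pir_miss_prob, x$seed))
  invisible(x)
}
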