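#' Exclusion mask for rhythm fitting
#'
#' Marks bins to exclude from the circadian fit: behaviorally active bins
#' plus a post-bout margin covering the slow recovery, so that suppressions
#' and their tails do not drag the smoothed trace (and hence the amplitude
#' denominator) down.
#'
#' @param etho an [ethogram()].
#' @param t0 start of the binned span (s).
#' @param n_bins number of bins.
#' @param bin_s bin width (s).
#' @param margin_s post-bout margin (s); default 1500 (five 5-min recovery
#'   constants, leaving < 1% of the deficit unmasked).
#' @return logical vector, `TRUE` = exclude.
#' @export
event_exclusion_mask <- function(etho, t0, n_bins, bin_s, margin_s = 1500) {
  ext <- etho
  act <- !(ext$behavior %in% quiescent_behaviors())
  ext$end_s[act] <- ext$end_s[act] + margin_s
  cover <- activity_indicator(
    ethogram_unchecked(ext$start_s, ext$end_s, ext$behavior),
    t0, n_bins, bin_s)
  cover
}

# internal: ethogram-shaped frame without the overlap validation (extended
# margins may overlap the following quiescent interval on purpose)
ethogram_unchecked <- function(start_s, end_s, behavior) {
  df <- data.frame(start_s = start_s, end_s = end_s, behavior = behavior,
                   stringsAsFactors = FALSE)
  class(df) <- c("ethogram", "data.frame")
  df
}

#' Run the full suppression analysis on one recording
#'
#' Convenience pipeline: align streams, fit the circadian rhythm with event
#' windows excluded, detect suppression events, and attach duration classes
#' and phase labels. Optionally computes recovery statistics.
#'
#' @param mua a `binned_series` of spike counts (or an `scn_sim`, whose
#'   streams are used directly).
#' @param etho an [ethogram()] (ignored when `mua` is an `scn_sim`).
#' @param schedule a [light_schedule()].
#' @param z,m_min detection thresholds, see [detect_suppressions()].
#' @param recovery if `TRUE`, add return-to-baseline and tau estimates.
#' @return list with `fit` (a `rhythm_fit`), `events` (detected suppression
#'   table), and `n_bouts_tested`.
#' @export
analyze_recording <- function(mua, etho = NULL, schedule = NULL,
                              z = 3, m_min = 10, recovery = FALSE) {
  if (inherits(mua, "scn_sim")) {
    sim <- mua
    etho <- sim$etho
    if (is.null(schedule))
      schedule <- light_schedule(sim$config$regime, sim$config$period_h)
    mua <- sim$mua
  }
  if (is.null(schedule)) schedule <- light_schedule()
  mask <- event_exclusion_mask(etho, mua$t0, length(mua$values), mua$bin_s)
  fit <- smooth_mua(mua, schedule, exclude_mask = mask)
  if (!fit$rhythmic)
    return(list(fit = fit, events = NULL, n_bouts_tested = 0L))
  events <- detect_suppressions(mua, etho, fit, z = z, m_min = m_min)
  if (recovery) events <- recovery_stats(mua, events)
  list(fit = fit, events = events,
       n_bouts_tested = attr(events, "n_bouts_tested"))
}

# md5 digests of a set of files, named by basename
file_digests <- function(paths) {
  d <- tools::md5sum(paths)
  names(d) <- basename(paths)
  as.list(d)
}

#' Simulate a recording and write its files
#'
#' Writes `mua.tsv`, `pir.tsv`, `ethogram.tsv`, `truth.json`, `config.yaml`
#' (and `amplitudes.tsv` in waveform mode) plus a `manifest.json` recording
#' the config snapshot, seed, package version, and output digests.
#' Re-running with the same config and seed reproduces the files
#' bit-identically.
#'
#' @param config a `sim_config`, or the path of a YAML config file.
#' @param out_dir output directory (created if missing).
#' @param seed master seed (defaults to the config's).
#' @param waveform also write the spike-amplitude stream.
#' @return the manifest, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL, waveform = FALSE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_recording(config, waveform = waveform)
  paths <- file.path(out_dir, c("mua.tsv", "pir.tsv", "ethogram.tsv",
                                "truth.json", "config.yaml"))
  write_binned_series(sim$mua, paths[1])
  write_binned_series(sim$pir, paths[2])
  write_ethogram(sim$etho, paths[3])
  jsonlite::write_json(
    list(bouts = sim$truth$bouts, excitations = sim$truth$excitations,
         amplitude = sim$truth$amplitude,
         tau_rec_min = sim$truth$tau_rec_min,
         coupled = sim$coupled),
    paths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_config(config, paths[5])
  if (waveform) {
    p <- file.path(out_dir, "amplitudes.tsv")
    utils::write.table(sim$amplitudes, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(stage = "simulate", seed = config$seed,
                   package_version = as.character(utils::packageVersion("scncoupling")),
                   outputs = file_digests(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Analyze a simulated/recorded data directory
#'
#' Reads `mua.tsv`, `pir.tsv`, `ethogram.tsv` and `config.yaml` from
#' `in_dir`, runs the full pipeline (rhythm fit, suppression detection,
#' recovery, type/day-night/hourly statistics, conditioned profiles and
#' amplitude scenarios) and writes `events_suppression.tsv`, `rhythm.json`,
#' `stats.json`, `profiles.tsv` and a chained manifest to `out_dir`.
#'
#' @param in_dir directory holding the input streams.
#' @param out_dir output directory.
#' @return list of headline statistics, invisibly.
#' @export
run_analyze <- function(in_dir, out_dir) {
  need <- c("mua.tsv", "ethogram.tsv", "config.yaml")
  missing <- need[!file.exists(file.path(in_dir, need))]
  if (length(missing))
    stop("missing input file(s) in ", in_dir, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- read_config(file.path(in_dir, "config.yaml"))
  mua <- read_binned_series(file.path(in_dir, "mua.tsv"), "mua")
  etho <- read_ethogram(file.path(in_dir, "ethogram.tsv"))
  pir_path <- file.path(in_dir, "pir.tsv")
  pir <- if (file.exists(pir_path)) read_binned_series(pir_path, "pir") else NULL
  schedule <- light_schedule(cfg$regime, cfg$period_h)

  res <- analyze_recording(mua, etho, schedule, recovery = TRUE)
  events <- res$events
  if (is.null(events)) events <- detect_suppressions_empty()

  stats <- list(
    n_events = nrow(events),
    n_bouts_tested = res$n_bouts_tested,
    rhythmic = res$fit$rhythmic,
    mean_amplitude_hz = res$fit$mean_amplitude_hz,
    responsiveness = classify_animal_responsiveness(
      nrow(events), res$n_bouts_tested))
  if (nrow(events) >= 4 && length(unique(events$initiating)) >= 2) {
    mt <- magnitude_by_type(events)
    stats$by_type <- mt$by_type
    stats$anova_F <- mt$anova$F
    stats$anova_p <- mt$anova$p
  }
  if (nrow(events) && any(events$is_day) && any(!events$is_day)) {
    dn <- day_night_stats(events)
    stats$day <- as.list(dn$day); stats$night <- as.list(dn$night)
    stats$day_night_p <- dn$p
  }
  if (nrow(events)) {
    stats$duration_fractions <- as.list(
      table(factor(events$duration_class,
                   levels = c("<1 min", "1-25 min", ">25 min"))) / nrow(events))
    stats$mean_return_min <- mean(events$return_min, na.rm = TRUE)
  }
  if (!is.null(pir) && res$fit$rhythmic) {
    prof <- suppressWarnings(conditioned_profiles(mua, pir, schedule))
    sc <- tryCatch(amplitude_scenarios(prof), error = function(e) NULL)
    if (!is.null(sc)) stats$amplitude_scenarios <- sc
    utils::write.table(
      data.frame(time_s = prof$time_s, phase_h = prof$phase_h,
                 rate_hz = prof$rate_hz, active = as.integer(prof$active)),
      file.path(out_dir, "profiles.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  write_event_table(events, file.path(out_dir, "events_suppression.tsv"),
                    meta = list(z = 3, m_min = 10, seed = cfg$seed))
  jsonlite::write_json(
    list(rhythmic = res$fit$rhythmic, bandwidth_h = res$fit$bandwidth_h,
         mean_amplitude_hz = res$fit$mean_amplitude_hz,
         cycles = res$fit$cycles),
    file.path(out_dir, "rhythm.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  in_manifest <- file.path(in_dir, "manifest.json")
  manifest <- list(stage = "analyze",
                   package_version = as.character(utils::packageVersion("scncoupling")),
                   input_manifest_digest = if (file.exists(in_manifest))
                     unname(tools::md5sum(in_manifest)) else NULL,
                   inputs = file_digests(file.path(in_dir, need)),
                   outputs = file_digests(
                     file.path(out_dir, c("events_suppression.tsv",
                                          "rhythm.json", "stats.json"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stats)
}

# empty suppression table with the canonical columns
detect_suppressions_empty <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             duration_s = numeric(0), initiating = character(0),
             baseline_hz = numeric(0), suppressed_hz = numeric(0),
             amplitude_hz = numeric(0), magnitude_pct = numeric(0),
             z = numeric(0), duration_class = character(0),
             phase_h = numeric(0), is_day = logical(0),
             return_min = numeric(0), censored = logical(0),
             tau_min = numeric(0))
}
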