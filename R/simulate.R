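#' Deterministic circadian firing-rate trace
#'
#' Evaluates the noise-free circadian MUA rate (Hz) at each spike-count bin.
#' The waveform is a smoothed trapezoid: a day plateau at `peak_rate`, a
#' night plateau at `trough_rate`, and sigmoidal transitions of ~2 h centered
#' at phase 0 (lights on / CT0) and mid-period (lights off / CT12). Plateaus
#' make per-cycle peak and trough levels well defined, matching the
#' plateau-like day levels seen in vivo. High rates fall in the subjective
#' day (rest phase of a nocturnal animal) and low rates in the subjective
#' night, in antiphase with behavior.
#'
#' @param config a [sim_config()].
#' @param duration_h recording length (hours); defaults to
#'   `config$duration_h`.
#' @return numeric vector of rates (Hz), one per MUA bin (evaluated at bin
#'   centers). Deterministic given the config.
#' @export
simulate_circadian_rate <- function(config, duration_h = config$duration_h) {
  validate_config(config)
  if (duration_h <= 0) stop("duration_h must be positive", call. = FALSE)
  n <- floor(duration_h * 3600 / config$mua_bin_s)
  tc <- (seq_len(n) - 0.5) * config$mua_bin_s
  config$trough_rate +
    (config$peak_rate - config$trough_rate) * circadian_shape(tc, config$period_h)
}

# Smoothed-trapezoid shape in [0, 1]: 1 on the day plateau, 0 at night.
# Transition width ~2 h (logistic scale 0.45 h). Periodic via image terms.
circadian_shape <- function(t_s, period_h) {
  h <- (t_s / 3600) %% period_h
  s <- 0.45
  half <- period_h / 2
  L <- function(x) stats::plogis(x / s)
  f <- numeric(length(h))
  for (k in c(-1, 0, 1)) {
    f <- f + L(h - k * period_h) - L(h - half - k * period_h)
  }
  pmin(pmax(f, 0), 1)
}

#' Is a recording time in subjective day?
#'
#' Day is phase \[0, period/2) (ZT/CT 0-12), night is \[period/2, period).
#'
#' @param t_s time in seconds from recording start (phase 0 at t = 0).
#' @param period_h circadian period in hours.
#' @return logical vector.
#' @export
is_subjective_day <- function(t_s, period_h = 24) {
  ((t_s / 3600) %% period_h) < period_h / 2
}

#' Simulate a behavior schedule (ethogram plus bout list)
#'
#' Generates non-overlapping behavior bouts separated by quiescent lying or
#' sitting, with at least 2 min of quiescence before every bout. Each bout is
#' opened by an initiating behavior (grooming, moving or walking, equal
#' probability) and, with probability `sustain_prob`, continued by sustaining
#' behaviors (eating, rearing, drinking) that hold the suppression at the
#' initiating depth. Bout durations come from the three-class mixture
#' (`<1 min` uniform on 10-60 s, `1-25 min` log-uniform, `>25 min` uniform on
#' 25-45 min). Night inter-bout gaps are uniform on the configured range; the
#' mean day gap is derived from `nocturnality` so that the configured
#' fraction of bout time falls in subjective night.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param duration_h schedule length in hours (default `config$duration_h`).
#' @return list with `etho` (an [ethogram()]) and `bouts` (data.frame:
#'   `onset_s`, `offset_s`, `duration_s`, `initiating`, `class`).
#' @export
simulate_behavior_schedule <- function(config, seed = config$seed,
                                       duration_h = config$duration_h) {
  validate_config(config)
  set.seed(seed)
  T_end <- duration_h * 3600
  P <- config$period_h * 3600
  half <- P / 2
  mix <- config$duration_mixture
  # expected bout duration under the mixture (s)
  dbar <- mix[1] * 35 + mix[2] * (1500 - 60) / log(1500 / 60) + mix[3] * 2100
  gbar_n <- (config$gap_night_min_s + config$gap_night_max_s) / 2
  nu <- config$nocturnality
  day_only_night <- nu >= 0.999
  if (!day_only_night) {
    cycle_d <- (dbar + gbar_n) * nu / max(1 - nu, 1e-9)
    gbar_d <- max(cycle_d - dbar, config$gap_night_min_s)
  }

  draw_duration <- function() {
    cls <- sample.int(3L, 1L, prob = mix)
    d <- switch(cls,
                stats::runif(1, 10, 60),
                exp(stats::runif(1, log(60), log(1500))),
                stats::runif(1, 1500, 2700))
    c(cls, max(10, round(d)))
  }

  onset <- offset <- numeric(0)
  cls_v <- integer(0)
  cap <- 0L; nb <- 0L
  grow <- function(len) {
    onset <<- c(onset, numeric(len)); offset <<- c(offset, numeric(len))
    cls_v <<- c(cls_v, integer(len)); cap <<- cap + len
  }
  grow(1024L)
  t <- 120 + round(stats::runif(1, 0, 480))
  repeat {
    in_day <- is_subjective_day(t, config$period_h)
    if (in_day && day_only_night) {
      # jump to the next night onset, keeping some quiescence jitter
      t <- (floor(t / P)) * P + half + round(stats::runif(1, 0, 300))
      if (t >= T_end) break
      next
    }
    gap <- if (in_day)
      stats::runif(1, 0.5 * gbar_d, 1.5 * gbar_d)
    else
      stats::runif(1, config$gap_night_min_s, config$gap_night_max_s)
    s <- round(t + gap)
    if (s >= T_end) break
    dd <- draw_duration()
    e <- s + dd[2]
    if (day_only_night) {
      if (is_subjective_day(s, config$period_h)) { t <- s; next }
      # trim a bout that would spill into the day
      night_end <- floor(s / P) * P + P
      if (e > night_end) e <- night_end
      if (e - s < 10) { t <- e; next }
    }
    if (e > T_end) break
    nb <- nb + 1L
    if (nb > cap) grow(cap)
    onset[nb] <- s; offset[nb] <- e; cls_v[nb] <- dd[1]
    t <- e
  }
  onset <- onset[seq_len(nb)]; offset <- offset[seq_len(nb)]
  cls_v <- cls_v[seq_len(nb)]
  init_v <- sample(initiating_behaviors(), nb, replace = TRUE)

  bouts <- data.frame(onset_s = onset, offset_s = offset,
                      duration_s = offset - onset,
                      initiating = init_v,
                      class = c("<1 min", "1-25 min", ">25 min")[cls_v],
                      stringsAsFactors = FALSE)

  # build interval table: quiescent filler + bout segments
  segs <- vector("list", nb + 1L)
  prev <- 0
  for (i in seq_len(nb)) {
    s <- onset[i]; e <- offset[i]
    ss <- se <- numeric(0); sb <- character(0)
    if (s > prev) {
      ss <- prev; se <- s
      sb <- sample(quiescent_behaviors(), 1L, prob = c(0.8, 0.2))
    }
    d <- e - s
    if (stats::runif(1) < config$sustain_prob && d >= 30) {
      init_len <- max(10, round(d * stats::runif(1, 0.3, 0.7)))
      pos <- s + init_len
      lens <- numeric(0)
      while (pos < e) {
        len <- min(round(stats::runif(1, 10, 120)), e - pos)
        lens <- c(lens, len)
        pos <- pos + len
      }
      starts <- s + init_len + cumsum(c(0, lens[-length(lens)]))
      ss <- c(ss, s, starts)
      se <- c(se, s + init_len, starts + lens)
      sb <- c(sb, init_v[i],
              sample(sustaining_behaviors(), length(lens), replace = TRUE))
    } else {
      ss <- c(ss, s); se <- c(se, e); sb <- c(sb, init_v[i])
    }
    segs[[i]] <- list(ss, se, sb)
    prev <- e
  }
  if (prev < T_end) {
    segs[[nb + 1L]] <- list(prev, T_end, "lying")
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  seg_s <- unlist(lapply(segs, `[[`, 1L))
  seg_e <- unlist(lapply(segs, `[[`, 2L))
  seg_b <- unlist(lapply(segs, `[[`, 3L))
  list(etho = ethogram(seg_s, seg_e, seg_b), bouts = bouts)
}

#' Couple behavior bouts (and disturbances) into the rate trace
#'
#' Applies the behavioral modulation model to a clean circadian rate trace:
#' from bout onset the rate is reduced, within one bin, by `depth x A` where
#' `A = peak_rate - trough_rate` is the circadian amplitude and `depth` is a
#' per-event Gaussian draw around the initiating behavior's table value,
#' scaled by the day or night depth factor of the onset phase and truncated
#' to \[0, 1\]. If the initiating behavior changes within a bout to a more
#' intense type, the depth steps down to the deeper value; sustaining
#' behaviors hold the current depth. After bout offset the deficit decays as
#' `exp(-t / tau_rec)`. Disturbance-evoked excitations add a square transient
#' increment; with the `undershoot` flag the transient is followed by a
#' decaying suppression. The modulated rate is floored at 0.
#'
#' @param rate numeric rate trace (Hz per MUA bin) from
#'   [simulate_circadian_rate()].
#' @param schedule output of [simulate_behavior_schedule()] (uses both the
#'   bout list and the ethogram segment structure for within-bout depth
#'   steps).
#' @param disturbance_times numeric vector of disturbance times (s), possibly
#'   empty.
#' @param config a [sim_config()].
#' @param seed integer seed for the depth and excitation draws.
#' @return list with `rate` (modulated trace), `deficit` (injected deficit per
#'   bin, Hz), and `truth`: ground-truth tables (`bouts` with injected depth
#'   and day flag, `excitations` with injected increment and duration,
#'   `amplitude`, `tau_rec_min`).
#' @export
apply_coupling <- function(rate, schedule, disturbance_times = numeric(0),
                           config, seed = config$seed) {
  validate_config(config)
  set.seed(seed)
  bin_s <- config$mua_bin_s
  n <- length(rate)
  tc <- (seq_len(n) - 0.5) * bin_s   # bin centers
  A <- config$peak_rate - config$trough_rate
  tau_s <- config$tau_rec_min * 60
  bouts <- schedule$bouts
  deficit <- numeric(n)

  # bins whose center falls in [s, e)
  idx_range <- function(s, e) {
    i0 <- max(1L, as.integer(ceiling(s / bin_s + 0.5 - 1e-9)))
    i1 <- min(n, as.integer(ceiling(e / bin_s + 0.5 - 1e-9)) - 1L)
    if (i0 > i1) integer(0) else i0:i1
  }

  if (nrow(bouts)) {
    if (any(bouts$offset_s > n * bin_s + bin_s))
      stop("bout extends beyond the rate trace span", call. = FALSE)
    day <- is_subjective_day(bouts$onset_s, config$period_h)
    scale <- ifelse(day, config$day_depth_scale, config$night_depth_scale)
    base_depth <- unname(config$depth_table[bouts$initiating]) * scale
    depth <- stats::rnorm(nrow(bouts), base_depth, config$depth_sd)
    depth <- pmin(pmax(depth, 0), 1)
    bouts$depth <- depth
    bouts$is_day <- day
    bouts$depth_final <- depth

    # per-bout segment depths: escalation on deeper initiating types
    etho <- schedule$etho
    init_set <- names(config$depth_table)
    seg_starts <- etho$start_s
    for (i in seq_len(nrow(bouts))) {
      s <- bouts$onset_s[i]; e <- bouts$offset_s[i]
      j0 <- max(1L, findInterval(s, seg_starts))
      j1 <- findInterval(e - 1e-9, seg_starts)
      segs <- etho[j0:j1, , drop = FALSE]
      segs <- segs[segs$end_s > s & segs$start_s < e &
                     !(segs$behavior %in% quiescent_behaviors()), ,
                   drop = FALSE]
      cur <- depth[i]
      D0 <- cur * A
      if (nrow(segs) > 1L) {
        for (j in seq_len(nrow(segs))) {
          b <- segs$behavior[j]
          if (b %in% init_set) {
            cand <- unname(config$depth_table[b]) * scale[i] *
              (depth[i] / max(base_depth[i], 1e-12))
            cur <- max(cur, cand)
          }
          idx <- idx_range(max(segs$start_s[j], s), min(segs$end_s[j], e))
          if (length(idx)) deficit[idx] <- pmax(deficit[idx], cur * A)
        }
        D0 <- cur * A
      } else {
        idx <- idx_range(s, e)
        if (length(idx)) deficit[idx] <- pmax(deficit[idx], D0)
      }
      # exponential recovery tail after offset (negligible beyond 8 tau)
      idx <- idx_range(e, e + 8 * tau_s)
      if (length(idx)) {
        tail_def <- D0 * exp(-(tc[idx] - e) / tau_s)
        deficit[idx] <- pmax(deficit[idx], tail_def)
      }
      bouts$depth_final[i] <- cur
    }
  } else {
    bouts$depth <- numeric(0)
    bouts$is_day <- logical(0)
    bouts$depth_final <- numeric(0)
  }

  increment <- numeric(n)
  exc <- data.frame(time_s = numeric(0), increment_hz = numeric(0),
                    duration_s = numeric(0))
  if (length(disturbance_times)) {
    ex <- config$excitation
    dur <- exp(stats::runif(length(disturbance_times),
                            log(ex$dur_min_s), log(ex$dur_max_s)))
    inc <- ex$increment_frac * A
    for (k in seq_along(disturbance_times)) {
      t0 <- disturbance_times[k]
      idx <- idx_range(t0, t0 + dur[k])
      increment[idx] <- increment[idx] + inc
      if (isTRUE(ex$undershoot)) {
        e <- t0 + dur[k]
        idx2 <- idx_range(e, e + 8 * tau_s)
        deficit[idx2] <- pmax(deficit[idx2],
                              0.3 * A * exp(-(tc[idx2] - e) / tau_s))
      }
    }
    exc <- data.frame(time_s = disturbance_times, increment_hz = inc,
                      duration_s = dur)
  }

  list(rate = pmax(rate - deficit + increment, 0),
       deficit = deficit,
       truth = list(bouts = bouts, excitations = exc, amplitude = A,
                    tau_rec_min = config$tau_rec_min))
}

#' Sample Poisson spike counts from a rate trace
#'
#' Counts per bin are independent Poisson draws with mean `rate * bin_s`.
#'
#' @param rate numeric rate trace (Hz), all values >= 0.
#' @param bin_s bin width in seconds.
#' @param seed integer seed.
#' @param t0 start time of the first bin (s).
#' @return a [binned_series()] of counts.
#' @export
sample_spikes <- function(rate, bin_s, seed, t0 = 0) {
  if (any(rate < 0)) stop("rate must be non-negative everywhere", call. = FALSE)
  set.seed(seed)
  binned_series(stats::rpois(length(rate), rate * bin_s), bin_s, t0 = t0,
                channel = "mua")
}

#' Simulate the PIR observation channel
#'
#' Each truly active MUA bin (non-quiescent behavior covering >= 1 s of it)
#' emits a PIR signal with probability `1 - pir_miss_prob`; inactive bins
#' never emit (no false positives). This reproduces a motion detector that
#' misses part of the behavioral activity.
#'
#' @param etho an [ethogram()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param n_bins number of MUA bins; defaults to the ethogram span.
#' @return a binary [binned_series()] with `channel = "pir"`.
#' @export
simulate_pir <- function(etho, config, seed = config$seed,
                         n_bins = NULL) {
  bin_s <- config$mua_bin_s
  if (is.null(n_bins)) n_bins <- floor(max(etho$end_s) / bin_s)
  active <- activity_indicator(etho, 0, n_bins, bin_s)
  set.seed(seed)
  hit <- stats::rbinom(n_bins, 1L, 1 - config$pir_miss_prob)
  binned_series(as.numeric(active) * hit, bin_s, t0 = 0, channel = "pir")
}

#' Simulate a per-spike amplitude stream with two subpopulations
#'
#' Splits the clean rate equally between a behavior-responsive and a
#' non-responsive subpopulation (equal baseline rates), applies the whole
#' injected deficit to the responsive one (floored at 0), samples Poisson
#' counts per bin for each, places spikes uniformly within bins, and draws
#' spike amplitudes from the per-subpopulation normal distributions.
#'
#' @param rate clean (unmodulated) rate trace, Hz per MUA bin.
#' @param deficit injected deficit per bin (Hz), as returned by
#'   [apply_coupling()].
#' @param config a [sim_config()]; uses `amp_dists` and `mua_bin_s`.
#' @param seed integer seed.
#' @return data.frame with `time_s`, `amplitude`, `subpop`
#'   (`"nonresponsive"` or `"responsive"`), sorted by time.
#' @export
simulate_spike_amplitudes <- function(rate, deficit = 0, config,
                                      seed = config$seed) {
  ad <- config$amp_dists
  if (abs(ad$nonresponsive[["mean"]] - ad$responsive[["mean"]]) <
      1e-9 * max(1, ad$responsive[["sd"]]))
    warning("subpopulation amplitude distributions fully overlap; ",
            "amplitude windows will not be separable")
  set.seed(seed)
  bin_s <- config$mua_bin_s
  n <- length(rate)
  r_non <- rate / 2
  r_resp <- pmax(rate / 2 - deficit, 0)
  draw <- function(r, pars, label) {
    counts <- stats::rpois(n, r * bin_s)
    tot <- sum(counts)
    if (tot == 0)
      return(data.frame(time_s = numeric(0), amplitude = numeric(0),
                        subpop = character(0)))
    bin_idx <- rep.int(seq_len(n), counts)
    data.frame(time_s = (bin_idx - 1) * bin_s + stats::runif(tot, 0, bin_s),
               amplitude = stats::rnorm(tot, pars[["mean"]], pars[["sd"]]),
               subpop = label, stringsAsFactors = FALSE)
  }
  out <- rbind(draw(r_non, ad$nonresponsive, "nonresponsive"),
               draw(r_resp, ad$responsive, "responsive"))
  out <- out[order(out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic SCN recording
#'
#' Runs the full generative chain: circadian rate, behavior schedule,
#' behavioral coupling (and optional disturbances), Poisson spike sampling,
#' and PIR observation. Component seeds are derived from the master seed by
#' fixed offsets (schedule +1, coupling +2, spikes +3, PIR +4, amplitudes
#' +5), so the streams are decoupled and the whole object is reproducible.
#'
#' @param config a [sim_config()].
#' @param seed master seed (default `config$seed`).
#' @param coupled if `FALSE`, the behavior schedule is generated but no
#'   suppression is injected (null recording for false-positive calibration).
#' @param disturbance_times optional disturbance times (s) for excitation
#'   transients.
#' @param waveform if `TRUE`, also simulate the per-spike amplitude stream.
#' @return an object of class `scn_sim`: list with `config`, `mua`
#'   (counts [binned_series()]), `pir`, `etho`, `bouts`, `truth`,
#'   `rate_clean`, `deficit`, and optionally `amplitudes`.
#' @export
simulate_recording <- function(config, seed = config$seed, coupled = TRUE,
                               disturbance_times = numeric(0),
                               waveform = FALSE) {
  validate_config(config)
  rate <- simulate_circadian_rate(config)
  sched <- simulate_behavior_schedule(config, seed = child_seed(seed, 1L))
  if (coupled) {
    coup <- apply_coupling(rate, sched, disturbance_times, config,
                           seed = child_seed(seed, 2L))
  } else {
    cfg0 <- config
    cfg0$depth_table[] <- 0
    cfg0$depth_sd <- 0
    coup <- apply_coupling(rate, sched, disturbance_times, cfg0,
                           seed = child_seed(seed, 2L))
  }
  mua <- sample_spikes(coup$rate, config$mua_bin_s,
                       seed = child_seed(seed, 3L))
  pir <- simulate_pir(sched$etho, config, seed = child_seed(seed, 4L),
                      n_bins = length(mua$values))
  out <- list(config = config, seed = seed, coupled = coupled,
              mua = mua, pir = pir, etho = sched$etho,
              bouts = coup$truth$bouts, truth = coup$truth,
              rate_clean = rate, rate_true = coup$rate,
              deficit = coup$deficit)
  if (waveform)
    out$amplitudes <- simulate_spike_amplitudes(rate, coup$deficit, config,
                                                seed = child_seed(seed, 5L))
  class(out) <- "scn_sim"
  out
}

#' @export
print.scn_sim <- function(x, ...) {
  cat(sprintf("<scn_sim> %.1f h, %d MUA bins, %d bouts, %s\n",
              length(x$mua$values) * x$mua$bin_s / 3600,
              length(x$mua$values), nrow(x$bouts),
              if (x$coupled) "coupled" else "uncoupled"))
  invisible(x)
}

#' Simulate a cohort of animals
#'
#' Generates one recording per animal: the first `n_responsive` animals get
#' behavior-coupled suppression, the rest are uncoupled. Among the
#' non-responsive animals, the first `n_light_responsive_nonbehavioral` are
#' flagged light-responsive (flag only; light responses are not simulated).
#'
#' @param config a [sim_config()]; per-animal duration is
#'   `config$cohort_duration_h`.
#' @param seed master seed; animal `i` uses `child_seed(seed, 100 + i)`.
#' @return list with `animals` (list of `scn_sim`) and `flags` (data.frame:
#'   `animal`, `responsive`, `light_responsive`).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  co <- config$cohort
  cfg <- config
  cfg$duration_h <- config$cohort_duration_h
  animals <- vector("list", co$n_animals)
  responsive <- seq_len(co$n_animals) <= co$n_responsive
  non_idx <- which(!responsive)
  light <- rep(FALSE, co$n_animals)
  if (co$n_light_responsive_nonbehavioral > 0)
    light[non_idx[seq_len(co$n_light_responsive_nonbehavioral)]] <- TRUE
  for (i in seq_len(co$n_animals)) {
    animals[[i]] <- simulate_recording(cfg, seed = child_seed(seed, 100L + i),
                                       coupled = responsive[i])
  }
  list(animals = animals,
       flags = data.frame(animal = seq_len(co$n_animals),
                          responsive = responsive,
                          light_responsive = light))
}
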