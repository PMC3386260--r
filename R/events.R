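#' Baseline firing rate before an event
#'
#' Mean discharge rate over the last 2 minutes immediately preceding an
#' event onset.
#'
#' @param series a `binned_series` of spike counts.
#' @param t_event event onset (s).
#' @param width_s baseline window width (s), default 120.
#' @return baseline rate in Hz.
#' @export
baseline_rate <- function(series, t_event, width_s = 120) {
  lo <- t_event - width_s
  if (lo < series$t0 - 1e-9)
    stop("insufficient data before the event for a baseline window",
         call. = FALSE)
  r <- window_rate(series, lo, t_event)
  if (is.na(r)) stop("empty baseline window", call. = FALSE)
  r
}

# mean level of the fit's phase-folded clean profile over [t0, t1),
# evaluated by circular linear interpolation on a 10-s grid
profile_level <- function(fit, t0, t1) {
  pr <- fit$profile
  if (is.null(pr) || all(is.na(pr$levels_hz))) return(NA_real_)
  nb <- pr$n_bins
  tt <- seq(t0 + 5, t1, by = 10)
  if (!length(tt)) tt <- (t0 + t1) / 2
  x <- ((tt %% pr$period_s) / pr$period_s) * nb + 0.5  # bin-center coords
  i0 <- floor(x)
  frac <- x - i0
  iA <- ((i0 - 1L) %% nb) + 1L
  iB <- (i0 %% nb) + 1L
  mean(pr$levels_hz[iA] * (1 - frac) + pr$levels_hz[iB] * frac)
}

# mean rate (Hz) over bins whose center falls in [t0, t1); NA when empty.
# The bin-center convention matches the resolution at which a step change
# can be localized: a bin straddling t0 belongs to the window only if more
# than half of it does.
window_rate <- function(series, t0, t1) {
  b <- series$bin_s
  i0 <- max(1L, as.integer(ceiling((t0 - series$t0) / b + 0.5 - 1e-9)))
  i1 <- min(length(series$values),
            as.integer(ceiling((t1 - series$t0) / b + 0.5 - 1e-9)) - 1L)
  if (i1 < i0) return(NA_real_)
  mean(series$values[i0:i1]) / b
}

#' Suppression magnitude as a percentage of circadian amplitude
#'
#' `M = 100 * (B - S) / A`, where `B` is the pre-event baseline rate, `S` the
#' mean rate during the suppression, and `A` the circadian amplitude. `M` is
#' invariant to rescaling the whole recording by a positive constant.
#'
#' @param B baseline rate (Hz).
#' @param S suppressed mean rate (Hz).
#' @param A circadian amplitude (Hz), must be positive.
#' @return magnitude in percent.
#' @export
suppression_magnitude <- function(B, S, A) {
  if (any(A <= 0)) stop("amplitude must be positive", call. = FALSE)
  100 * (B - S) / A
}

#' Classify an event duration into the three duration classes
#'
#' Classes: `<1 min` is \[0, 60) s, `1-25 min` is \[60 s, 25 min\] (closed at
#' 25 min), `>25 min` is above.
#'
#' @param duration_s event duration(s) in seconds.
#' @return character vector of class labels.
#' @export
classify_duration <- function(duration_s) {
  ifelse(duration_s < 60, "<1 min",
         ifelse(duration_s <= 1500, "1-25 min", ">25 min"))
}

#' Extract behavior bouts from an ethogram
#'
#' Collapses consecutive non-quiescent intervals into bouts, records each
#' bout's initiating behavior (first segment label) and the quiescent gap
#' preceding it.
#'
#' @param etho an [ethogram()].
#' @return data.frame with `onset_s`, `offset_s`, `duration_s`, `initiating`,
#'   `pre_gap_s` (quiescence preceding the bout; `Inf` for the first).
#' @export
find_bouts <- function(etho) {
  act <- !(etho$behavior %in% quiescent_behaviors())
  if (!any(act))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), initiating = character(0),
                      pre_gap_s = numeric(0)))
  runs <- rle(act)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ai <- which(runs$values)
  onset <- etho$start_s[starts[ai]]
  offset <- etho$end_s[ends[ai]]
  init <- etho$behavior[starts[ai]]
  pre <- c(Inf, onset[-1L] - offset[-length(offset)])
  if (length(onset)) pre[1L] <- onset[1L] - min(etho$start_s)
  data.frame(onset_s = onset, offset_s = offset,
             duration_s = offset - onset, initiating = init,
             pre_gap_s = pre, stringsAsFactors = FALSE)
}

#' Detect behavior-associated suppression events
#'
#' For every behavior bout preceded by at least 2 min of quiescence, the
#' detector compares the mean rate during the bout (`S`) with the baseline
#' rate over the 2 min before onset (`B`) and declares a suppression event
#' when the drop exceeds `z` Poisson standard errors *and* the magnitude
#' `M = 100 (B - S) / A` reaches `m_min` percent of the circadian amplitude
#' `A` (taken from the cycle containing the onset). Bouts separated by less
#' than 2 min of quiescence are merged into a single event; a bout starting
#' within `baseline_reuse_min` minutes of the previous detected offset
#' reuses the previous baseline instead of a recovery-contaminated window.
#'
#' Detection is drift-corrected: the expected clean-rhythm change between
#' the baseline window and the bout window is read off the (event-masked)
#' smoothed trace and added to the observed drop before testing, so bouts
#' riding the dusk/dawn transitions do not masquerade as suppressions. The
#' reported magnitude itself stays in its standard form `100 (B - S) / A`.
#'
#' The statistical criterion (z, m_min) is an explicit analysis choice whose
#' false-positive rate is calibrated on uncoupled simulations; see
#' [classify_animal_responsiveness()].
#'
#' @param series a `binned_series` of spike counts.
#' @param etho an [ethogram()] aligned with `series`.
#' @param fit a rhythmic `rhythm_fit` (for the amplitude denominator).
#' @param z detection threshold in Poisson SEs (default 3).
#' @param m_min minimum magnitude in percent of amplitude (default 10).
#' @param quiescence_min_s required pre-bout quiescence (s).
#' @param baseline_reuse_min reuse window for contaminated baselines
#'   (minutes; default `3 * 5` assuming the ~5-min recovery constant).
#' @return data.frame of detected events (`onset_s`, `offset_s`,
#'   `duration_s`, `initiating`, `baseline_hz`, `suppressed_hz`,
#'   `amplitude_hz`, `magnitude_pct`, `z`, `duration_class`, `phase_h`,
#'   `is_day`), with attribute `n_bouts_tested` (number of
#'   quiescence-preceded bouts evaluated).
#' @export
detect_suppressions <- function(series, etho, fit, z = 3, m_min = 10,
                                quiescence_min_s = 120,
                                baseline_reuse_min = 15) {
  if (!isTRUE(fit$rhythmic))
    stop("amplitude undefined: rhythm fit is arrhythmic", call. = FALSE)
  bouts <- find_bouts(etho)
  # merge bouts separated by < 2 min quiescence into one episode
  if (nrow(bouts) > 1L) {
    grp <- cumsum(c(TRUE, bouts$pre_gap_s[-1L] >= quiescence_min_s))
    merged <- do.call(rbind, lapply(split(seq_len(nrow(bouts)), grp), function(ii) {
      data.frame(onset_s = bouts$onset_s[ii[1L]],
                 offset_s = max(bouts$offset_s[ii]),
                 initiating = bouts$initiating[ii[1L]],
                 pre_gap_s = bouts$pre_gap_s[ii[1L]],
                 stringsAsFactors = FALSE)
    }))
    merged$duration_s <- merged$offset_s - merged$onset_s
    bouts <- merged
  }
  sched <- fit$schedule
  rows <- vector("list", nrow(bouts))
  n_tested <- 0L
  prev_B <- NA_real_
  prev_offset <- -Inf
  for (i in seq_len(nrow(bouts))) {
    s <- bouts$onset_s[i]; e <- bouts$offset_s[i]
    if (bouts$pre_gap_s[i] < quiescence_min_s) next
    if (s - series$t0 < quiescence_min_s) next
    n_tested <- n_tested + 1L
    B <- if (s - prev_offset < baseline_reuse_min * 60 && !is.na(prev_B))
      prev_B
    else
      baseline_rate(series, s, width_s = quiescence_min_s)
    S <- window_rate(series, s, e)
    if (is.na(S)) next
    A <- amplitude_at(fit, s)
    T_bout <- e - s
    # predicted clean-rhythm change between the two windows (drift term),
    # read off the phase-folded clean profile
    delta <- profile_level(fit, s, e) -
      profile_level(fit, s - quiescence_min_s, s)
    if (is.na(delta)) delta <- 0
    se_drop <- sqrt(B / quiescence_min_s + B / T_bout)
    drop_c <- B + delta - S
    zi <- drop_c / max(se_drop, 1e-12)
    M_c <- 100 * drop_c / A
    M <- suppression_magnitude(B, S, A)
    prev_B <- B
    prev_offset <- e
    if (zi >= z && M_c >= m_min) {
      ph <- to_circadian_time(s, sched)
      rows[[i]] <- data.frame(
        onset_s = s, offset_s = e, duration_s = T_bout,
        initiating = bouts$initiating[i],
        baseline_hz = B, suppressed_hz = S, amplitude_hz = A,
        magnitude_pct = M, z = zi,
        duration_class = classify_duration(T_bout),
        phase_h = ph, is_day = ph < 12,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), initiating = character(0),
                      baseline_hz = numeric(0), suppressed_hz = numeric(0),
                      amplitude_hz = numeric(0), magnitude_pct = numeric(0),
                      z = numeric(0), duration_class = character(0),
                      phase_h = numeric(0), is_day = logical(0))
  rownames(out) <- NULL
  attr(out, "n_bouts_tested") <- n_tested
  out
}

#' Return-to-baseline time and exponential recovery constant
#'
#' After the event offset, the 10-s-rebinned rate is scanned for the first
#' time at which it stays inside the baseline noise band for 6 consecutive
#' 10-s bins; that time (minutes after offset) is the return-to-baseline
#' time. The band is `B +/- band_hz`, by default two Poisson standard errors
#' of a 10-s bin at the baseline rate. The post-offset deficit
#' `B - rate(t)` is also fitted by least squares to `D exp(-t / tau)` and
#' the time constant reported.
#'
#' @param series a `binned_series` of spike counts.
#' @param offset_s event offset (s).
#' @param B baseline rate (Hz).
#' @param max_window_s how far past the offset to scan (s); trimmed to the
#'   next event by the caller.
#' @param band_hz half-width of the baseline band (Hz); default
#'   `2 * sqrt(B / 10)`.
#' @param rebin_s working resolution (s).
#' @param consecutive number of consecutive in-band bins required.
#' @return list with `return_min` (minutes; `NA` if never re-attained),
#'   `censored` (logical), `tau_min` (fitted exponential constant, minutes),
#'   `D_hz` (fitted initial deficit).
#' @export
recovery_time <- function(series, offset_s, B, max_window_s = 1800,
                          band_hz = NULL, rebin_s = 10, consecutive = 6) {
  if (is.null(band_hz)) band_hz <- 2 * sqrt(B / rebin_s)
  i0 <- floor((offset_s - series$t0) / series$bin_s + 1e-9) + 1L
  i1 <- min(length(series$values),
            floor((offset_s + max_window_s - series$t0) / series$bin_s))
  if (i1 <= i0) return(list(return_min = NA_real_, censored = TRUE,
                            tau_min = NA_real_, D_hz = NA_real_))
  sub <- binned_series(series$values[i0:i1], series$bin_s,
                       t0 = series$t0 + (i0 - 1L) * series$bin_s,
                       channel = "mua")
  rb <- rebin_series(sub, rebin_s)
  r <- rb$values / rebin_s
  t_rel <- bin_times(rb) + rebin_s / 2 - offset_s
  inband <- abs(r - B) <= band_hz
  run <- 0L
  ret <- NA_real_
  for (j in seq_along(inband)) {
    run <- if (inband[j]) run + 1L else 0L
    if (run == consecutive) {
      ret <- t_rel[j - consecutive + 1L] - rebin_s / 2
      break
    }
  }
  # exponential time constant: log-linear fit over the decay segment, i.e.
  # the leading bins whose deficit still exceeds 3 Poisson SEs (beyond that
  # the log-deficit is dominated by counting noise)
  def <- B - r
  tau_hat <- D_hat <- NA_real_
  noise <- 3 * sqrt(B / rebin_s)
  above <- def > noise
  n_lead <- if (all(above)) length(def) else which(!above)[1L] - 1L
  if (n_lead >= 4L) {
    tt <- t_rel[seq_len(n_lead)]
    ld <- log(def[seq_len(n_lead)])
    fit <- stats::lm.fit(cbind(1, tt), ld)
    slope <- fit$coefficients[[2L]]
    if (is.finite(slope) && slope < 0) {
      tau_hat <- -1 / slope / 60
      D_hat <- exp(fit$coefficients[[1L]])
    }
  }
  list(return_min = if (is.na(ret)) NA_real_ else max(ret, 0) / 60,
       censored = is.na(ret), tau_min = tau_hat, D_hz = D_hat)
}

#' Recovery statistics for a table of detected events
#'
#' Applies [recovery_time()] to each event, scanning up to the next event
#' onset (or `max_window_s`), and requiring at least `min_post_s` of
#' post-offset data.
#'
#' @param series a `binned_series` of spike counts.
#' @param events event table from [detect_suppressions()].
#' @param max_window_s maximum scan window (s).
#' @param min_post_s minimum clean post-offset span (s) for an event to be
#'   evaluated.
#' @return `events` with added columns `return_min`, `censored`, `tau_min`.
#' @export
recovery_stats <- function(series, events, max_window_s = 1800,
                           min_post_s = 1800) {
  n <- nrow(events)
  events$return_min <- rep(NA_real_, n)
  events$censored <- rep(NA, n)
  events$tau_min <- rep(NA_real_, n)
  if (!n) return(events)
  next_onset <- c(events$onset_s[-1L], Inf)
  for (i in seq_len(n)) {
    avail <- min(next_onset[i], series_end(series)) - events$offset_s[i]
    if (avail < min_post_s) next
    rec <- recovery_time(series, events$offset_s[i], events$baseline_hz[i],
                         max_window_s = min(avail, max_window_s))
    events$return_min[i] <- rec$return_min
    events$censored[i] <- rec$censored
    events$tau_min[i] <- rec$tau_min
  }
  events
}

#' Detect disturbance-evoked excitation transients
#'
#' For each disturbance time, an excitation event is declared when the
#' 10-s-rebinned rate exceeds `B + z * SE` within `latency_max_s` of the
#' disturbance; its duration is the time the rate stays above the band.
#' Events are post-classified as `"undershoot"` when the rate subsequently
#' drops below `B - z * SE` for two consecutive bins within the recovery
#' window, else `"return"`. Disturbances falling inside a detected
#' suppression event are flagged and excluded.
#'
#' @param series a `binned_series` of spike counts.
#' @param disturbance_times numeric vector of disturbance times (s).
#' @param fit a rhythmic `rhythm_fit` (for the amplitude scaling of the
#'   increment).
#' @param suppressions optional suppression event table used to exclude
#'   disturbances inside ongoing suppressions.
#' @param z threshold in Poisson SEs of a 10-s bin.
#' @param latency_max_s maximum onset latency (s).
#' @param recovery_window_s window for the undershoot check (s).
#' @return data.frame with `disturbance_s`, `detected`, `excluded`,
#'   `latency_s`, `peak_increment_hz`, `peak_increment_pct`, `duration_s`,
#'   `post_class`.
#' @export
detect_excitations <- function(series, disturbance_times, fit,
                               suppressions = NULL, z = 3,
                               latency_max_s = 30,
                               recovery_window_s = 900) {
  rebin_s <- 10
  rows <- lapply(disturbance_times, function(t0) {
    excluded <- FALSE
    if (!is.null(suppressions) && nrow(suppressions)) {
      excluded <- any(t0 >= suppressions$onset_s & t0 < suppressions$offset_s)
    }
    out <- data.frame(disturbance_s = t0, detected = FALSE,
                      excluded = excluded, latency_s = NA_real_,
                      peak_increment_hz = NA_real_,
                      peak_increment_pct = NA_real_,
                      duration_s = NA_real_, post_class = NA_character_,
                      stringsAsFactors = FALSE)
    if (excluded) return(out)
    B <- baseline_rate(series, t0)
    se <- sqrt(B / rebin_s)
    i0 <- floor((t0 - series$t0) / series$bin_s + 1e-9) + 1L
    i1 <- min(length(series$values),
              floor((t0 + recovery_window_s - series$t0) / series$bin_s))
    if (i1 <= i0) return(out)
    sub <- binned_series(series$values[i0:i1], series$bin_s,
                         t0 = series$t0 + (i0 - 1L) * series$bin_s)
    rb <- rebin_series(sub, rebin_s)
    r <- rb$values / rebin_s
    t_rel <- bin_times(rb) - t0
    above <- r > B + z * se
    cand <- which(above & t_rel < latency_max_s)
    if (!length(cand)) return(out)
    first <- cand[1L]
    last <- first
    while (last < length(above) && above[last + 1L]) last <- last + 1L
    out$detected <- TRUE
    out$latency_s <- max(t_rel[first], 0)
    out$duration_s <- (last - first + 1L) * rebin_s
    peak <- max(r[first:last]) - B
    out$peak_increment_hz <- peak
    A <- amplitude_at(fit, t0)
    out$peak_increment_pct <- 100 * peak / A
    below <- r < B - z * se
    post <- below[(last + 1L):length(below)]
    under <- FALSE
    if (length(post) >= 2L)
      under <- any(post[-length(post)] & post[-1L])
    out$post_class <- if (under) "undershoot" else "return"
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(disturbance_s = numeric(0), detected = logical(0),
                      excluded = logical(0), latency_s = numeric(0),
                      peak_increment_hz = numeric(0),
                      peak_increment_pct = numeric(0),
                      duration_s = numeric(0), post_class = character(0))
  out
}

#' Classify an animal as behavior-responsive or not
#'
#' Tests whether the fraction of quiescence-preceded bouts that yielded
#' detected suppressions exceeds the calibrated false-positive rate of the
#' detector, using a one-sided binomial test at the 99% level.
#'
#' @param n_detected number of detected suppression events.
#' @param n_bouts number of quiescence-preceded bouts evaluated.
#' @param fp_rate calibrated per-bout false-positive rate of the detector
#'   under zero coupling (default 0.005, an upper bound from the null
#'   calibration).
#' @param alpha significance level (default 0.01, i.e. the null 99th
#'   percentile).
#' @param min_bouts minimum number of evaluated bouts for a verdict.
#' @return `"responsive"`, `"non-responsive"`, or `"indeterminate"`.
#' @export
classify_animal_responsiveness <- function(n_detected, n_bouts,
                                           fp_rate = 0.005, alpha = 0.01,
                                           min_bouts = 20) {
  if (n_bouts < min_bouts) return("indeterminate")
  p <- stats::binom.test(n_detected, n_bouts, p = fp_rate,
                         alternative = "greater")$p.value
  if (p < alpha) "responsive" else "non-responsive"
}
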