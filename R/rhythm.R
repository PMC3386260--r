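#' Rebin a counts series to a coarser bin width
#'
#' Sums counts into consecutive groups so that the new width is an integer
#' multiple of the old one. A trailing partial group is dropped.
#'
#' @param x a `binned_series` of counts.
#' @param new_bin_s target bin width (s).
#' @return a `binned_series` of counts at the coarser resolution.
#' @export
rebin_series <- function(x, new_bin_s = 10) {
  k <- new_bin_s / x$bin_s
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("new_bin_s must be an integer multiple of the current bin width",
         call. = FALSE)
  k <- as.integer(round(k))
  n <- floor(length(x$values) / k)
  v <- x$values[seq_len(n * k)]
  out <- colSums(matrix(v, nrow = k))
  binned_series(out, new_bin_s, t0 = x$t0, channel = x$channel)
}

# Weighted centered moving average; w = 0 marks excluded bins. Gaps where a
# whole window is excluded are filled by linear interpolation.
moving_average <- function(v, w, half_win) {
  n <- length(v)
  cs_v <- cumsum(c(0, v * w))
  cs_w <- cumsum(c(0, w))
  lo <- pmax(seq_len(n) - half_win, 1L)
  hi <- pmin(seq_len(n) + half_win, n)
  num <- cs_v[hi + 1L] - cs_v[lo]
  den <- cs_w[hi + 1L] - cs_w[lo]
  out <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(out)) {
    idx <- which(!is.na(out))
    if (length(idx) < 2L) stop("too few usable bins to smooth", call. = FALSE)
    out <- stats::approx(idx, out[idx], xout = seq_len(n), rule = 2)$y
  }
  out
}

# Alternating local extrema of a numeric trace with flat-plateau midpoint
# tie-break, pruned so that every retained rise/fall exceeds `prominence`.
# Returns a data.frame with columns idx (position) and type (+1 max, -1 min).
find_extrema <- function(x, prominence) {
  n <- length(x)
  d <- diff(x)
  sgn <- sign(d)
  nz <- sgn != 0
  if (!any(nz)) return(data.frame(idx = integer(0), type = integer(0)))
  if (all(nz)) {
    # fast path (typical for noisy smoothed traces): no exact plateaus
    m <- length(sgn)
    chg <- which(sgn[-1L] != sgn[-m])
    idx <- chg + 1L
    type <- ifelse(sgn[chg] > 0, 1L, -1L)
  } else {
    # carry the last non-zero slope through plateaus; place the extremum at
    # the plateau midpoint
    run <- sgn
    last <- 0
    for (i in seq_len(n - 1L)) {
      if (run[i] == 0) run[i] <- last else last <- run[i]
    }
    idx <- integer(0); type <- integer(0)
    i <- 1L
    while (i < n - 1L) {
      if (run[i + 1L] != run[i] && run[i] != 0 && run[i + 1L] != 0) {
        j0 <- i + 1L
        while (j0 > 1L && x[j0 - 1L] == x[j0]) j0 <- j0 - 1L
        j1 <- i + 1L
        while (j1 < n && x[j1 + 1L] == x[j1]) j1 <- j1 + 1L
        idx <- c(idx, as.integer(round((j0 + j1) / 2)))
        type <- c(type, if (run[i] > 0) 1L else -1L)
      }
      i <- i + 1L
    }
  }
  if (!length(idx)) return(data.frame(idx = integer(0), type = integer(0)))
  # prominence pruning: repeatedly drop adjacent extremum pairs whose swing
  # is below `prominence`. Weak pairs are removed in left-to-right passes
  # (skipping overlaps) until the list stabilizes, then a strict
  # weakest-first sweep finishes off any stragglers.
  repeat {
    k <- length(idx)
    if (k < 2L) break
    swings <- abs(diff(x[idx]))
    weak <- swings < prominence
    if (!any(weak)) break
    drop <- logical(k)
    i <- 1L
    while (i < k) {
      if (weak[i] && !drop[i]) {
        drop[i] <- TRUE; drop[i + 1L] <- TRUE
        i <- i + 2L
      } else i <- i + 1L
    }
    if (!any(drop)) break
    idx <- idx[!drop]; type <- type[!drop]
  }
  repeat {
    if (length(idx) < 2L) break
    swings <- abs(diff(x[idx]))
    weak <- which.min(swings)
    if (swings[weak] >= prominence) break
    idx <- idx[-c(weak, weak + 1L)]
    type <- type[-c(weak, weak + 1L)]
  }
  data.frame(idx = idx, type = type)
}

#' Smooth an MUA series by the single-peak/single-trough criterion
#'
#' Rebins the spike counts to 10-s bins, converts to Hz, and applies a
#' centered moving average whose bandwidth is chosen by scanning an
#' increasing grid and keeping the smallest value for which every complete
#' circadian cycle contains exactly one (prominence-filtered) local maximum
#' and one local minimum. Cycles run from mid-period to mid-period (lights
#' off to lights off under LD, CT12 to CT12 otherwise), so each complete
#' cycle holds one night trough and one day peak.
#'
#' @param series a `binned_series` of spike counts.
#' @param schedule a [light_schedule()].
#' @param exclude_mask optional logical vector (per input bin): `TRUE` bins
#'   (e.g. behaviorally active episodes and their recovery tails) are
#'   excluded from the fit.
#' @param bw_grid_h bandwidth grid in hours (full window width).
#' @param rebin_s working resolution in seconds.
#' @param prominence_frac minimum extremum prominence, as a fraction of the
#'   smoothed trace's range, used to ignore residual noise wiggles on
#'   plateaus.
#' @param level_halfwin_s half-window (s) over which the smoothed trace is
#'   averaged around each extremum to report its level; averaging suppresses
#'   the upward (downward) noise bias of taking a pointwise max (min).
#' @return an object of class `rhythm_fit`: list with `rhythmic` (logical),
#'   `smoothed` (a `binned_series` in Hz at `rebin_s`), `bandwidth_h`,
#'   `cycles` (data.frame: `cycle`, `peak_time_s`, `peak_hz`,
#'   `trough_time_s`, `trough_hz`, `amplitude_hz`), and `mean_amplitude_hz`.
#'   If no bandwidth satisfies the criterion the fit is marked arrhythmic
#'   and amplitude fields are `NA`.
#' @export
smooth_mua <- function(series, schedule = light_schedule(),
                       exclude_mask = NULL,
                       bw_grid_h = seq(0.5, 6, by = 0.5),
                       rebin_s = 10,
                       prominence_frac = 0.05,
                       level_halfwin_s = 1800) {
  if (length(series$values) * series$bin_s < schedule$period_h * 3600)
    stop("series must span at least one full circadian cycle", call. = FALSE)
  k <- as.integer(round(rebin_s / series$bin_s))
  rb <- rebin_series(series, rebin_s)
  rate <- rb$values / rebin_s
  w <- rep(1, length(rate))
  if (!is.null(exclude_mask)) {
    if (length(exclude_mask) != length(series$values))
      stop("exclude_mask must match the input series length", call. = FALSE)
    n <- length(rate)
    m <- matrix(exclude_mask[seq_len(n * k)], nrow = k)
    w <- as.numeric(colSums(m) == 0)  # keep only fully clean coarse bins
  }

  P_s <- schedule$period_h * 3600
  t_bins <- bin_times(rb) + rebin_s / 2
  # complete cycles: [half + m*P, half + (m+1)*P) within the span
  span0 <- rb$t0; span1 <- series_end(rb)
  first_cycle <- ceiling((span0 - P_s / 2) / P_s)
  last_cycle <- floor((span1 - P_s / 2) / P_s)
  cycle_starts <- if (last_cycle >= first_cycle)
    P_s / 2 + P_s * seq(first_cycle, last_cycle) else numeric(0)
  cycle_starts <- cycle_starts[cycle_starts >= span0 - 1e-9 &
                                 cycle_starts + P_s <= span1 + 1e-9]

  # phase-folded clean-rhythm profile from unmasked bins (5-min phase bins,
  # empty bins filled by circular interpolation); used by the event detector
  # as the drift reference, robust where whole stretches are masked
  nb <- 288L
  ph_idx <- pmin(nb, floor(((t_bins %% P_s) / P_s) * nb) + 1L)
  wsum <- tapply(w, ph_idx, sum)
  prof <- rep(NA_real_, nb)
  got <- as.integer(names(wsum))
  prof[got] <- as.numeric(tapply(rate * w, ph_idx, sum)) / as.numeric(wsum)
  prof[!is.finite(prof)] <- NA_real_
  if (anyNA(prof) && sum(!is.na(prof)) >= 2L) {
    ii <- which(!is.na(prof))
    # circular linear interpolation across empty phase bins
    ext_x <- c(ii - nb, ii, ii + nb)
    ext_y <- rep(prof[ii], 3L)
    prof <- stats::approx(ext_x, ext_y, xout = seq_len(nb))$y
  }
  profile <- list(levels_hz = prof, n_bins = nb, period_s = P_s)

  for (bw in bw_grid_h) {
    half_win <- max(1L, as.integer(round(bw * 3600 / rebin_s / 2)))
    sm <- moving_average(rate, w, half_win)
    rng <- max(sm) - min(sm)
    if (rng <= 0) next
    ext <- find_extrema(sm, prominence = prominence_frac * rng)
    if (!nrow(ext)) next
    ok <- TRUE
    cyc <- vector("list", length(cycle_starts))
    for (ci in seq_along(cycle_starts)) {
      cs <- cycle_starts[ci]
      in_cyc <- ext$idx[t_bins[ext$idx] >= cs & t_bins[ext$idx] < cs + P_s]
      types <- ext$type[t_bins[ext$idx] >= cs & t_bins[ext$idx] < cs + P_s]
      if (sum(types == 1L) != 1L || sum(types == -1L) != 1L) { ok <- FALSE; break }
      # anchor the peak/trough at the cycle's global extremum of the
      # smoothed trace (the pruned extrema fix the count; their surviving
      # positions can sit at a plateau edge)
      cyc_idx <- which(t_bins >= cs & t_bins < cs + P_s)
      pk <- cyc_idx[which.max(sm[cyc_idx])]
      tr <- cyc_idx[which.min(sm[cyc_idx])]
      # level = mean of the smoothed trace over the contiguous plateau
      # around the extremum (bins within the prominence band of its level,
      # capped at level_halfwin_s per side). Averaging removes the outward
      # noise bias of a pointwise min/max, and the band cap stops the
      # window at the day/night transitions.
      hw <- max(1L, as.integer(round(level_halfwin_s / rebin_s)))
      level <- function(j, band) {
        ok <- abs(sm - sm[j]) <= band
        lo <- j; hi <- j
        while (lo > 1L && ok[lo - 1L] && j - lo < hw) lo <- lo - 1L
        while (hi < length(sm) && ok[hi + 1L] && hi - j < hw) hi <- hi + 1L
        mean(sm[lo:hi])
      }
      band <- prominence_frac * rng
      cyc[[ci]] <- data.frame(cycle = ci,
                              peak_time_s = t_bins[pk],
                              peak_hz = level(pk, band),
                              trough_time_s = t_bins[tr],
                              trough_hz = level(tr, band),
                              amplitude_hz = level(pk, band) - level(tr, band))
    }
    if (ok && length(cycle_starts)) {
      cycles <- do.call(rbind, cyc)
      fit <- list(rhythmic = TRUE,
                  smoothed = binned_series(pmax(sm, 0), rebin_s, t0 = rb$t0,
                                           channel = "mua"),
                  bandwidth_h = bw, schedule = schedule,
                  cycles = cycles,
                  cycle_starts_s = cycle_starts,
                  profile = profile,
                  mean_amplitude_hz = mean(cycles$amplitude_hz))
      class(fit) <- "rhythm_fit"
      return(fit)
    }
  }
  fit <- list(rhythmic = FALSE, smoothed = NULL, bandwidth_h = NA_real_,
              schedule = schedule, cycles = NULL,
              cycle_starts_s = cycle_starts, profile = profile,
              mean_amplitude_hz = NA_real_)
  class(fit) <- "rhythm_fit"
  fit
}

#' @export
print.rhythm_fit <- function(x, ...) {
  if (!x$rhythmic) {
    cat("<rhythm_fit> arrhythmic (no bandwidth met the one-peak/one-trough criterion)\n")
  } else {
    cat(sprintf("<rhythm_fit> bandwidth %g h, %d complete cycle(s), mean amplitude %.2f Hz\n",
                x$bandwidth_h, nrow(x$cycles), x$mean_amplitude_hz))
  }
  invisible(x)
}

#' Circadian amplitude from a rhythm fit
#'
#' Amplitude is the peak-minus-trough difference of the smoothed trace,
#' per complete cycle, plus the mean over cycles.
#'
#' @param fit a `rhythm_fit` from [smooth_mua()].
#' @return list with `per_cycle` (numeric vector, Hz) and `mean` (Hz).
#' @export
rhythm_amplitude <- function(fit) {
  if (!isTRUE(fit$rhythmic))
    stop("amplitude is undefined for an arrhythmic fit", call. = FALSE)
  list(per_cycle = fit$cycles$amplitude_hz, mean = fit$mean_amplitude_hz)
}

# Amplitude of the cycle containing time t_s; recording mean as fallback for
# times outside complete cycles.
amplitude_at <- function(fit, t_s) {
  if (!isTRUE(fit$rhythmic)) return(NA_real_)
  cs <- fit$cycle_starts_s
  out <- rep(fit$mean_amplitude_hz, length(t_s))
  if (length(cs)) {
    ci <- findInterval(t_s, cs)
    P_s <- fit$schedule$period_h * 3600
    inside <- ci >= 1 & ci <= length(cs) & t_s < cs[pmax(ci, 1)] + P_s
    out[inside] <- fit$cycles$amplitude_hz[ci[inside]]
  }
  out
}

#' Map recording time to circadian phase (ZT or CT hours)
#'
#' Under LD the phase is Zeitgeber Time with ZT12 at lights off; under
#' constant conditions it is Circadian Time from the reference phase and the
#' configured period. Recording time 0 corresponds to phase 0 by the
#' package's file convention.
#'
#' @param t_s time(s) in seconds from recording start.
#' @param schedule a [light_schedule()].
#' @return numeric phase in `[0, 24)` hours (scaled to the period).
#' @export
to_circadian_time <- function(t_s, schedule = light_schedule()) {
  if (any(t_s < schedule$reference_s))
    stop("time precedes the schedule reference", call. = FALSE)
  ((t_s - schedule$reference_s) / 3600) %% schedule$period_h /
    schedule$period_h * 24
}
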