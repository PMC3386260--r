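#' Spike-amplitude histogram over a baseline window
#'
#' Builds the amplitude histogram of all spikes in a quiescent baseline
#' window (by convention the 100 s immediately preceding a behavior bout).
#' The histogram total equals the number of spikes in the window regardless
#' of bin width.
#'
#' @param amps amplitude stream: data.frame with `time_s` and `amplitude`.
#' @param t0,t1 baseline window bounds (s); `t1 - t0` must be >= 100 s.
#' @param breaks passed to [graphics::hist()] semantics via
#'   [base::cut()]; either a bin width or a vector of break points.
#' @return list with `mids`, `counts`, `breaks`, `n` (total spikes) and the
#'   window bounds.
#' @export
amplitude_histogram <- function(amps, t0, t1, breaks = 0.25) {
  if (t1 - t0 < 100 - 1e-9)
    stop("baseline window must be at least 100 s", call. = FALSE)
  a <- amps$amplitude[amps$time_s >= t0 & amps$time_s < t1]
  if (!length(a)) stop("no spikes in the baseline window", call. = FALSE)
  if (length(breaks) == 1L) {
    w <- breaks
    lo <- floor(min(a) / w) * w
    hi <- ceiling(max(a) / w) * w + w / 2
    breaks <- seq(lo, hi, by = w)
  }
  counts <- tabulate(findInterval(a, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  list(mids = (breaks[-1L] + breaks[-length(breaks)]) / 2,
       counts = counts, breaks = breaks, n = length(a),
       window = c(t0, t1))
}

#' Equal-count amplitude threshold windows
#'
#' Splits the above-noise amplitude range into `k` contiguous, non-overlapping
#' windows holding (as nearly as possible) equal baseline spike counts:
#' boundaries are the empirical i/k quantiles of the above-noise baseline
#' amplitudes. Windows are half-open upward, `[low, high)`, with the top
#' window unbounded; a spike exactly at a boundary belongs to the upper
#' window.
#'
#' @param amps amplitude stream (data.frame with `time_s`, `amplitude`).
#' @param t0,t1 baseline window (s).
#' @param k number of windows.
#' @param noise_threshold amplitudes at or below this are treated as noise
#'   and excluded.
#' @return object of class `amplitude_windows`: list with `bounds` (matrix
#'   k x 2 of `[low, high)`), `noise_threshold`, `baseline_counts`,
#'   `baseline_rate_hz`, `window` (the baseline bounds).
#' @export
equal_count_windows <- function(amps, t0, t1, k = 2, noise_threshold = 0) {
  a <- amps$amplitude[amps$time_s >= t0 & amps$time_s < t1]
  a <- a[a > noise_threshold]
  n <- length(a)
  if (n < k) stop("fewer above-noise baseline spikes than windows",
                  call. = FALSE)
  if (length(unique(a)) < k)
    stop("fewer distinct amplitude values than windows", call. = FALSE)
  # empirical i/k quantile boundaries, placed midway between the adjacent
  # order statistics so each window holds an equal share within one spike
  a_s <- sort(a)
  m <- round(seq_len(k - 1L) * n / k)
  qs <- (a_s[m] + a_s[pmin(m + 1L, n)]) / 2
  lows <- unname(c(noise_threshold, qs))
  highs <- unname(c(qs, Inf))
  # lowest window is open at the noise floor: (noise, b1); others [b_i, b_i+1)
  counts <- vapply(seq_len(k), function(i) {
    if (i == 1L) sum(a > lows[1L] & a < highs[1L])
    else sum(a >= lows[i] & a < highs[i])
  }, numeric(1))
  structure(list(bounds = cbind(low = lows, high = highs),
                 noise_threshold = noise_threshold,
                 baseline_counts = counts,
                 baseline_rate_hz = counts / (t1 - t0),
                 window = c(t0, t1), k = k),
            class = "amplitude_windows")
}

#' @export
print.amplitude_windows <- function(x, ...) {
  cat(sprintf("<amplitude_windows> k = %d above noise %.3g\n", x$k,
              x$noise_threshold))
  for (i in seq_len(x$k))
    cat(sprintf("  [%g, %g): %d baseline spikes (%.2f Hz)\n",
                x$bounds[i, 1], x$bounds[i, 2], x$baseline_counts[i],
                x$baseline_rate_hz[i]))
  invisible(x)
}

#' Per-window binned spike-count series
#'
#' Counts, per time bin, the spikes whose amplitude falls in each threshold
#' window. Summed over windows this reproduces the total above-noise count
#' series exactly.
#'
#' @param amps amplitude stream (data.frame with `time_s`, `amplitude`).
#' @param windows an [equal_count_windows()] object.
#' @param bin_s bin width (s).
#' @param t0 start of the binned span (s).
#' @param t_end end of the binned span (s); default the last spike time.
#' @return list of `binned_series`, one per window.
#' @export
window_series <- function(amps, windows, bin_s = 2, t0 = 0,
                          t_end = max(amps$time_s)) {
  n_bins <- ceiling((t_end - t0) / bin_s)
  lapply(seq_len(windows$k), function(i) {
    lo <- windows$bounds[i, 1]; hi <- windows$bounds[i, 2]
    sel <- if (i == 1L) amps$amplitude > lo & amps$amplitude < hi
           else amps$amplitude >= lo & amps$amplitude < hi
    tt <- amps$time_s[sel]
    tt <- tt[tt >= t0 & tt < t_end]
    counts <- tabulate(floor((tt - t0) / bin_s) + 1L, nbins = n_bins)
    binned_series(counts, bin_s, t0 = t0, channel = "mua")
  })
}

#' Per-window suppression magnitudes and heterogeneity verdict
#'
#' Computes the suppression magnitude separately within each amplitude
#' window (same `M = 100 (B_w - S_w) / A` statistic as the total-series
#' analysis) and tests whether the windows respond heterogeneously: the
#' verdict is `"heterogeneous"` when the largest window contrast exceeds
#' twice its pooled Poisson standard error.
#'
#' @param series_list per-window series from [window_series()].
#' @param onset_s,offset_s event bounds (s).
#' @param windows the [equal_count_windows()] object (for baseline rates).
#' @param A circadian amplitude (Hz) of the *total* series; each window's
#'   magnitude uses its share so that window magnitudes are comparable to
#'   the total magnitude (`A / k` per window under equal baseline splits).
#' @return list with `per_window` (data.frame: `window`, `baseline_hz`,
#'   `suppressed_hz`, `magnitude_pct`, `se_pct`), `verdict`
#'   (`"heterogeneous"` or `"homogeneous"`), and `suppressed_window` (index
#'   of the window with the largest magnitude).
#' @export
window_contrast <- function(series_list, onset_s, offset_s, windows, A) {
  if (A <= 0) stop("amplitude must be positive", call. = FALSE)
  k <- length(series_list)
  A_w <- A / k
  T_base <- diff(windows$window)
  T_evt <- offset_s - onset_s
  per <- do.call(rbind, lapply(seq_len(k), function(i) {
    B_w <- windows$baseline_rate_hz[i]
    S_w <- window_rate(series_list[[i]], onset_s, offset_s)
    M_w <- suppression_magnitude(B_w, S_w, A_w)
    se_rate <- sqrt(B_w / T_base + max(B_w, S_w) / T_evt)
    data.frame(window = i, baseline_hz = B_w, suppressed_hz = S_w,
               magnitude_pct = M_w, se_pct = 100 * se_rate / A_w)
  }))
  hi <- which.max(per$magnitude_pct)
  lo <- which.min(per$magnitude_pct)
  contrast <- per$magnitude_pct[hi] - per$magnitude_pct[lo]
  pooled <- sqrt(per$se_pct[hi]^2 + per$se_pct[lo]^2)
  list(per_window = per,
       verdict = if (contrast > 2 * pooled) "heterogeneous" else "homogeneous",
       suppressed_window = hi)
}
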