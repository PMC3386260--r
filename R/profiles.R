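#' Behavior-conditioned circadian activity profiles
#'
#' Rebins the MUA counts to 10-s bins, labels each bin active when any PIR
#' signal falls within it, and smooths the active and inactive subsets
#' separately with the rhythm smoother (each subset masks the other's bins).
#' On behavior-coupled recordings the active curve runs below the inactive
#' curve; the two subsets partition all analyzed bins.
#'
#' @param mua a `binned_series` of spike counts.
#' @param pir a `binned_series` of PIR values (binarized at > 0).
#' @param schedule a [light_schedule()].
#' @param rebin_s profile resolution (s).
#' @return object of class `conditioned_profile`: list with `time_s`,
#'   `phase_h`, `rate_hz`, `active` (per 10-s bin), fitted `fit_active` and
#'   `fit_inactive` (`rhythm_fit` objects), and `coverage` (fraction of
#'   1-h phase bins in which each subset has data).
#' @export
conditioned_profiles <- function(mua, pir, schedule = light_schedule(),
                                 rebin_s = 10) {
  al <- align_streams(mua, pir)
  rb <- rebin_series(al$mua, rebin_s)
  k <- as.integer(round(rebin_s / al$pir$bin_s))
  n <- length(rb$values)
  pv <- al$pir$values[seq_len(n * k)] > 0
  active <- as.logical(colSums(matrix(pv, nrow = k)) > 0)
  rate <- rb$values / rebin_s
  phase <- to_circadian_time(bin_times(rb) + rebin_s / 2, schedule)

  cover <- function(sel) {
    hrs <- unique(floor(phase[sel]))
    length(hrs) / 24
  }
  cov <- c(active = cover(active), inactive = cover(!active))
  if (any(cov < 0.5))
    warning(sprintf(
      "sparse phase coverage (active %.0f%%, inactive %.0f%% of hour bins); profile is partial",
      100 * cov[["active"]], 100 * cov[["inactive"]]))

  mask_from <- function(keep10) {
    # expand the 10-s keep flags back to the original bin width
    rep(!keep10, each = k)[seq_along(al$mua$values)]
  }
  fit_subset <- function(keep10) {
    if (sum(keep10) < 2L) return(NULL)
    smooth_mua(al$mua, schedule, exclude_mask = mask_from(keep10))
  }
  fit_active <- fit_subset(active)
  fit_inactive <- fit_subset(!active)
  structure(list(time_s = bin_times(rb), phase_h = phase, rate_hz = rate,
                 active = active, fit_active = fit_active,
                 fit_inactive = fit_inactive, coverage = cov),
            class = "conditioned_profile")
}

#' @export
print.conditioned_profile <- function(x, ...) {
  cat(sprintf("<conditioned_profile> %d bins (%.0f%% active); coverage active %.0f%%, inactive %.0f%%\n",
              length(x$rate_hz), 100 * mean(x$active),
              100 * x$coverage[["active"]], 100 * x$coverage[["inactive"]]))
  invisible(x)
}

#' Amplitude scenarios from a conditioned profile
#'
#' The two bounding scenarios for the circadian amplitude under behavioral
#' feedback: when activity is concentrated at night (and absent by day) the
#' effective amplitude is `peak(inactive) - trough(active)`; when activity
#' falls in the day instead it is `peak(active) - trough(inactive)`.
#' Both are returned in Hz and as a percentage of the inactive-curve
#' (baseline) amplitude.
#'
#' @param profile a [conditioned_profiles()] object.
#' @return list with `night_active_hz`, `day_active_hz`, `baseline_hz`,
#'   `night_active_pct`, `day_active_pct`.
#' @export
amplitude_scenarios <- function(profile) {
  fa <- profile$fit_active
  fi <- profile$fit_inactive
  if (is.null(fa) || is.null(fi))
    stop("missing conditioned curve: one subset is empty", call. = FALSE)
  if (!isTRUE(fa$rhythmic) || !isTRUE(fi$rhythmic))
    stop("both conditioned curves must be rhythmic", call. = FALSE)
  peak_a <- mean(fa$cycles$peak_hz); trough_a <- mean(fa$cycles$trough_hz)
  peak_i <- mean(fi$cycles$peak_hz); trough_i <- mean(fi$cycles$trough_hz)
  A0 <- peak_i - trough_i
  night_active <- peak_i - trough_a
  day_active <- peak_a - trough_i
  list(night_active_hz = night_active, day_active_hz = day_active,
       baseline_hz = A0,
       night_active_pct = 100 * night_active / A0,
       day_active_pct = 100 * day_active / A0)
}

#' Classical one-way ANOVA from sums of squares
#'
#' Computes the between/within decomposition explicitly. Degenerate cases:
#' zero within-group variance with distinct means gives `F = Inf`, `p = 0`;
#' all values identical gives `F = 0`, `p = 1`.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor).
#' @return list with `F`, `df1`, `df2`, `p`, `ss_between`, `ss_within`.
#' @export
anova_oneway <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  n <- length(values)
  grand <- mean(values)
  means <- tapply(values, g, mean)
  ns <- tabulate(g)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((values - means[g])^2)
  df1 <- nlevels(g) - 1L
  df2 <- n - nlevels(g)
  if (ss_w <= 1e-12 * max(ss_b, 1)) {
    if (ss_b <= 1e-12) return(list(F = 0, df1 = df1, df2 = df2, p = 1,
                                   ss_between = ss_b, ss_within = ss_w))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0,
                ss_between = ss_b, ss_within = ss_w))
  }
  Fv <- (ss_b / df1) / (ss_w / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       ss_between = ss_b, ss_within = ss_w)
}

#' Suppression magnitude by initiating behavior type
#'
#' Groups detected events by their initiating behavior, reports per-type
#' mean, SEM and n, runs the one-way ANOVA across types, and flags
#' Bonferroni-adjusted pairwise pooled-variance t tests.
#'
#' @param events event table from [detect_suppressions()].
#' @param min_n groups with fewer events are excluded (with a warning).
#' @param alpha family significance level for the pairwise flags.
#' @return list with `by_type` (data.frame: `initiating`, `mean_pct`,
#'   `sem_pct`, `n`), `anova` (from [anova_oneway()]), and `pairwise`
#'   (data.frame: `a`, `b`, `t`, `p_adj`, `significant`).
#' @export
magnitude_by_type <- function(events, min_n = 2, alpha = 0.01) {
  tab <- table(events$initiating)
  keep <- names(tab)[tab >= min_n]
  drop <- setdiff(names(tab), keep)
  if (length(drop))
    warning("excluding type(s) with n < ", min_n, ": ",
            paste(drop, collapse = ", "))
  ev <- events[events$initiating %in% keep, , drop = FALSE]
  if (length(keep) < 2) stop("need >= 2 types with enough events", call. = FALSE)
  by_type <- do.call(rbind, lapply(keep, function(ty) {
    x <- ev$magnitude_pct[ev$initiating == ty]
    data.frame(initiating = ty, mean_pct = mean(x),
               sem_pct = stats::sd(x) / sqrt(length(x)), n = length(x))
  }))
  by_type <- by_type[order(by_type$mean_pct), ]
  rownames(by_type) <- NULL
  aov1 <- anova_oneway(ev$magnitude_pct, ev$initiating)
  pairs <- utils::combn(keep, 2)
  m <- ncol(pairs)
  mse <- aov1$ss_within / aov1$df2
  pw <- do.call(rbind, lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    xa <- ev$magnitude_pct[ev$initiating == a]
    xb <- ev$magnitude_pct[ev$initiating == b]
    tstat <- (mean(xa) - mean(xb)) /
      sqrt(mse * (1 / length(xa) + 1 / length(xb)))
    p <- 2 * stats::pt(abs(tstat), aov1$df2, lower.tail = FALSE)
    data.frame(a = a, b = b, t = tstat, p_adj = min(1, p * m),
               significant = min(1, p * m) < alpha)
  }))
  list(by_type = by_type, anova = aov1, pairwise = pw)
}

#' Day/night suppression statistics
#'
#' Splits events into subjective day (phase \[0, 12)) and night
#' (\[12, 24)), reports (mean, SEM, n) per class, and tests the day/night
#' difference: a two-way ANOVA with animal as a blocking factor when at
#' least two animals are present (fitted by least squares via [stats::lm()]),
#' otherwise the one-way F test, at `alpha = 0.05`.
#'
#' @param events event table with `magnitude_pct` and `is_day` (and
#'   optionally `animal`).
#' @return list with `day` and `night` (each `c(mean, sem, n)`), `p`,
#'   `significant`, `method`.
#' @export
day_night_stats <- function(events) {
  if (!nrow(events)) stop("no events", call. = FALSE)
  if (all(events$is_day) || all(!events$is_day))
    stop("all events fall in one phase class", call. = FALSE)
  summ <- function(x) c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
                        n = length(x))
  day <- summ(events$magnitude_pct[events$is_day])
  night <- summ(events$magnitude_pct[!events$is_day])
  has_animals <- "animal" %in% names(events) &&
    length(unique(events$animal)) >= 2
  if (has_animals) {
    fit <- stats::lm(magnitude_pct ~ factor(is_day) + factor(animal),
                     data = events)
    an <- stats::anova(fit)
    p <- an[["Pr(>F)"]][1L]
    method <- "two-way ANOVA (phase + animal block)"
  } else {
    p <- anova_oneway(events$magnitude_pct, events$is_day)$p
    method <- "one-way ANOVA (phase)"
  }
  list(day = day, night = night, p = p, significant = p < 0.05,
       method = method)
}

#' Per-circadian-hour event summary
#'
#' Mean suppression magnitude and event count in each of the 24 circadian
#' hour bins `[h, h+1)`. Empty hours are reported with `n = 0`.
#'
#' @param events event table with `phase_h` and `magnitude_pct`.
#' @return data.frame with `hour`, `mean_pct`, `n`.
#' @export
per_hour_profile <- function(events) {
  if (!nrow(events)) stop("need at least one event", call. = FALSE)
  hr <- floor(events$phase_h) %% 24
  do.call(rbind, lapply(0:23, function(h) {
    x <- events$magnitude_pct[hr == h]
    data.frame(hour = h,
               mean_pct = if (length(x)) mean(x) else NA_real_,
               n = length(x))
  }))
}
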