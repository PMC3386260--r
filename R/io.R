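#' Uniformly binned time series
#'
#' Container for spike counts (or PIR values) in uniform time bins. Values
#' are counts per bin for `channel = "mua"` and non-negative activity values
#' for `channel = "pir"` (binarized at > 0 for analysis).
#'
#' @param values numeric vector, one value per bin, all non-negative.
#' @param bin_s bin width in seconds.
#' @param t0 start time of the first bin, seconds from recording start.
#' @param channel `"mua"` or `"pir"`.
#' @return an object of class `binned_series`.
#' @export
binned_series <- function(values, bin_s, t0 = 0, channel = c("mua", "pir")) {
  channel <- match.arg(channel)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("binned series must have length >= 1", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("binned series values must be non-negative and non-missing", call. = FALSE)
  if (bin_s <= 0) stop("bin_s must be positive", call. = FALSE)
  structure(list(t0 = t0, bin_s = bin_s, values = values, channel = channel),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("<binned_series:%s> %d bins of %g s from t=%g s (%.2f h)\n",
              x$channel, length(x$values), x$bin_s, x$t0,
              length(x$values) * x$bin_s / 3600))
  invisible(x)
}

#' Bin start times of a binned series
#' @param x a `binned_series`.
#' @return numeric vector of bin start times in seconds.
#' @export
bin_times <- function(x) x$t0 + (seq_along(x$values) - 1L) * x$bin_s

#' End of the covered span of a binned series (seconds)
#' @param x a `binned_series`.
#' @export
series_end <- function(x) x$t0 + length(x$values) * x$bin_s

#' Convert counts per bin to a firing rate in Hz
#' @param x a `binned_series` holding counts.
#' @return numeric vector of rates (Hz), one per bin.
#' @export
series_rate <- function(x) x$values / x$bin_s

#' Read a two-column binned series file
#'
#' Parses a delimited text file with columns `t_start_s` and a value column
#' (count or PIR level). A header line is optional; `#` comment lines are
#' skipped. The constant bin width is inferred from consecutive start times;
#' a non-uniform step is a hard error naming the offending row.
#'
#' @param path file path.
#' @param channel `"mua"` or `"pir"`.
#' @return a [binned_series()].
#' @export
read_binned_series <- function(path, channel = c("mua", "pir")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) stop("empty series file: ", path, call. = FALSE)
  first <- strsplit(lines[[1L]], "[\t,;[:space:]]+")[[1L]]
  has_header <- suppressWarnings(anyNA(as.numeric(first)))
  if (has_header) lines <- lines[-1L]
  if (!length(lines)) stop("no data rows in: ", path, call. = FALSE)
  parts <- strsplit(lines, "[\t,;[:space:]]+")
  mat <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[1:2]), numeric(2)))
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 2, any))[1L]
    stop(sprintf("non-numeric data at row %d of %s", bad + has_header, path),
         call. = FALSE)
  }
  t <- mat[1L, ]; v <- mat[2L, ]
  if (any(v < 0)) {
    bad <- which(v < 0)[1L]
    stop(sprintf("negative value at row %d of %s", bad + has_header, path),
         call. = FALSE)
  }
  if (length(t) > 1L) {
    dt <- diff(t)
    if (any(abs(dt - dt[1L]) > 1e-9 * max(1, abs(dt[1L])))) {
      bad <- which(abs(dt - dt[1L]) > 1e-9 * max(1, abs(dt[1L])))[1L] + 1L
      stop(sprintf("non-uniform bin width at row %d of %s", bad + has_header,
                   path), call. = FALSE)
    }
    bin_s <- dt[1L]
  } else {
    bin_s <- if (channel == "mua") 2 else 2
  }
  binned_series(v, bin_s = bin_s, t0 = t[1L], channel = channel)
}

#' Write a binned series to a TSV file
#'
#' Two tab-separated columns, `t_start_s` and `count` (or `pir`), UTF-8,
#' Unix newlines. Round-trips through [read_binned_series()] exactly.
#'
#' @param x a `binned_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binned_series <- function(x, path) {
  col2 <- if (x$channel == "pir") "pir" else "count"
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("t_start_s\t", col2),
               paste(format(bin_times(x), trim = TRUE, scientific = FALSE),
                     format(x$values, trim = TRUE, scientific = FALSE),
                     sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Construct an ethogram
#'
#' A sorted table of non-overlapping behavior intervals at 1-s resolution.
#' Valid labels are the nine scored behavior categories (see
#' [behavior_labels()]).
#'
#' @param start_s,end_s interval bounds in seconds (`start < end`).
#' @param behavior character vector of labels.
#' @return a `data.frame` of class `ethogram`.
#' @export
ethogram <- function(start_s, end_s, behavior) {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   behavior = as.character(behavior))
  bad <- setdiff(unique(df$behavior), behavior_labels())
  if (length(bad))
    stop(sprintf("unknown behavior label(s) %s; valid labels are: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(behavior_labels(), collapse = ", ")), call. = FALSE)
  if (any(df$start_s >= df$end_s))
    stop("ethogram intervals must satisfy start < end", call. = FALSE)
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L && any(df$start_s[-1L] < df$end_s[-nrow(df)] - 1e-9)) {
    bad <- which(df$start_s[-1L] < df$end_s[-nrow(df)] - 1e-9)[1L] + 1L
    stop(sprintf("overlapping ethogram intervals at row %d", bad),
         call. = FALSE)
  }
  class(df) <- c("ethogram", "data.frame")
  df
}

#' Read an ethogram TSV file
#'
#' Expects three columns `start_s`, `end_s`, `behavior` (header optional).
#' Intervals are validated: sorted, non-overlapping, known labels only.
#'
#' @param path file path.
#' @return an [ethogram()].
#' @export
read_ethogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("start_s", "end_s", "behavior") %in% names(df))) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
    names(df) <- c("start_s", "end_s", "behavior")
  }
  ethogram(df$start_s, df$end_s, df$behavior)
}

#' Write an ethogram to a TSV file
#' @param x an `ethogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ethogram <- function(x, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("start_s\tend_s\tbehavior",
               paste(format(x$start_s, trim = TRUE, scientific = FALSE),
                     format(x$end_s, trim = TRUE, scientific = FALSE),
                     x$behavior, sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Per-bin activity indicator from an ethogram
#'
#' Marks each MUA bin as behaviorally active if non-quiescent behavior
#' (anything but lying/sitting) covers at least 1 s of the bin. The 1-s
#' coverage rule for 2-s bins is a fixed analysis convention.
#'
#' @param etho an [ethogram()].
#' @param t0 start of the binned span (s).
#' @param n_bins number of bins.
#' @param bin_s bin width (s).
#' @return logical vector of length `n_bins`.
#' @export
activity_indicator <- function(etho, t0, n_bins, bin_s) {
  cover <- numeric(n_bins)
  act <- etho[!(etho$behavior %in% quiescent_behaviors()), , drop = FALSE]
  t_end <- t0 + n_bins * bin_s
  for (i in seq_len(nrow(act))) {
    s <- max(act$start_s[i], t0); e <- min(act$end_s[i], t_end)
    if (e <= s) next
    first <- floor((s - t0) / bin_s) + 1
    last <- ceiling((e - t0) / bin_s)
    idx <- first:last
    bs <- t0 + (idx - 1) * bin_s
    cover[idx] <- cover[idx] + pmin(e, bs + bin_s) - pmax(s, bs)
  }
  cover >= min(1, bin_s) - 1e-9
}

#' Align MUA, PIR and ethogram streams on their common span
#'
#' Trims all streams to the intersection of their time spans and resamples
#' the ethogram to a per-MUA-bin activity indicator.
#'
#' @param mua a `binned_series` of spike counts.
#' @param pir a `binned_series` of PIR values, or `NULL`.
#' @param etho an [ethogram()], or `NULL`.
#' @return a list with trimmed `mua`, `pir`, `etho`, logical `active` per MUA
#'   bin, and the common `span` (c(start, end), seconds).
#' @export
align_streams <- function(mua, pir = NULL, etho = NULL) {
  starts <- c(mua$t0,
              if (!is.null(pir)) pir$t0,
              if (!is.null(etho) && nrow(etho)) min(etho$start_s))
  ends <- c(series_end(mua),
            if (!is.null(pir)) series_end(pir),
            if (!is.null(etho) && nrow(etho)) max(etho$end_s))
  lo <- max(starts); hi <- min(ends)
  if (hi <= lo) stop("streams have no overlapping time span", call. = FALSE)
  trim <- function(x) {
    i0 <- floor((lo - x$t0) / x$bin_s + 1e-9) + 1
    i1 <- floor((hi - x$t0) / x$bin_s + 1e-9)
    binned_series(x$values[i0:i1], x$bin_s, t0 = x$t0 + (i0 - 1) * x$bin_s,
                  channel = x$channel)
  }
  mua2 <- trim(mua)
  pir2 <- if (!is.null(pir)) trim(pir) else NULL
  etho2 <- etho
  if (!is.null(etho)) {
    keep <- etho$end_s > lo & etho$start_s < hi
    etho2 <- etho[keep, , drop = FALSE]
    etho2$start_s <- pmax(etho2$start_s, lo)
    etho2$end_s <- pmin(etho2$end_s, hi)
    class(etho2) <- c("ethogram", "data.frame")
  }
  active <- if (!is.null(etho2))
    activity_indicator(etho2, mua2$t0, length(mua2$values), mua2$bin_s)
  else rep(FALSE, length(mua2$values))
  list(mua = mua2, pir = pir2, etho = etho2, active = active,
       span = c(lo, hi))
}

#' Write a detected-event table with a JSON sidecar
#'
#' One row per event, tab-separated, all numeric fields at full precision.
#' A `<path>.json` sidecar records the run configuration and seed so the
#' table is self-describing.
#'
#' @param events data.frame of events (possibly 0 rows).
#' @param path output path.
#' @param meta optional list written to the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path, meta = NULL) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", eol = "\n")
  if (!is.null(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a detected-event table written by [write_event_table()]
#' @param path file path.
#' @return a data.frame (0 rows if the table only has a header).
#' @export
read_event_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a flat YAML simulation config file
#'
#' The file holds the [sim_config()] fields as plain key/value pairs
#' (nested lists for `excitation`, `cohort` and `amp_dists`). Unknown keys
#' are rejected; missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return a validated `sim_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$depth_table)) raw$depth_table <- unlist(raw$depth_table)
  if (!is.null(raw$duration_mixture))
    raw$duration_mixture <- as.numeric(unlist(raw$duration_mixture))
  if (!is.null(raw$amp_dists)) {
    raw$amp_dists$nonresponsive <- unlist(raw$amp_dists$nonresponsive)
    raw$amp_dists$responsive <- unlist(raw$amp_dists$responsive)
  }
  do.call(sim_config, raw)
}

#' Write a simulation config to a flat YAML file
#' @param cfg a `sim_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$depth_table <- as.list(x$depth_table)
  x$amp_dists$nonresponsive <- as.list(x$amp_dists$nonresponsive)
  x$amp_dists$responsive <- as.list(x$amp_dists$responsive)
  yaml::write_yaml(x, path)
  invisible(path)
}
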