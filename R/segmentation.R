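# Wall-clock helpers ---------------------------------------------------------

local_epoch <- function(date, hms, tz) {
  as.numeric(as.POSIXct(paste(date, hms), tz = tz))
}

local_date <- function(epoch, tz) {
  as.Date(as.POSIXct(epoch, origin = "1970-01-01", tz = "UTC"), tz = tz)
}

# number of samples of a recording falling in [t0, t1)
samples_in_interval <- function(rec, t0, t1) {
  fs <- rec$fs
  total <- 0L
  for (i in seq_len(nrow(rec$chunks))) {
    cs <- rec$chunks$start[i]; cn <- rec$chunks$n[i]
    lo <- max(0, ceiling((t0 - cs) * fs - 1e-9))
    hi <- min(cn - 1, ceiling((t1 - cs) * fs - 1e-9) - 1)
    if (hi >= lo) total <- total + (hi - lo + 1)
  }
  as.integer(total)
}

#' Cut a recording into calendar-day segments
#'
#' Days are wall-clock days `00:00:00 - 23:59:59` in the given time zone;
#' every sample is assigned to exactly one day. Partial first and last days
#' are returned -- exclusion is a separate step ([filter_segments()]) -- and
#' nighttime samples are retained so each kept day covers a full 24 h.
#' Each segment carries its daytime completeness: the fraction of expected
#' samples present in the standardized daytime window 07:01:00-23:59:59
#' (61139 s, computed from the actual wall-clock epochs, so daylight-saving
#' days use their true day length).
#'
#' @param rec an `accel_recording`.
#' @param tz Olson time-zone name defining the day boundary (the device clock
#'   is epoch-based; the day boundary is wall-clock).
#' @return list of `day_segment` objects: `date`, `recording`,
#'   `daytime_expected`, `daytime_observed`, `daytime_completeness`, `tz`.
#' @export
segment_days <- function(rec, tz = "UTC") {
  if (n_samples(rec) == 0L) return(list())
  t_first <- rec$chunks$start[1L]
  t_last <- recording_end(rec) - 1 / rec$fs
  dates <- seq(local_date(t_first, tz), local_date(t_last, tz), by = "day")
  out <- list()
  for (k in seq_along(dates)) {
    d <- dates[k]
    d0 <- local_epoch(d, "00:00:00", tz)
    d1 <- local_epoch(d + 1, "00:00:00", tz)
    sub <- window_recording(rec, d0, d1)
    if (n_samples(sub) == 0L) next
    day0 <- local_epoch(d, "07:01:00", tz)
    day1 <- local_epoch(d, "23:59:59", tz)
    expected <- round(rec$fs * (day1 - day0))
    observed <- samples_in_interval(sub, day0, day1)
    out[[length(out) + 1L]] <- structure(list(
      date = d, recording = sub, tz = tz,
      daytime_expected = expected, daytime_observed = observed,
      daytime_completeness = if (expected > 0) observed / expected else 0),
      class = "day_segment")
  }
  out
}

#' @export
print.day_segment <- function(x, ...) {
  cat(sprintf("<day_segment> %s (%s): %d samples, daytime completeness %.1f%%\n",
              format(x$date), x$tz, n_samples(x$recording),
              100 * x$daytime_completeness))
  invisible(x)
}

#' Apply the daytime completeness exclusion rule
#'
#' A day segment is excluded when at least `missing_threshold` of the samples
#' expected in the daytime window are missing; at exactly the threshold the
#' segment is excluded. With the default 0.5, a segment is kept only if its
#' daytime completeness exceeds 50%.
#'
#' @param segments list of `day_segment` objects.
#' @param missing_threshold fraction of missing daytime samples at or above
#'   which a segment is dropped; in (0, 1], default 0.5.
#' @return the kept segments, order preserved.
#' @export
filter_segments <- function(segments, missing_threshold = 0.5) {
  if (!(missing_threshold > 0 && missing_threshold <= 1)) {
    stop("missing_threshold must be in (0, 1]", call. = FALSE)
  }
  keep <- vapply(segments, function(s) {
    s$daytime_completeness > 1 - missing_threshold
  }, TRUE)
  segments[keep]
}
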