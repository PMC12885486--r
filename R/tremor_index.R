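#' Tremor Index per sampling-time window
#'
#' Sums the squared level amplitudes over non-overlapping windows of
#' `st_minutes` and scales by `beta`: `TI = beta * sum(theta_f^2)` over the
#' `q = st_minutes * 60 * fs_f` samples of each window. With the level in
#' radians and the default `beta = 1e4`, TI is reported in tiu
#' (1 tiu = 100 mrad^2 per window). Windows are aligned to wall-clock
#' multiples of `st_minutes` (on the hour, quarter past, ...), matching
#' typical on-the-hour / half-past medication times. A window is valid only
#' if all `q` of its samples exist; windows overlapping gaps or extending
#' beyond the data are marked invalid with `ti = NA`, never imputed or
#' partially summed.
#'
#' @param level a `level_series` (see [level_for_frequency()]).
#' @param st_minutes window length in minutes (default 15); `st_minutes * 60
#'   * fs_f` must be a whole number of samples.
#' @param beta scaling operator (default 1e4, which reports tiu).
#' @param tz time zone used for wall-clock window alignment.
#' @param span optional `c(start, end)` Unix seconds over which to enumerate
#'   windows; defaults to the level's data span.
#' @param edge_policy `"ignore"` (default) tolerates the boundary-affected
#'   samples at chunk ends inside otherwise-complete windows; `"invalidate"`
#'   additionally marks windows containing such samples invalid.
#' @return a `ti_series` data.frame with columns `window_start` (Unix
#'   seconds), `ti`, `valid`; attributes `f`, `fs_f`, `st_minutes`, `beta`.
#' @export
tremor_index <- function(level, st_minutes = 15, beta = 1e4, tz = "UTC",
                         span = NULL, edge_policy = c("ignore", "invalidate")) {
  stopifnot(inherits(level, "level_series"))
  edge_policy <- match.arg(edge_policy)
  if (st_minutes <= 0) stop("st_minutes must be positive", call. = FALSE)
  st_s <- st_minutes * 60
  q_len <- st_s * level$fs_f
  if (abs(q_len - round(q_len)) > 1e-6) {
    stop(sprintf("window of %g min is not a whole number of samples at %.4g Hz",
                 st_minutes, level$fs_f), call. = FALSE)
  }
  q_len <- round(q_len)
  ch <- level$chunks
  if (is.null(span)) {
    if (nrow(ch) == 0L) return(empty_ti_series(level, st_minutes, beta))
    span <- c(min(ch$start), max(ch$start + ch$n / level$fs_f))
  }
  off <- utc_offset(span[1L], tz)
  w0 <- span[1L] - ((span[1L] + off) %% st_s)
  nw <- ceiling((span[2L] - w0) / st_s - 1e-9)
  if (nw < 1L) return(empty_ti_series(level, st_minutes, beta))
  starts <- w0 + (seq_len(nw) - 1L) * st_s

  ti <- rep(NA_real_, length(starts))
  valid <- rep(FALSE, length(starts))
  if (nrow(ch) > 0L && q_len <= max(ch$n)) {
    for (i in seq_len(nrow(ch))) {
      cs <- ch$start[i]; cn <- ch$n[i]
      i0 <- ceiling((starts - cs) * level$fs_f - 1e-9)
      ok <- i0 >= 0 & (i0 + q_len) <= cn
      if (edge_policy == "invalidate") {
        ok <- ok & i0 >= level$edge & (i0 + q_len) <= cn - level$edge
      }
      if (!any(ok)) next
      cs2 <- c(0, cumsum(level$values[ch$offset[i] + seq_len(cn)]^2))
      ti[ok] <- beta * (cs2[i0[ok] + q_len + 1L] - cs2[i0[ok] + 1L])
      valid[ok] <- TRUE
    }
  } else if (nrow(ch) > 0L) {
    warning(sprintf("window of %d samples exceeds every chunk; all windows invalid",
                    q_len), call. = FALSE)
  }
  structure(data.frame(window_start = starts, ti = ti, valid = valid),
            f = level$f, fs_f = level$fs_f, st_minutes = st_minutes,
            beta = beta, tz = tz,
            class = c("ti_series", "data.frame"))
}

empty_ti_series <- function(level, st_minutes, beta) {
  structure(data.frame(window_start = numeric(0), ti = numeric(0),
                       valid = logical(0)),
            f = level$f, fs_f = level$fs_f, st_minutes = st_minutes,
            beta = beta, class = c("ti_series", "data.frame"))
}

utc_offset <- function(epoch, tz) {
  lt <- as.POSIXlt(as.POSIXct(epoch, origin = "1970-01-01", tz = "UTC"), tz = tz)
  off <- lt$gmtoff
  if (is.null(off) || is.na(off)) 0 else off
}

#' Full TI profile of a recording
#'
#' Runs the complete quantification pipeline on a recording: calendar-day
#' segmentation and the daytime completeness filter, the elevation angle,
#' per-frequency wavelet levels, and the windowed Tremor Index, giving full
#' 24-hour coverage (nighttime included) for every kept day.
#'
#' @param rec an `accel_recording`.
#' @param config a [ti_run_config()] list of pipeline parameters.
#' @param segments optionally, pre-computed and pre-filtered day segments;
#'   when NULL they are derived from `rec` using `config`.
#' @return named list (`"f3"`, `"f4"`, ...) of `ti_series` data.frames with
#'   an added `date` column, windows concatenated across kept days. Empty
#'   list if no day survives the filter.
#' @export
ti_profile <- function(rec, config = ti_run_config(), segments = NULL) {
  if (is.null(segments)) {
    segments <- filter_segments(segment_days(rec, config$timezone),
                                config$missing_threshold)
  }
  if (length(segments) == 0L) return(structure(list(), names = character(0)))
  per_f <- lapply(config$frequencies, function(f) list())
  names(per_f) <- paste0("f", config$frequencies)
  for (seg in segments) {
    elev <- elevation(seg$recording)
    levels <- levels_for_frequencies(elev, config$frequencies,
                                     config$wavelet_order, config$depth,
                                     with_smooth = FALSE)
    d0 <- local_epoch(seg$date, "00:00:00", seg$tz)
    d1 <- local_epoch(seg$date + 1, "00:00:00", seg$tz)
    for (k in seq_along(levels)) {
      tis <- tremor_index(levels[[k]], config$st_minutes, config$beta,
                          tz = seg$tz, span = c(d0, d1),
                          edge_policy = config$edge_policy)
      tis$date <- seg$date
      per_f[[k]][[length(per_f[[k]]) + 1L]] <- tis
    }
  }
  out <- lapply(seq_along(per_f), function(k) {
    combined <- do.call(rbind, per_f[[k]])
    for (a in c("f", "fs_f", "st_minutes", "beta", "tz")) {
      attr(combined, a) <- attr(per_f[[k]][[1L]], a)
    }
    class(combined) <- c("ti_series", "data.frame")
    combined
  })
  names(out) <- names(per_f)
  out
}

#' Valid TI values of a `ti_series`
#' @param tis a `ti_series`.
#' @return numeric vector of TI values from valid windows.
#' @export
valid_ti <- function(tis) tis$ti[tis$valid]
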