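#' Three-axis wrist accelerometer recording
#'
#' Container for one hand's calibrated acceleration stream. Samples are stored
#' as contiguous chunks on a regular `1/fs` grid; gaps between chunks are
#' first-class metadata and are never interpolated. Chunk `i` holds samples
#' `offset + 1 .. offset + n` of the `ax`/`ay`/`az` vectors, with sample `k`
#' (0-based within the chunk) timestamped `start + k / fs` (Unix seconds UTC).
#'
#' @param ax,ay,az equal-length numeric vectors of acceleration in g.
#' @param fs sampling rate in Hz (> 0).
#' @param chunks data.frame with columns `start` (Unix seconds), `offset`
#'   (0-based index into the sample vectors) and `n` (sample count). Defaults
#'   to a single chunk starting at `start_epoch`.
#' @param start_epoch Unix start time in seconds, used when `chunks` is NULL.
#' @param hand hand label: `"T"` (most tremor-affected), `"nT"` (least), or
#'   `"unknown"`.
#' @return an object of class `accel_recording`.
#' @export
accel_recording <- function(ax, ay, az, fs, start_epoch = NULL, chunks = NULL,
                            hand = c("unknown", "T", "nT")) {
  hand <- match.arg(hand)
  n <- length(az)
  if (length(ax) != n || length(ay) != n) {
    stop("ax, ay, az must have identical lengths", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a positive finite number", call. = FALSE)
  }
  if (is.null(chunks)) {
    if (is.null(start_epoch) || !is.finite(start_epoch)) {
      stop("start_epoch must be finite", call. = FALSE)
    }
    chunks <- data.frame(start = as.numeric(start_epoch), offset = 0L, n = n)
  }
  if (sum(chunks$n) != n) stop("chunk sample counts do not match data", call. = FALSE)
  if (nrow(chunks) > 1L) {
    ends <- chunks$start + chunks$n / fs
    if (any(diff(chunks$start) <= 0) || any(chunks$start[-1L] < ends[-nrow(chunks)] - 1e-9)) {
      stop("chunks must be sorted and non-overlapping", call. = FALSE)
    }
  }
  structure(list(ax = ax, ay = ay, az = az, fs = fs, chunks = chunks, hand = hand),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  gaps <- recording_gaps(x)
  cat(sprintf(
    "<accel_recording> hand=%s fs=%g Hz, %d samples in %d chunk(s), %d gap(s)\n",
    x$hand, x$fs, n_samples(x), nrow(x$chunks), nrow(gaps)))
  cat(sprintf("  span: %.0f .. %.0f (Unix s), %.2f h of data\n",
              x$chunks$start[1L], recording_end(x), n_samples(x) / x$fs / 3600))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `accel_recording`.
#' @export
n_samples <- function(rec) sum(rec$chunks$n)

#' End epoch of a recording (one sample period past the last sample)
#' @param rec an `accel_recording`.
#' @export
recording_end <- function(rec) {
  k <- nrow(rec$chunks)
  rec$chunks$start[k] + rec$chunks$n[k] / rec$fs
}

#' Gap intervals of a recording
#' @param rec an `accel_recording`.
#' @return data.frame with `start` and `end` (Unix seconds) of each
#'   half-open data-free interval between chunks.
#' @export
recording_gaps <- function(rec) {
  k <- nrow(rec$chunks)
  if (k < 2L) return(data.frame(start = numeric(0), end = numeric(0)))
  ends <- rec$chunks$start + rec$chunks$n / rec$fs
  data.frame(start = ends[-k], end = rec$chunks$start[-1L])
}

#' Sample timestamps of a recording
#' @param rec an `accel_recording`.
#' @return numeric vector of Unix-second epochs, one per sample.
#' @export
sample_times <- function(rec) {
  unlist(lapply(seq_len(nrow(rec$chunks)), function(i) {
    rec$chunks$start[i] + (seq_len(rec$chunks$n[i]) - 1) / rec$fs
  }), use.names = FALSE)
}

#' Read an Empatica-E4-style accelerometer CSV
#'
#' The dialect: the first row holds the Unix start timestamp (seconds), the
#' second the sampling rate in Hz, and every following row three
#' comma-separated acceleration values in counts of 1/64 g. Files whose
#' header rows repeat the value once per column (as the device writes them)
#' are accepted. Values are calibrated to g by dividing by 64; non-integer
#' counts are tolerated (pre-calibrated exports) and divided the same way.
#'
#' @param path path to the CSV file.
#' @param hand hand label to attach (`"T"`, `"nT"` or `"unknown"`).
#' @return an `accel_recording` with a single chunk.
#' @export
read_e4_acc <- function(path, hand = c("unknown", "T", "nT")) {
  hand <- match.arg(hand)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  hdr <- readLines(path, n = 2L)
  parse_header_row <- function(line, row, what) {
    v <- suppressWarnings(as.numeric(strsplit(line, ",", fixed = TRUE)[[1L]]))
    if (length(v) == 0L || anyNA(v) || any(!is.finite(v)) || length(unique(v)) != 1L) {
      stop(sprintf("malformed header: line %d does not parse as a single numeric %s",
                   row, what), call. = FALSE)
    }
    v[1L]
  }
  if (length(hdr) < 2L) stop("malformed header: file has fewer than 2 lines", call. = FALSE)
  start_epoch <- parse_header_row(hdr[1L], 1L, "timestamp")
  fs <- parse_header_row(hdr[2L], 2L, "sampling rate")
  if (fs <= 0) stop("malformed header: line 2 sampling rate must be > 0", call. = FALSE)

  n_lines <- length(utils::count.fields(path, sep = ",", blank.lines.skip = FALSE))
  if (n_lines <= 2L) {
    stop(sprintf("empty recording: %s has no sample rows", path), call. = FALSE)
  }
  body <- tryCatch(
    data.table::fread(path, skip = 2L, header = FALSE, sep = ",",
                      colClasses = "numeric", showProgress = FALSE),
    error = function(e) {
      bad <- which(utils::count.fields(path, sep = ",") != 3L)
      bad <- bad[bad > 2L]
      stop(sprintf("malformed body row %d: expected 3 columns",
                   if (length(bad)) bad[1L] - 2L else NA_integer_), call. = FALSE)
    })
  if (nrow(body) == 0L) stop(sprintf("empty recording: %s has no sample rows", path),
                             call. = FALSE)
  if (ncol(body) != 3L) {
    bad <- which(utils::count.fields(path, sep = ",") != 3L)
    bad <- bad[bad > 2L]
    stop(sprintf("malformed body row %d: expected 3 columns",
                 if (length(bad)) bad[1L] - 2L else 1L), call. = FALSE)
  }
  accel_recording(ax = body[[1L]] / 64, ay = body[[2L]] / 64, az = body[[3L]] / 64,
                  fs = fs, start_epoch = start_epoch, hand = hand)
}

#' Write a single-chunk recording in the E4 CSV dialect
#'
#' Counts are `round(g * 64)`, so reading the file back reproduces the
#' quantized values exactly.
#'
#' @param rec an `accel_recording` with exactly one chunk.
#' @param path output path.
#' @export
write_e4_acc <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  if (nrow(rec$chunks) != 1L) {
    stop("write_e4_acc writes one chunk; use write_e4_session for gapped recordings",
         call. = FALSE)
  }
  writeLines(c(format(rec$chunks$start[1L], scientific = FALSE),
               format(rec$fs, scientific = FALSE)), path)
  data.table::fwrite(data.table::data.table(
    x = round(rec$ax * 64), y = round(rec$ay * 64), z = round(rec$az * 64)),
    path, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write a recording as one E4 CSV file per contiguous chunk
#' @param rec an `accel_recording`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return character vector of written paths.
#' @export
write_e4_session <- function(rec, dir, prefix = "ACC") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(rec$chunks))
  for (i in seq_len(nrow(rec$chunks))) {
    idx <- rec$chunks$offset[i] + seq_len(rec$chunks$n[i])
    one <- accel_recording(rec$ax[idx], rec$ay[idx], rec$az[idx], rec$fs,
                           start_epoch = rec$chunks$start[i], hand = rec$hand)
    paths[i] <- file.path(dir, sprintf("%s_%03d.csv", prefix, i))
    write_e4_acc(one, paths[i])
  }
  paths
}

#' Read and stitch all E4 CSV files in a directory
#' @param dir directory containing `*.csv` files in the E4 dialect.
#' @param hand hand label to attach.
#' @param max_gap_s see [stitch()].
#' @export
read_e4_session <- function(dir, hand = c("unknown", "T", "nT"), max_gap_s = 0.1) {
  hand <- match.arg(hand)
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no CSV files in %s", dir), call. = FALSE)
  stitch(lapply(files, read_e4_acc, hand = hand), max_gap_s = max_gap_s)
}

#' Stitch recordings retrieved as separate files into one recording
#'
#' Input recordings are sorted by start time and concatenated. Consecutive
#' files that abut within `max_gap_s` of the exact sample grid continue the
#' same chunk; larger separations become recorded gaps. No samples are ever
#' fabricated or interpolated: the output sample count is the sum of the
#' inputs'.
#'
#' @param recordings list of `accel_recording` objects sharing `fs` and hand
#'   label.
#' @param max_gap_s tolerance in seconds for treating two files as contiguous
#'   (default 0.1).
#' @return a single `accel_recording`.
#' @export
stitch <- function(recordings, max_gap_s = 0.1) {
  stopifnot(length(recordings) >= 1L,
            all(vapply(recordings, inherits, TRUE, "accel_recording")))
  fs <- recordings[[1L]]$fs
  hand <- recordings[[1L]]$hand
  if (any(vapply(recordings, function(r) r$fs, 0) != fs)) {
    stop("incompatible recordings: sampling rates differ", call. = FALSE)
  }
  if (any(vapply(recordings, function(r) r$hand, "") != hand)) {
    stop("incompatible recordings: hand labels differ", call. = FALSE)
  }
  ord <- order(vapply(recordings, function(r) r$chunks$start[1L], 0))
  recordings <- recordings[ord]
  starts <- vapply(recordings, function(r) r$chunks$start[1L], 0)
  ends <- vapply(recordings, recording_end, 0)
  if (any(starts[-1L] < ends[-length(ends)] - 1e-9)) {
    stop("recordings overlap in time; refusing to stitch", call. = FALSE)
  }
  chunk_list <- list()
  off <- 0L
  for (r in recordings) {
    ch <- r$chunks
    ch$offset <- ch$offset + off
    off <- off + n_samples(r)
    chunk_list[[length(chunk_list) + 1L]] <- ch
  }
  chunks <- do.call(rbind, chunk_list)
  # merge chunks that abut on the sample grid
  keep <- rep(TRUE, nrow(chunks))
  for (i in seq_len(nrow(chunks))[-1L]) {
    prev <- max(which(keep[seq_len(i - 1L)]))
    expected <- chunks$start[prev] + chunks$n[prev] / fs
    if (abs(chunks$start[i] - expected) <= max_gap_s &&
        chunks$offset[i] == chunks$offset[prev] + chunks$n[prev]) {
      chunks$n[prev] <- chunks$n[prev] + chunks$n[i]
      keep[i] <- FALSE
    }
  }
  chunks <- chunks[keep, , drop = FALSE]
  rownames(chunks) <- NULL
  accel_recording(
    ax = unlist(lapply(recordings, function(r) r$ax), use.names = FALSE),
    ay = unlist(lapply(recordings, function(r) r$ay), use.names = FALSE),
    az = unlist(lapply(recordings, function(r) r$az), use.names = FALSE),
    fs = fs, chunks = chunks, hand = hand)
}

#' Restrict a recording to a half-open time interval
#' @param rec an `accel_recording`.
#' @param t0,t1 Unix-second bounds; samples with `t0 <= t < t1` are kept.
#' @return an `accel_recording` (possibly with zero samples).
#' @export
window_recording <- function(rec, t0, t1) {
  fs <- rec$fs
  sel_ax <- list(); sel_ay <- list(); sel_az <- list()
  ch_out <- list()
  off <- 0L
  for (i in seq_len(nrow(rec$chunks))) {
    cs <- rec$chunks$start[i]; cn <- rec$chunks$n[i]
    lo <- max(0L, ceiling((t0 - cs) * fs - 1e-9))
    hi <- min(cn - 1L, ceiling((t1 - cs) * fs - 1e-9) - 1L)
    if (hi < lo) next
    idx <- rec$chunks$offset[i] + (lo:hi) + 1L
    sel_ax[[length(sel_ax) + 1L]] <- rec$ax[idx]
    sel_ay[[length(sel_ay) + 1L]] <- rec$ay[idx]
    sel_az[[length(sel_az) + 1L]] <- rec$az[idx]
    ch_out[[length(ch_out) + 1L]] <- data.frame(
      start = cs + lo / fs, offset = off, n = hi - lo + 1L)
    off <- off + hi - lo + 1L
  }
  if (length(ch_out) == 0L) {
    return(accel_recording(numeric(0), numeric(0), numeric(0), fs,
                           chunks = data.frame(start = t0, offset = 0L, n = 0L),
                           hand = rec$hand))
  }
  accel_recording(unlist(sel_ax), unlist(sel_ay), unlist(sel_az), fs,
                  chunks = do.call(rbind, ch_out), hand = rec$hand)
}

#' Export a recording to a columnar debug CSV
#' @param rec an `accel_recording`.
#' @param path output path; columns `epoch_s, ax_g, ay_g, az_g`.
#' @export
write_recording_csv <- function(rec, path) {
  data.table::fwrite(data.table::data.table(
    epoch_s = sample_times(rec), ax_g = rec$ax, ay_g = rec$ay, az_g = rec$az), path)
  invisible(path)
}
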