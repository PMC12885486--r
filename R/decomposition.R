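#' Elevation-angle signal
#'
#' Converts a calibrated recording to the one-dimensional elevation angle
#' `theta = arctan(az / 1)` in radians. Only the dorsal (Oz) axis enters: the
#' forward (Ox) and palm-plane (Oy) axes are dominated by daily activities
#' and are discarded, and the forearm length is fixed at 1 as the neutral
#' operand, which standardizes the angle across wearers.
#'
#' @param rec an `accel_recording` in g.
#' @return an `elevation_series`: `theta` (radians, in `(-pi/2, pi/2)`),
#'   `fs`, and the recording's chunk table.
#' @export
elevation <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  structure(list(theta = atan(rec$az), fs = rec$fs, chunks = rec$chunks),
            class = "elevation_series")
}

#' Per-frequency target sampling rate
#'
#' The rate `8 f / 3` Hz places integer frequency `f` at the centre of the
#' first dyadic detail band `(fs_f/4, fs_f/2]`, so a single wavelet level
#' isolates fluctuations around `f`. All target rates are exact small
#' rational multiples of the 32 Hz device rate, and none exceeds it for
#' `f <= 12`.
#'
#' @param f integer frequency in Hz, 3 to 12.
#' @return the target rate in Hz (possibly non-integer, e.g. 40/3 for 5 Hz).
#' @examples
#' target_rate(12)  # 32: no resampling
#' target_rate(3)   # 8
#' @export
target_rate <- function(f) {
  if (!is.numeric(f) || length(f) != 1L || f != round(f) || f < 3 || f > 12) {
    stop("f must be an integer frequency in 3..12 Hz", call. = FALSE)
  }
  8 * f / 3
}

#' Wavelet level assigned to one target frequency
#'
#' Resamples the elevation series to [target_rate()] of `f` and extracts the
#' first maximal-overlap wavelet detail (nominal band `(2f/3, 4f/3]`,
#' centred at `f`) together with the depth-`depth` smooth. Chunks are
#' processed independently (never across a gap); chunks too short for the
#' decomposition are skipped with a warning.
#'
#' @param series an `elevation_series` (see [elevation()]).
#' @param f integer frequency in Hz, 3..12.
#' @param wavelet_order Daubechies order (default 4).
#' @param depth decomposition depth J (default 4); only the smooth depends
#'   on it.
#' @return a `level_series`: `f`, `fs_f`, `values` and `smooth` (radians,
#'   co-indexed), `chunks`, `band`, and `edge` (boundary-affected samples at
#'   each chunk end).
#' @export
level_for_frequency <- function(series, f, wavelet_order = 4, depth = 4) {
  levels_for_frequencies(series, f, wavelet_order, depth)[[1L]]
}

#' Wavelet levels for a set of target frequencies
#'
#' Same as [level_for_frequency()] for several frequencies at once. The
#' forward transform of each chunk is shared across frequencies: the chunk is
#' reflection-extended and Fourier-transformed once, and for every `f` the
#' spectrum is truncated to the target rate and multiplied by the detail and
#' smooth transfer gains before the inverse transform. This is the
#' frequency-domain composition of [fft_resample()] and [modwt_mra()].
#'
#' @inheritParams level_for_frequency
#' @param frequencies integer frequencies in Hz, each in 3..12.
#' @param with_smooth also compute the smooth (default TRUE); the Tremor
#'   Index needs only the detail, and skipping the smooth halves the work.
#' @return named list of `level_series`, names `"f3"`, `"f4"`, ...
#' @export
levels_for_frequencies <- function(series, frequencies = 3:12,
                                   wavelet_order = 4, depth = 4,
                                   with_smooth = TRUE) {
  stopifnot(inherits(series, "elevation_series"))
  for (f in frequencies) target_rate(f)  # validates
  g <- db_scaling_filter(wavelet_order)
  minlen <- modwt_min_length(length(g), depth)
  fs <- series$fs

  ratios <- lapply(frequencies, function(f) rational_ratio(fs, target_rate(f)))
  qlcm <- Reduce(lcm2, vapply(ratios, function(r) r$q, 0L))

  acc <- lapply(frequencies, function(f) list(values = list(), smooth = list(),
                                              chunks = list(), off = 0L))
  names(acc) <- paste0("f", frequencies)

  for (i in seq_len(nrow(series$chunks))) {
    cs <- series$chunks$start[i]
    cn <- series$chunks$n[i]
    x <- series$theta[series$chunks$offset[i] + seq_len(cn)]
    re <- reflect_extend(x, mult = qlcm)
    Xf <- NULL
    for (k in seq_along(frequencies)) {
      p <- ratios[[k]]$p; q <- ratios[[k]]$q
      n_out <- floor(cn * p / q)
      if (n_out < minlen) {
        warning(sprintf(
          "chunk %d (%d samples) too short for f=%g Hz (needs %d resampled samples); skipped",
          i, cn, frequencies[k], minlen), call. = FALSE)
        next
      }
      if (is.null(Xf)) Xf <- stats::fft(re$ext)
      M <- re$M
      Mo <- M %/% q * p
      Y <- rep(0 + 0i, Mo)
      h <- min(M, Mo) %/% 2L
      Y[1:h] <- Xf[1:h]
      Y[(Mo - h + 2L):Mo] <- Xf[(M - h + 2L):M]
      a <- acc[[k]]
      if (with_smooth) {
        tr <- modwt_mra_transfers(g, depth, Mo)
        d1 <- tr$details[[1L]]
        a$smooth[[length(a$smooth) + 1L]] <-
          Re(stats::fft(Y * tr$smooth, inverse = TRUE))[seq_len(n_out)] / M
      } else {
        # only the first detail feeds the TI; its transfer needs no cascade
        d1 <- modwt_power_responses(g, Mo)$Q
      }
      a$values[[length(a$values) + 1L]] <-
        Re(stats::fft(Y * d1, inverse = TRUE))[seq_len(n_out)] / M
      a$chunks[[length(a$chunks) + 1L]] <-
        data.frame(start = cs, offset = a$off, n = n_out)
      a$off <- a$off + n_out
      acc[[k]] <- a
    }
  }

  out <- vector("list", length(frequencies))
  names(out) <- names(acc)
  for (k in seq_along(frequencies)) {
    f <- frequencies[k]
    fs_f <- target_rate(f)
    a <- acc[[k]]
    out[[k]] <- structure(list(
      f = f, fs_f = fs_f,
      values = unlist(a$values, use.names = FALSE),
      smooth = unlist(a$smooth, use.names = FALSE),
      chunks = if (length(a$chunks)) do.call(rbind, a$chunks)
               else data.frame(start = numeric(0), offset = integer(0), n = integer(0)),
      band = c(fs_f / 4, fs_f / 2),
      edge = ceiling(minlen / 2),
      wavelet_order = wavelet_order, depth = depth),
      class = "level_series")
  }
  out
}

#' @export
print.level_series <- function(x, ...) {
  cat(sprintf(
    "<level_series> f=%g Hz (band %.2f-%.2f Hz), fs_f=%.4g Hz, %d samples, db%d depth %d\n",
    x$f, x$band[1L], x$band[2L], x$fs_f, length(x$values), x$wavelet_order, x$depth))
  invisible(x)
}

lcm2 <- function(a, b) {
  gcd <- function(x, y) if (y == 0) x else gcd(y, x %% y)
  as.integer(a / gcd(a, b) * b)
}
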