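#' Exact rational ratio between two sampling rates
#'
#' Finds the reduced fraction `p/q` with `fs_out = fs_in * p / q`. Rates that
#' are not related by a small rational ratio are a configuration error: the
#' per-frequency target rates used by the tremor pipeline all reduce to
#' denominators of at most 12 from a 32 Hz device rate.
#'
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @param max_den largest denominator considered (default 64).
#' @return list with integers `p` and `q`.
#' @keywords internal
rational_ratio <- function(fs_in, fs_out, max_den = 64L) {
  r <- fs_out / fs_in
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p >= 1 && abs(p / q - r) < 1e-9) return(list(p = as.integer(p), q = as.integer(q)))
  }
  stop(sprintf("no small rational ratio between rates %g and %g Hz", fs_in, fs_out),
       call. = FALSE)
}

#' Band-limited rational resampling
#'
#' Resamples a signal by the exact rational factor `p/q` in the frequency
#' domain: the input is reflection-extended, transformed, its spectrum
#' truncated (or zero-padded) to the new Nyquist rate, and inverse
#' transformed. This is inherently anti-aliased -- content above the output
#' Nyquist frequency is removed exactly -- and preserves DC and sub-Nyquist
#' sinusoids to within the ringing of the brick-wall cutoff. Transients are
#' confined to the ends of the output (the reflection point and the circular
#' wrap point).
#'
#' @param x numeric vector.
#' @param p,q integers; the output rate is `p/q` times the input rate.
#' @return numeric vector of length `floor(length(x) * p / q)`.
#' @examples
#' fs <- 32; t <- (0:(32 * 10 - 1)) / fs
#' y <- fft_resample(sin(2 * pi * 2 * t), 1, 4)  # 32 Hz -> 8 Hz
#' @export
fft_resample <- function(x, p, q) {
  p <- as.integer(p); q <- as.integer(q)
  if (p < 1 || q < 1) stop("p and q must be positive integers", call. = FALSE)
  if (p == q) return(x)
  n <- length(x)
  re <- reflect_extend(x, mult = q)
  M <- re$M
  Mo <- M %/% q * p
  X <- stats::fft(re$ext)
  Y <- rep(0 + 0i, Mo)
  h <- min(M, Mo) %/% 2L
  Y[1:h] <- X[1:h]
  Y[(Mo - h + 2L):Mo] <- X[(M - h + 2L):M]
  Re(stats::fft(Y, inverse = TRUE))[seq_len(floor(n * p / q))] / M
}

#' Resample an elevation series to a new rate
#'
#' Applies [fft_resample()] chunk-wise, never across a recording gap.
#'
#' @param series an `elevation_series` (see [elevation()]).
#' @param fs_out target sampling rate in Hz; must be an exact small rational
#'   multiple of the series rate and not exceed it.
#' @return an `elevation_series` at rate `fs_out`.
#' @export
resample_series <- function(series, fs_out) {
  stopifnot(inherits(series, "elevation_series"))
  if (fs_out > series$fs + 1e-9) {
    stop("resample_series only lowers the rate", call. = FALSE)
  }
  rr <- rational_ratio(series$fs, fs_out)
  theta <- vector("list", nrow(series$chunks))
  chunks <- series$chunks
  off <- 0L
  for (i in seq_len(nrow(chunks))) {
    xi <- series$theta[chunks$offset[i] + seq_len(chunks$n[i])]
    yi <- fft_resample(xi, rr$p, rr$q)
    theta[[i]] <- yi
    chunks$offset[i] <- off
    chunks$n[i] <- length(yi)
    off <- off + length(yi)
  }
  structure(list(theta = unlist(theta), fs = fs_out, chunks = chunks),
            class = "elevation_series")
}
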