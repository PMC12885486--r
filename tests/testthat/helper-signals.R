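# Shared builders and independent oracles for the test suite.

# recording whose elevation angle is exactly `theta` (az = tan(theta))
rec_from_theta <- function(theta, fs = 32, start_epoch = 0, hand = "unknown") {
  n <- length(theta)
  accel_recording(numeric(n), numeric(n), tan(theta), fs,
                  start_epoch = start_epoch, hand = hand)
}

sinusoid <- function(f, fs, duration_s, amp = 1, phase = 0) {
  t <- (0:(round(fs * duration_s) - 1)) / fs
  amp * sin(2 * pi * f * t + phase)
}

# periodogram band-energy oracle: fraction of energy in (lo, hi] Hz
band_energy_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  fr <- (0:(n - 1)) * fs / n
  half <- fr <= fs / 2
  sum(sp[half & fr > lo & fr <= hi]) / sum(sp[half])
}

# FFT amplitude oracle: peak amplitude near frequency f
fft_amplitude <- function(x, fs, f, tol_hz = 0.2) {
  n <- length(x)
  a <- 2 * Mod(stats::fft(x)) / n
  fr <- (0:(n - 1)) * fs / n
  max(a[fr <= fs / 2 & abs(fr - f) <= tol_hz])
}

# mean TI over valid windows at each frequency of a theta signal
mean_ti_by_frequency <- function(theta, fs = 32, frequencies = 3:12,
                                 st_minutes = 1) {
  rec <- rec_from_theta(theta, fs)
  lv <- levels_for_frequencies(elevation(rec), frequencies, with_smooth = FALSE)
  vapply(lv, function(L) {
    tis <- tremor_index(L, st_minutes = st_minutes)
    mean(valid_ti(tis))
  }, 0)
}

# write a small E4-dialect CSV from raw counts
write_e4_fixture <- function(path, ts, fs, counts) {
  writeLines(c(format(ts, scientific = FALSE), format(fs, scientific = FALSE),
               apply(counts, 1, paste, collapse = ",")), path)
  path
}
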