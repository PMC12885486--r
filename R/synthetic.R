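#' Tremor component table for a simulation profile
#' @param freq tremor frequency in Hz (3-12).
#' @param amp_g acceleration amplitude on the Oz axis in g.
#' @param duty fraction of time in the burst state, in \[0, 1\].
#' @param burst_s mean burst length in seconds.
#' @return data.frame of components.
#' @export
sim_components <- function(freq, amp_g, duty = 0.2, burst_s = 20) {
  stopifnot(all(freq >= 3 & freq <= 12), all(duty >= 0 & duty <= 1),
            all(amp_g >= 0))
  if (length(freq) == 0L) {
    return(data.frame(freq = numeric(0), amp_g = numeric(0),
                      duty = numeric(0), burst_s = numeric(0)))
  }
  data.frame(freq = freq, amp_g = amp_g, duty = duty, burst_s = burst_s)
}

#' Simulation profile for one hand
#'
#' Describes what one wrist's accelerometer sees: a gravity-orientation
#' baseline, a slow (0.1-2 Hz) daily-activity process, intermittent tremor
#' components gated by a two-state burst/quiet process, Gaussian sensor
#' noise, and 1/64 g quantization. During nighttime hours (local 00:00-07:00)
#' activity amplitude and burst duty are scaled down.
#'
#' @param tremor data.frame from [sim_components()]; zero rows for a
#'   tremor-free hand.
#' @param activity_g amplitude (sd) of the slow daily-motion process in g.
#' @param activity_hf_g amplitude of broadband movement noise that
#'   accompanies activity. Real wrists produce 3-12 Hz content during
#'   voluntary movement, so both hands' TI distributions are long-tailed
#'   even without tremor.
#' @param bout_active_s,bout_quiet_s mean lengths (s) of the active and
#'   quiet states of the activity-bout process; daily activity comes in
#'   bouts (cooking, walking, typing) separated by rest, which is what
#'   spreads window-level TI over orders of magnitude.
#' @param noise_sd_g sensor noise standard deviation in g.
#' @param baseline_g constant Oz gravity component in g.
#' @param amp_sd log-scale standard deviation of burst-to-burst tremor
#'   amplitude (tremor waxes and wanes between bursts).
#' @param episode_s,episode_duty tremor occurs in symptomatic episodes
#'   (e.g. medication OFF periods) of mean length `episode_s` seconds
#'   covering `episode_duty` of the time; bursts are drawn only inside
#'   episodes, so most windows carry no tremor and the tremor hand's TI
#'   distribution grows a long tail.
#' @param night_activity,night_duty multiplicative nighttime factors for
#'   activity amplitude and burst duty.
#' @return a `sim_profile` list.
#' @export
sim_profile <- function(tremor = sim_components(numeric(0), numeric(0)),
                        activity_g = 0.05, activity_hf_g = 0.18,
                        bout_active_s = 300, bout_quiet_s = 1200,
                        amp_sd = 0.25, episode_s = 3600, episode_duty = 0.35,
                        noise_sd_g = 0.008, baseline_g = 0.95,
                        night_activity = 0.3, night_duty = 0.3) {
  structure(list(tremor = tremor, activity_g = activity_g,
                 activity_hf_g = activity_hf_g,
                 bout_active_s = bout_active_s, bout_quiet_s = bout_quiet_s,
                 amp_sd = amp_sd, episode_s = episode_s,
                 episode_duty = episode_duty,
                 noise_sd_g = noise_sd_g, baseline_g = baseline_g,
                 night_activity = night_activity, night_duty = night_duty),
            class = "sim_profile")
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  cs <- c(0, cumsum(x))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - 1L - w %/% 2L)
  hi <- pmin(n, seq_len(n) + (w - 1L) %/% 2L)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# per-sample activity intensity: two-state bout process with lognormal
# per-bout intensity and 10 s edge tapers
activity_intensity <- function(n, fs, bout_active_s, bout_quiet_s) {
  duty <- bout_active_s / (bout_active_s + bout_quiet_s)
  bouts <- draw_bursts(n / fs, duty, bout_active_s)
  a <- numeric(n)
  for (b in seq_len(nrow(bouts))) {
    i0 <- max(1L, floor(bouts$start[b] * fs) + 1L)
    i1 <- min(n, ceiling(bouts$end[b] * fs))
    a[i0:i1] <- exp(stats::rnorm(1L, 0, 0.2))
  }
  sm <- moving_average(a, max(1L, round(10 * fs)))
  # intensity fluctuates within a bout (~30 s correlation), so one long bout
  # does not imprint several windows with the same TI
  ar <- exp(-1 / (30 * fs))
  mod <- stats::filter(stats::rnorm(n), ar, method = "recursive")
  mod <- mod / max(stats::sd(mod), 1e-12)
  mod <- pmin(1.5, pmax(-1.5, as.numeric(mod)))
  as.numeric(sm) * exp(0.5 * mod)
}

# band-limited (0.1-2 Hz) unit-sd noise via spectral shaping
slow_activity_process <- function(n, fs) {
  if (n < 8L) return(numeric(n))
  M <- stats::nextn(n, c(2, 3, 5))
  W <- stats::fft(stats::rnorm(M))
  fr <- (0:(M - 1L)) * fs / M
  fr <- pmin(fr, fs - fr)
  mask <- rep(0, M)
  mask[fr >= 0.1 & fr <= 2] <- 1
  ramp <- fr > 0.05 & fr < 0.1
  mask[ramp] <- 0.5 - 0.5 * cos(pi * (fr[ramp] - 0.05) / 0.05)
  roll <- fr > 2 & fr < 2.5
  mask[roll] <- 0.5 + 0.5 * cos(pi * (fr[roll] - 2) / 0.5)
  x <- Re(stats::fft(W * mask, inverse = TRUE))[seq_len(n)] / M
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# quasi-periodic episode schedule: symptomatic episodes recur with the cadence
# of medication cycles, so their total coverage is stable between sessions
draw_episodes <- function(duration_s, duty, episode_s) {
  if (duty <= 0) return(data.frame(start = numeric(0), end = numeric(0)))
  if (duty >= 1) return(data.frame(start = 0, end = duration_s))
  period <- episode_s / duty
  k <- ceiling(duration_s / period) + 1L
  starts <- (seq_len(k) - 1L + stats::runif(k, 0, 0.3)) * period
  lens <- episode_s * exp(pmin(0.3, pmax(-0.3, stats::rnorm(k, 0, 0.15))))
  keep <- starts < duration_s
  data.frame(start = starts[keep], end = pmin(starts[keep] + lens[keep], duration_s))
}

# exponential burst/quiet gating; returns a data.frame of burst intervals (s)
draw_bursts <- function(duration_s, duty, burst_s) {
  if (duty <= 0) return(data.frame(start = numeric(0), end = numeric(0)))
  if (duty >= 1) return(data.frame(start = 0, end = duration_s))
  quiet_s <- burst_s * (1 - duty) / duty
  t <- stats::rexp(1L, 1 / quiet_s)
  starts <- numeric(0); ends <- numeric(0)
  while (t < duration_s) {
    b <- max(1, stats::rexp(1L, 1 / burst_s))
    starts <- c(starts, t); ends <- c(ends, min(t + b, duration_s))
    t <- t + b + stats::rexp(1L, 1 / quiet_s)
  }
  data.frame(start = starts, end = ends)
}

#' Simulate one hand's accelerometer recording
#'
#' Generates an Oz-dominant synthetic recording at the device rate with
#' known ground-truth tremor bursts. Tremor frequency jitters slowly within
#' about +/-0.3 Hz inside a burst, and burst edges are tapered over 0.25 s.
#'
#' @param profile a [sim_profile()].
#' @param start_epoch Unix start time in seconds.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz (default 32).
#' @param tz time zone used for the nighttime rule.
#' @param hand hand label for the recording.
#' @param gaps optional data.frame with `start`/`end` offsets in seconds from
#'   the recording start; those intervals are removed as data gaps.
#' @param seed optional integer seed for reproducibility.
#' @return list with `recording` (an `accel_recording`) and `truth`
#'   (data.frame of kept burst intervals: `freq`, `start`, `end` in Unix
#'   seconds).
#' @export
simulate_hand <- function(profile, start_epoch, duration_s, fs = 32,
                          tz = "UTC", hand = c("T", "nT", "unknown"),
                          gaps = NULL, seed = NULL) {
  stopifnot(inherits(profile, "sim_profile"))
  hand <- match.arg(hand)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  off <- utc_offset(start_epoch, tz)
  sec_local <- (start_epoch + off + (0:(n - 1L)) / fs) %% 86400
  night <- sec_local < 7 * 3600

  bout <- activity_intensity(n, fs, profile$bout_active_s, profile$bout_quiet_s)
  bout[night] <- bout[night] * profile$night_activity
  act <- slow_activity_process(n, fs) * profile$activity_g * bout
  # broadband movement noise while the arm is moving
  hf <- profile$activity_hf_g * bout * stats::rnorm(n)

  az <- profile$baseline_g + act + hf + stats::rnorm(n, 0, profile$noise_sd_g)
  truth <- list()
  tr <- profile$tremor
  episodes <- draw_episodes(duration_s, profile$episode_duty, profile$episode_s)
  shared <- NULL
  for (j in seq_len(nrow(tr))) {
    # components share one burst gating: a tremor episode expresses all of a
    # participant's frequencies at once (amplitude and jitter stay per-component)
    if (is.null(shared)) shared <- draw_bursts(duration_s, tr$duty[j], tr$burst_s[j])
    bursts <- shared
    if (nrow(bursts) > 0L && nrow(episodes) > 0L) {
      in_ep <- vapply(bursts$start, function(s0) {
        any(s0 >= episodes$start & s0 < episodes$end)
      }, TRUE)
      bursts <- bursts[in_ep, , drop = FALSE]
    } else {
      bursts <- bursts[0L, , drop = FALSE]
    }
    if (nrow(bursts) > 0L) {
      # nighttime thinning: drop bursts starting at night with prob 1 - night_duty
      st_loc <- (start_epoch + off + bursts$start) %% 86400
      drop <- st_loc < 7 * 3600 &
        stats::runif(nrow(bursts)) > profile$night_duty
      bursts <- bursts[!drop, , drop = FALSE]
    }
    if (nrow(bursts) == 0L) next
    gate <- numeric(n)
    i0 <- pmax(1L, floor(bursts$start * fs) + 1L)
    i1 <- pmin(n, ceiling(bursts$end * fs))
    for (b in seq_along(i0)) gate[i0[b]:i1[b]] <- 1
    gate <- moving_average(gate, max(1L, round(0.25 * fs)))
    jitter <- stats::filter(stats::rnorm(n), 0.995, method = "recursive")
    jitter <- jitter / max(stats::sd(jitter), 1e-12) * 0.15
    jitter <- pmin(0.3, pmax(-0.3, jitter))
    phase <- 2 * pi * cumsum(tr$freq[j] + jitter) / fs
    # burst-to-burst amplitude variation (tremor waxes and wanes)
    amp <- numeric(n)
    for (b in seq_along(i0)) {
      amp[i0[b]:i1[b]] <- tr$amp_g[j] * exp(stats::rnorm(1L, 0, profile$amp_sd))
    }
    az <- az + amp * as.numeric(gate) * sin(phase)
    truth[[length(truth) + 1L]] <- data.frame(
      freq = tr$freq[j], start = start_epoch + bursts$start,
      end = start_epoch + bursts$end)
  }
  ax <- 0.3 * act + stats::rnorm(n, 0, profile$noise_sd_g)
  ay <- 0.5 * act + stats::rnorm(n, 0, profile$noise_sd_g)

  quant <- function(v) round(v * 64) / 64
  rec <- accel_recording(quant(ax), quant(ay), quant(az), fs,
                         start_epoch = start_epoch, hand = hand)
  if (!is.null(gaps) && nrow(gaps) > 0L) {
    pieces <- list()
    t0 <- start_epoch
    bounds <- rbind(gaps, data.frame(start = duration_s, end = duration_s))
    for (i in seq_len(nrow(bounds))) {
      piece <- window_recording(rec, t0, start_epoch + bounds$start[i])
      if (n_samples(piece) > 0L) pieces[[length(pieces) + 1L]] <- piece
      t0 <- start_epoch + bounds$end[i]
    }
    rec <- stitch(pieces)
  }
  list(recording = rec,
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(freq = numeric(0), start = numeric(0),
                               end = numeric(0)))
}

#' Per-participant tremor design for a synthetic cohort
#'
#' Assigns each participant a tremor breadth (number of affected
#' frequencies, taken centre-out from the rest-tremor band), component
#' amplitudes, and clinical item intensities consistent with the injected
#' tremor: intensities grow monotonically with breadth, so the symptom load
#' L is monotone in the designed breadth.
#'
#' @param n number of participants (>= 3).
#' @param freq_order order in which frequencies are added with breadth.
#' @param amp_g amplitude of the first (strongest) component in g.
#' @param duty burst duty cycle.
#' @param max_breadth largest breadth in the design.
#' @return data.frame with one row per participant (`participant_id`,
#'   `breadth`, `postural`, `kinetic`, `rest`, `L`) and a `components`
#'   list-column of [sim_components()] tables.
#' @export
cohort_design <- function(n = 7, freq_order = 5:10,
                          amp_g = 0.3, duty = 0.75, max_breadth = 5) {
  stopifnot(n >= 3)
  breadth <- round(seq(0, max_breadth, length.out = n))
  # intensities ramp quickly with breadth (dominant rest tremor), keeping the
  # symptom load roughly proportional to the number of affected frequencies
  rest <- pmin(4L, 3L * breadth)
  postural <- pmin(4L, breadth)
  kinetic <- pmax(0L, pmin(4L, breadth - 1L))
  comps <- lapply(breadth, function(b) {
    if (b == 0) sim_components(numeric(0), numeric(0))
    else sim_components(freq_order[seq_len(b)], amp_g * 0.95^(seq_len(b) - 1L),
                        duty = duty)
  })
  out <- data.frame(participant_id = sprintf("P%02d", seq_len(n)),
                    breadth = breadth, postural = postural,
                    kinetic = kinetic, rest = rest,
                    L = symptom_load(postural, kinetic, rest))
  out$components <- comps
  out
}

#' Simulate a two-hand cohort with ground truth
#'
#' Emulates the study design: each participant wears the device on the most
#' tremor-affected hand first, then on the least affected hand
#' (asynchronous wear), with tremor injected only in the T hand according to
#' the cohort design. Everything is seedable and the clinical table is
#' consistent with the injected tremor. Cohort participants follow a
#' persistent-tremor phenotype -- sustained tremor inside symptomatic
#' episodes with steady amplitude -- which is the regime in which the
#' second-peak separation statistic is informative; activity bouts are
#' sparse enough that the rest peak stays the distribution's mode.
#'
#' @param design a [cohort_design()] data.frame.
#' @param start_epoch Unix start of the first wear period.
#' @param hours_per_hand recording length per session in hours.
#' @param days_per_hand number of daily sessions per hand; sessions are a
#'   day apart and pooled by the analysis, mirroring multi-day wear.
#' @param fs sampling rate in Hz.
#' @param tz time zone.
#' @param seed integer seed.
#' @return list with `participants` (per id: `T`, `nT` recordings and
#'   `truth`), `clinical` (per-participant scores and load for the T hand),
#'   and `design`.
#' @export
simulate_cohort <- function(design = cohort_design(), start_epoch = 1722470400,
                            hours_per_hand = 24, days_per_hand = 1, fs = 32,
                            tz = "UTC", seed = 1) {
  set.seed(seed)
  dur <- hours_per_hand * 3600
  wear <- function(profile, first_epoch, hand) {
    sims <- lapply(seq_len(days_per_hand), function(d) {
      simulate_hand(profile, first_epoch + (d - 1) * 86400, dur, fs, tz,
                    hand = hand)
    })
    list(recording = stitch(lapply(sims, `[[`, "recording")),
         truth = do.call(rbind, lapply(sims, `[[`, "truth")))
  }
  participants <- list()
  for (i in seq_len(nrow(design))) {
    prof_T <- sim_profile(tremor = design$components[[i]], amp_sd = 0.05,
                          episode_duty = 0.45, episode_s = 900)
    prof_nT <- sim_profile()
    sim_T <- wear(prof_T, start_epoch, "T")
    sim_nT <- wear(prof_nT, start_epoch + days_per_hand * 86400, "nT")
    participants[[design$participant_id[i]]] <-
      list(T = sim_T$recording, nT = sim_nT$recording, truth = sim_T$truth,
           expected_freqs = design$components[[i]]$freq)
  }
  clinical <- design[, c("participant_id", "postural", "kinetic", "rest", "L")]
  clinical$hand <- "T"
  list(participants = participants, clinical = clinical, design = design)
}
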