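# build a level_series directly so TI arithmetic is tested in isolation
fake_level <- function(values, f = 12, start = 0, chunks = NULL) {
  fs_f <- target_rate(f)
  if (is.null(chunks)) {
    chunks <- data.frame(start = start, offset = 0L, n = length(values))
  }
  structure(list(f = f, fs_f = fs_f, values = values, smooth = NULL,
                 chunks = chunks, band = c(fs_f / 4, fs_f / 2),
                 edge = 53L, wavelet_order = 4, depth = 4),
            class = "level_series")
}

test_that("TI evaluates the windowed energy sum exactly", {
  # all-zero level
  ti0 <- tremor_index(fake_level(numeric(32 * 1800)), 15, 1e4)
  expect_equal(valid_ti(ti0), rep(0, 2))
  # constant level 1e-3 rad at f=12, ST 15 min: 1e4 * 28800 * 1e-6 = 288 tiu
  tic <- tremor_index(fake_level(rep(1e-3, 32 * 2700)), 15, 1e4)
  expect_equal(valid_ti(tic), rep(288, 3))
})

test_that("TI matches a brute-force sum oracle on random windows", {
  set.seed(21)
  v <- rnorm(32 * 3600, sd = 1e-3)
  tis <- tremor_index(fake_level(v), st_minutes = 15, beta = 1e4)
  for (k in seq_len(nrow(tis))) {
    if (!tis$valid[k]) next
    idx <- (tis$window_start[k] * 32 + 1):((tis$window_start[k] + 900) * 32)
    expect_equal(tis$ti[k], 1e4 * sum(v[idx]^2), tolerance = 1e-12)
  }
})

test_that("TI is quadratic in level amplitude and linear in beta", {
  v <- sinusoid(12, 32, 3600, amp = 2e-3)
  t1 <- valid_ti(tremor_index(fake_level(v), 15, 1e4))
  t2 <- valid_ti(tremor_index(fake_level(2 * v), 15, 1e4))
  expect_equal(t2 / t1, rep(4, length(t1)), tolerance = 0.05)
  tb <- valid_ti(tremor_index(fake_level(v), 15, 2e4))
  expect_equal(tb, 2 * t1, tolerance = 1e-12)
})

test_that("windows align to wall-clock quarter hours in the local zone", {
  tz <- "Europe/Oslo"                      # UTC+2 in June
  start <- as.numeric(as.POSIXct("2024-06-10 10:07:00", tz = tz))
  tis <- tremor_index(fake_level(rep(1e-3, 32 * 3600), start = start),
                      15, 1e4, tz = tz)
  lt <- as.POSIXlt(as.POSIXct(tis$window_start, origin = "1970-01-01",
                              tz = "UTC"), tz = tz)
  expect_true(all(lt$min %% 15 == 0 & lt$sec == 0))
  # first and last windows are partial, middle ones valid
  expect_equal(sum(tis$valid), 3)
})

test_that("a window longer than the data invalidates everything with a warning", {
  expect_warning(tis <- tremor_index(fake_level(rnorm(320)), 15, 1e4),
                 "exceeds every chunk")
  expect_true(all(!tis$valid))
  expect_true(all(is.na(tis$ti)))
})

test_that("windows overlapping a gap are invalid; others are untouched", {
  v <- rep(1e-3, 32 * 86400)
  m <- 1718150400                           # 2024-06-12 00:00 UTC
  # gap 10:00:00-10:30:00 expressed as two chunks
  n1 <- 32 * 36000
  ch <- data.frame(start = c(m, m + 37800), offset = c(0L, n1),
                   n = c(n1, 32 * (86400 - 37800)))
  lv <- fake_level(v[seq_len(sum(ch$n))], chunks = ch, start = m)
  tis <- tremor_index(lv, 15, 1e4, span = c(m, m + 86400))
  expect_equal(nrow(tis), 96)
  expect_equal(which(!tis$valid), c(41, 42))   # 10:00 and 10:15 windows
})

test_that("the invalidate edge policy drops boundary windows only", {
  v <- rep(1e-3, 32 * 7200)
  tis_i <- tremor_index(fake_level(v), 15, 1e4, edge_policy = "invalidate")
  tis_d <- tremor_index(fake_level(v), 15, 1e4)
  expect_equal(sum(tis_d$valid) - sum(tis_i$valid), 2)
})

test_that("ti_profile covers each kept day with st-minute windows at all frequencies", {
  m <- as.numeric(as.POSIXct("2024-03-04", tz = "UTC"))
  day <- simulate_hand(sim_profile(), m, 86400, seed = 31)
  cfg <- ti_run_config(frequencies = c(3, 12))
  pr <- ti_profile(day$recording, cfg)
  expect_named(pr, c("f3", "f12"))
  expect_equal(vapply(pr, nrow, 0), c(f3 = 96, f12 = 96))
  expect_true(all(pr$f3$valid))
  expect_gte(min(pr$f3$ti), 0)
  # determinism
  pr2 <- ti_profile(day$recording, cfg)
  expect_identical(pr, pr2)
  # empty input
  empty <- filter_segments(segment_days(window_recording(day$recording, m, m + 60),
                                        "UTC"))
  expect_length(ti_profile(day$recording, cfg, segments = empty), 0)
})
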