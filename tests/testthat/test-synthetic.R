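m0 <- as.numeric(as.POSIXct("2024-03-04 09:00:00", tz = "UTC"))

test_that("simulation is deterministic under a seed and varies across seeds", {
  prof <- sim_profile(tremor = sim_components(5, 0.2))
  a <- simulate_hand(prof, m0, 600, seed = 1)
  b <- simulate_hand(prof, m0, 600, seed = 1)
  c <- simulate_hand(prof, m0, 600, seed = 2)
  expect_identical(a$recording$az, b$recording$az)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$recording$az, c$recording$az))
})

test_that("a zero-amplitude profile is baseline plus noise, quantized to 1/64 g", {
  sim <- simulate_hand(sim_profile(activity_g = 0, activity_hf_g = 0,
                                   noise_sd_g = 0.01),
                       m0, 300, seed = 3)
  az <- sim$recording$az
  expect_equal(mean(az), 0.95, tolerance = 0.01)
  expect_lt(sd(az), 0.02)
  expect_true(all(abs(az * 64 - round(az * 64)) < 1e-9))
  expect_equal(nrow(sim$truth), 0)
})

test_that("the injected tone dominates the periodogram during bursts", {
  prof <- sim_profile(tremor = sim_components(5, 0.3, duty = 0.3, burst_s = 30),
                      activity_g = 0.02, activity_hf_g = 0.02,
                      episode_duty = 1)
  sim <- simulate_hand(prof, m0, 1200, seed = 4)
  expect_gt(nrow(sim$truth), 0)
  b <- sim$truth[which.max(sim$truth$end - sim$truth$start), ]
  i0 <- round((b$start - m0) * 32) + 1
  i1 <- round((b$end - m0) * 32)
  seg <- sim$recording$az[i0:i1] - mean(sim$recording$az[i0:i1])
  sp <- Mod(fft(seg))^2
  fr <- (0:(length(seg) - 1)) * 32 / length(seg)
  peak <- fr[fr > 2.5 & fr <= 16][which.max(sp[fr > 2.5 & fr <= 16])]
  expect_true(peak >= 4 && peak <= 6)
})

test_that("gap schedules remove samples and produce recorded gaps", {
  gaps <- data.frame(start = 100, end = 160)
  sim <- simulate_hand(sim_profile(), m0, 300, gaps = gaps, seed = 5)
  expect_equal(n_samples(sim$recording), (300 - 60) * 32)
  g <- recording_gaps(sim$recording)
  expect_equal(g$start, m0 + 100)
  expect_equal(g$end, m0 + 160)
})

test_that("recordings round-trip through the E4 writer and reader", {
  sim <- simulate_hand(sim_profile(), m0, 3600, seed = 6)
  d <- withr::local_tempdir()
  paths <- write_e4_session(sim$recording, d)
  expect_length(paths, 1)
  back <- read_e4_session(d)
  expect_equal(n_samples(back), 3600 * 32)
  expect_equal(recording_end(back) - back$chunks$start[1], 3600)
  expect_identical(back$az, sim$recording$az)
})

test_that("cohort design scales breadth and load monotonically", {
  des <- cohort_design(7)
  expect_equal(nrow(des), 7)
  expect_true(!is.unsorted(des$breadth))
  expect_true(!is.unsorted(des$L))
  expect_equal(des$breadth[1], 0)
  expect_equal(vapply(des$components, nrow, 0L), des$breadth)
  expect_true(all(des$L >= 0 & des$L <= 36))
})

test_that("multi-day cohort wear pools sessions a day apart", {
  des <- cohort_design(3, max_breadth = 2)
  cohort <- simulate_cohort(des, start_epoch = m0, hours_per_hand = 0.5,
                            days_per_hand = 2, seed = 9)
  rec <- cohort$participants$P01$T
  expect_equal(nrow(rec$chunks), 2)
  expect_equal(diff(rec$chunks$start), 86400)
})

test_that("a minimal cohort runs end to end and returns finite statistics", {
  des <- cohort_design(3, max_breadth = 4)
  cohort <- simulate_cohort(des, start_epoch = m0, hours_per_hand = 0.75,
                            seed = 7)
  expect_named(cohort$participants, c("P01", "P02", "P03"))
  expect_equal(cohort$participants$P01$T$hand, "T")
  expect_equal(cohort$clinical$L, des$L)
  cfg <- ti_run_config(frequencies = c(5, 6), st_minutes = 1.5,
                       missing_threshold = 1)
  res <- cohort_separation(cohort, cfg)
  expect_equal(nrow(res$per_participant), 3)
  expect_true(all(is.finite(res$per_participant$C)))
  if (!is.null(res$association)) {
    expect_true(is.finite(res$association$pearson_r))
  }
})
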