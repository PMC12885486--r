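test_that("the binned PDF normalises counts over a linear [0, max] grid", {
  pdf <- ti_histogram(c(1, 1, 1, 3), nbins = 2)
  expect_equal(pdf$edges, c(0, 1.5, 3))
  expect_equal(pdf$probabilities, c(0.75, 0.25))
  expect_equal(pdf$n, 4)
  # normalisation for arbitrary input
  set.seed(5)
  v <- rexp(500)
  expect_equal(sum(ti_histogram(v)$probabilities), 1, tolerance = 1e-12)
  expect_true(all(diff(ti_histogram(v)$edges) > 0))
  # degenerate inputs
  expect_error(ti_histogram(numeric(0)), "no TI values")
  expect_error(ti_histogram(c(1, NA)), "finite")
  expect_equal(ti_histogram(rep(2, 10), 20)$probabilities[20], 1)
  expect_equal(sum(ti_histogram(rep(0, 10), 20)$probabilities > 0), 1)
})

test_that("uniform draws fill 20 bins evenly (sampling oracle)", {
  set.seed(6)
  pdf <- ti_histogram(runif(1e4), nbins = 20)
  expect_true(all(abs(pdf$probabilities - 0.05) < 0.02))
})

test_that("log-log regression recovers exact power laws", {
  centers_pdf <- ti_histogram(seq(0.5, 19.5, by = 1) + 0.001, nbins = 20,
                              ti_max = 20)
  # overwrite probabilities with an exact p ~ center^-2 law
  p <- centers_pdf$centers^-2
  centers_pdf$probabilities <- p / sum(p)
  fit <- loglog_regression(centers_pdf)
  expect_equal(fit$slope, -2, tolerance = 1e-9)
  expect_gt(fit$r_squared, 1 - 1e-12)
  # flat distribution: slope 0
  centers_pdf$probabilities <- rep(1 / 20, 20)
  expect_equal(loglog_regression(centers_pdf)$slope, 0, tolerance = 1e-12)
  # fewer than 2 usable bins
  centers_pdf$probabilities <- c(1, rep(0, 19))
  expect_error(loglog_regression(centers_pdf), "degenerate fit")
})

test_that("a long-tailed TI mixture gives a negative log-log slope", {
  set.seed(7)
  v <- c(abs(rnorm(900, 0, 2)), rexp(100, 1 / 50))  # rest mass + rare bursts
  expect_lt(loglog_regression(ti_histogram(v))$slope, 0)
})

test_that("shape moments follow known distributions and conventions", {
  set.seed(8)
  z <- rnorm(2e5)
  m <- shape_moments(z)
  expect_equal(m$kurtosis, 3, tolerance = 0.2)     # Pearson: normal -> 3
  expect_equal(m$skewness, 0, tolerance = 0.1)
  e <- rexp(2e5)
  me <- shape_moments(e)
  expect_equal(me$skewness, 2, tolerance = 0.2)
  expect_equal(me$kurtosis, 9, tolerance = 1)
  # symmetric two-point sample: skewness 0, kurtosis 1 (closed form)
  tp <- shape_moments(rep(c(-3, 3), 50))
  expect_equal(tp$skewness, 0)
  expect_equal(tp$kurtosis, 1)
  expect_gte(tp$kurtosis, 1 + tp$skewness^2)        # moment inequality
  expect_error(shape_moments(c(1, 2, 3)), "at least 4")
  expect_error(shape_moments(rep(1, 10)), "zero variance")
})

test_that("distribution_summary tabulates pooled per-hand, per-frequency stats", {
  m <- as.numeric(as.POSIXct("2024-03-04 09:00:00", tz = "UTC"))
  # sparse high-amplitude bursts in the T hand: heavier tail than activity
  pool_two_days <- function(prof, seed, hand) {
    set.seed(seed)
    a <- simulate_hand(prof, m, 5 * 3600, hand = hand)
    b <- simulate_hand(prof, m + 86400, 5 * 3600, hand = hand)
    stitch(list(a$recording, b$recording))
  }
  prof_T <- sim_profile(tremor = sim_components(5, 0.8, duty = 0.08),
                        amp_sd = 0.6)
  cfg <- ti_run_config(frequencies = 5, st_minutes = 3, missing_threshold = 1)
  profs <- list(T = ti_profile(pool_two_days(prof_T, 41, "T"), cfg),
                nT = ti_profile(pool_two_days(sim_profile(), 42, "nT"), cfg))
  tbl <- distribution_summary(profs, nbins = 20)
  expect_equal(nrow(tbl), 2)
  expect_equal(tbl$hand, c("T", "nT"))
  expect_equal(tbl$f_hz, c(5, 5))
  expect_true(all(tbl$n_windows > 150))
  expect_true(all(is.finite(tbl$kurtosis)))
  expect_true(all(is.finite(tbl$slope)))
  # long-tailed PDFs in both hands: decaying log-log fit
  expect_true(all(tbl$slope < 0))
  expect_true(all(tbl$kurtosis >= 1 + tbl$skewness^2))  # moment inequality
})
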