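mk_pdf <- function(probabilities, centers) {
  w <- if (length(centers) > 1) centers[2] - centers[1] else 1
  structure(list(edges = c(centers - w / 2, centers[length(centers)] + w / 2),
                 centers = centers, probabilities = probabilities,
                 counts = probabilities * 100, n = 100,
                 nbins = length(centers)),
            class = "binned_pdf")
}

test_that("second peak is the second-largest bin, ties toward lower TI", {
  expect_equal(second_peak_bin(mk_pdf(c(0.6, 0.3, 0.1), c(1, 3, 5))), 3)
  expect_equal(second_peak_bin(mk_pdf(c(0.3, 0.3, 0.4), c(1, 3, 5))), 1)
  expect_error(second_peak_bin(mk_pdf(c(1, 0, 0), c(1, 3, 5))),
               "fewer than 2 occupied")
})

test_that("hand distance is a log10 difference and antisymmetric", {
  pT <- mk_pdf(c(0.5, 0.1, 0.4), c(5, 10, 15))   # second peak at 15
  pn <- mk_pdf(c(0.5, 0.4, 0.1), c(5, 10, 15))   # second peak at 10
  hd <- hand_distance(pT, pn)
  expect_equal(hd$D_f, log10(15) - log10(10))
  expect_equal(hand_distance(pn, pT)$D_f, -hd$D_f)
  expect_equal(hand_distance(pT, pT)$D_f, 0)
  # explicit log10 example: bins at 10 and 1 tiu
  expect_equal(hand_distance(mk_pdf(c(0.6, 0.4), c(1, 10)),
                             mk_pdf(c(0.4, 0.6), c(1, 10)))$D_f, 1)
  pz <- mk_pdf(c(0.4, 0.6), c(0, 10))   # second peak lands on the zero bin
  expect_error(hand_distance(pz, pz), "log-domain")
  expect_error(hand_distance(pT, mk_pdf(c(0.5, 0.5), c(2, 4))), "shared grid")
})

test_that("separated_count applies the 30%-of-max rule inclusively", {
  d <- data.frame(f = c(5, 6, 9),
                  bin_T = c(40, 50, 10), bin_nT = c(10, 0.5, 10))
  d$D_f <- log10(d$bin_T) - log10(d$bin_nT)
  tm <- c(`5` = 100, `6` = 100, `9` = 100)
  sc <- separated_count(d, tm, rule = "linear")
  # f5 sits exactly at the 30%-of-max boundary ("at least 30%" separates)
  expect_equal(unname(sc$c_f), c(1, 1, 0))
  expect_equal(sc$C, 2)
  expect_equal(sc$threshold_rule, "linear")
  # literal rule compares the log distance itself
  sc2 <- separated_count(d, c(`5` = 2, `6` = 2, `9` = 2), rule = "literal")
  expect_equal(unname(sc2$c_f), c(1, 1, 0))
  # undefined frequencies are excluded with a warning
  d$bin_T[1] <- NA
  expect_warning(sc3 <- separated_count(d, tm), "undefined")
  expect_equal(sc3$C, 1)
})

test_that("symptom load multiplies present types by cumulative intensity", {
  expect_equal(symptom_load(postural = 1, kinetic = 0, rest = 2), 6)
  expect_equal(symptom_load(0, 0, 0), 0)
  expect_equal(symptom_load(4, 4, 4), 36)
  expect_equal(symptom_load(c(1, 0), c(0, 0), c(2, 0)), c(6, 0))
  expect_error(symptom_load(5, 0, 0), "0..4")
  expect_error(symptom_load(1.5, 0, 0), "0..4")
})

test_that("clinical scores round-trip through CSV with computed load", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(participant_id = c("P1", "P2"), hand = "T",
                       postural = c(1, 0), kinetic = c(0, 0), rest = c(2, 4)),
            p, row.names = FALSE)
  sc <- read_clinical_scores(p)
  expect_equal(sc$L, c(6, 4))
  writeLines("a,b\n1,2", p)
  expect_error(read_clinical_scores(p), "columns")
})

test_that("association normalises to 0-10 and handles perfect agreement", {
  C <- c(1, 3, 5, 7, 9)
  L <- C * 3.6                      # identical after normalisation
  a <- associate(C, L, n_freqs = 10)
  expect_equal(a$pearson_r, 1)
  expect_equal(a$mean_diff, 0)
  expect_true(a$ci95[1] <= 0 && a$ci95[2] >= 0)
  # anti-ordered lists give negative correlation
  expect_lt(associate(C, rev(C) * 3, n_freqs = 10)$pearson_r, 0)
  expect_error(associate(c(1, 2), c(1, 2)), "at least 3")
  expect_error(associate(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(associate(1:4, 1:3), "aligned")
})

test_that("separate_hands flags injected tremor frequencies end to end", {
  m <- as.numeric(as.POSIXct("2024-03-04 09:00:00", tz = "UTC"))
  # persistent-phenotype tremor at 5-6 Hz; two pooled daily sessions
  wear <- function(prof, seed, hand) {
    set.seed(seed)
    a <- simulate_hand(prof, m, 3 * 3600, hand = hand)
    b <- simulate_hand(prof, m + 86400, 3 * 3600, hand = hand)
    stitch(list(a$recording, b$recording))
  }
  prof_T <- sim_profile(tremor = sim_components(c(5, 6), c(0.45, 0.4),
                                                duty = 0.75),
                        amp_sd = 0.05, episode_duty = 0.45, episode_s = 900)
  cfg <- ti_run_config(frequencies = c(5, 6, 9, 10), st_minutes = 2,
                       missing_threshold = 1)
  hits <- 0
  for (r in 1:3) {
    sep <- suppressWarnings(
      separate_hands(ti_profile(wear(prof_T, 50 + r, "T"), cfg),
                     ti_profile(wear(sim_profile(), 80 + r, "nT"), cfg),
                     nbins = cfg$nbins, rule = cfg$separation_rule))
    expect_s3_class(sep, "separation_result")
    expect_equal(attr(sep, "C"), sum(sep$c_f, na.rm = TRUE))
    expect_gt(sep$D_f[sep$f == 5], 0)       # tremor hand second peak higher
    hits <- hits + isTRUE(sep$c_f[sep$f == 5] == 1) +
      isTRUE(sep$c_f[sep$f == 6] == 1)
  }
  expect_gte(hits, 4)   # injected frequencies flagged in most sessions
})
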