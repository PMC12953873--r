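test_that("pitch conversions follow concert tuning and equal temperament", {
  expect_equal(hz_to_midi(440), 69)
  expect_equal(hz_to_midi(880), 81)
  expect_equal(hz_to_midi(261.6256), 60, tolerance = 1e-3)
  expect_error(hz_to_midi(0), "positive")
  expect_equal(midi_to_hz(hz_to_midi(123.4)), 123.4)
  expect_equal(cents_between(69.5, 69), 50)
  expect_equal(cents_between(60, 60), 0)
  expect_equal(pythagorean_comma(), 23.46, tolerance = 5e-3)
})

test_that("gross singing errors are screened at a semitone and 300 ms", {
  sc <- toy_score(10, pitch = 60)
  ev <- generate_unison_performance(
    sc, perf_sim_config(onset_jitter_sd = 0, shared_timing_sd = 0,
                        pitch_jitter_sd = 0, drift_slope = 0,
                        gross_pitch_error_rate = 0,
                        gross_onset_error_rate = 0, tempo = 2))
  ev <- as_event_table(ev)
  # corrupt singer a, event 3: exactly one semitone sharp -> removed
  i_pitch <- which(ev$singer == "a" & ev$event_index == 3)
  ev$f0_hz[i_pitch] <- midi_to_hz(61)
  # event 5 late by 301 ms -> removed; event 7 late by 299 ms -> kept
  ev$onset_s[ev$singer == "a" & ev$event_index == 5] <-
    ev$onset_s[ev$singer == "a" & ev$event_index == 5] + 0.301
  ev$onset_s[ev$singer == "a" & ev$event_index == 7] <-
    ev$onset_s[ev$singer == "a" & ev$event_index == 7] + 0.299
  linked <- link_score(ev, sc)
  res <- remove_gross_errors(linked, reference = "score", tempo = 2)
  gone <- setdiff(paste(linked$singer, linked$event_index),
                  paste(res$events$singer, res$events$event_index))
  expect_setequal(gone, c("a 3", "a 5"))
  expect_equal(res$report$n_removed, 2)
  # a clean stream loses nothing
  clean <- remove_gross_errors(link_score(as_event_table(
    generate_unison_performance(sc, perf_sim_config(
      gross_pitch_error_rate = 0, gross_onset_error_rate = 0))), sc),
    reference = "score", tempo = 2)
  expect_equal(clean$report$n_removed, 0)
})

test_that("every note is removed when gross pitch errors saturate", {
  sc <- toy_score(40, pitch = 60)
  ev <- as_event_table(generate_unison_performance(
    sc, perf_sim_config(pitch_jitter_sd = 0, drift_slope = 0,
                        gross_pitch_error_rate = 1,
                        gross_onset_error_rate = 0, seed = 3)))
  res <- remove_gross_errors(link_score(ev, sc), reference = "score",
                             tempo = 2)
  expect_equal(nrow(res$events), 0)
  expect_equal(res$report$fraction_removed, 1)
})

test_that("drift removal residualizes exactly as ordinary least squares", {
  base <- data.frame(singer = "a", voice = "v", piece = "p",
                     condition = "c", block = 1L, repeat_index = 1L,
                     event_index = 1:3, onset_s = c(0, 1, 2),
                     stringsAsFactors = FALSE)
  base$deviation <- c(0, 0.1, 0.26)
  out <- detrend_pitch(base)
  expect_equal(out$residual_deviation, c(0.01, -0.02, 0.01),
               tolerance = 1e-12)
  # perfectly linear and constant deviations leave zero residuals
  lin <- base
  lin$deviation <- 0.05 + 0.02 * lin$onset_s
  expect_equal(detrend_pitch(lin)$residual_deviation, rep(0, 3))
  const <- base
  const$deviation <- rep(0.3, 3)
  expect_equal(detrend_pitch(const)$residual_deviation, rep(0, 3))
})

test_that("detrending is idempotent on trends and applied exactly once", {
  set.seed(31)
  base <- data.frame(singer = "a", voice = "v", piece = "p",
                     condition = "c", block = 1L, repeat_index = 1L,
                     event_index = 1:30, onset_s = seq(0, 29),
                     deviation = rnorm(30, sd = 0.1),
                     stringsAsFactors = FALSE)
  r1 <- detrend_pitch(base)$residual_deviation
  trended <- base
  trended$deviation <- base$deviation + 0.4 + 0.03 * base$onset_s
  r2 <- detrend_pitch(trended)$residual_deviation
  expect_equal(r1, r2)
  expect_error(detrend_pitch(detrend_pitch(base)), "already")
  degen <- base[1:5, ]
  degen$onset_s <- 2
  expect_error(detrend_pitch(degen), "degenerate")
})

test_that("pair matching joins on score events and rejects duplicates", {
  a <- data.frame(event_index = 1:10, onset_s = 1:10,
                  residual_deviation = rep(0, 10))
  b <- a[-7, ]
  m <- match_pairs(a, a)
  expect_equal(nrow(m), 10)
  expect_equal(nrow(match_pairs(a, b)), 9)
  expect_false(7 %in% match_pairs(a, b)$event_index)
  dup <- rbind(a, a[1, ])
  expect_error(match_pairs(dup, a), "duplicate")
})

test_that("the two pair filters act independently at their thresholds", {
  pairs <- data.frame(event_index = 1:5,
                      onset_a = c(0, 0, 0, 0, 0),
                      onset_b = c(0.010, 0.020, 0.310, 0.400, 0),
                      residual_a = c(0.1, 2.6, 0.2, 3.0, 0),
                      residual_b = rep(0, 5))
  f <- filter_pairs(pairs)
  expect_equal(f$pairs$kept_intonation, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(f$pairs$kept_timing, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(nrow(f$intonation), 3)
  expect_equal(nrow(f$timing), 3)
  # a pair can fail one filter and survive the other
  expect_true(f$pairs$kept_timing[2] && !f$pairs$kept_intonation[2])
  expect_true(f$pairs$kept_intonation[3] && !f$pairs$kept_timing[3])
  oracle <- brute_pair_filter(pairs)
  expect_identical(which(f$pairs$kept_intonation), oracle$intonation)
  expect_identical(which(f$pairs$kept_timing), oracle$timing)
  expect_true(is.finite(f$report$iqr_onset_criterion_s))
})

test_that("accuracy records reduce to hand arithmetic and flag empty sets", {
  pairs <- data.frame(voice = "v", piece = "p", unit = "u",
                      condition = "c", block = 1L, repeat_index = 1L,
                      event_index = 1:2, onset_a = c(0, 1),
                      onset_b = c(0.03, 1.05),
                      residual_a = c(0.10, 0.20), residual_b = c(0, 0))
  f <- filter_pairs(pairs)
  rec <- accuracy_table(f, "piece")
  expect_equal(rec$MAPE, 15)           # mean of 10 and 20 cents
  expect_equal(rec$MOE, 0.04)          # mean of 30 and 50 ms
  expect_equal(rec$LMAPE, -log(0.15))  # fractional-MIDI units inside log
  expect_equal(rec$LMOE, -log(0.04))
  expect_identical(rec$MAPE, brute_mape(pairs$residual_a, pairs$residual_b))
  expect_identical(rec$MOE, brute_moe(pairs$onset_a, pairs$onset_b))
  # identical streams: zero errors, L-values undefined but flagged
  zero <- pairs
  zero$onset_b <- zero$onset_a
  zero$residual_b <- zero$residual_a
  recz <- accuracy_table(filter_pairs(zero), "piece")
  expect_equal(recz$MAPE, 0)
  expect_equal(recz$MOE, 0)
  expect_true(is.na(recz$LMAPE) && is.na(recz$LMOE))
})

test_that("accuracy measures are invariant to common shifts of a pair", {
  set.seed(13)
  pairs <- data.frame(voice = "v", piece = "p", unit = "u",
                      condition = "c", block = 1L, repeat_index = 1L,
                      event_index = 1:50, onset_a = cumsum(runif(50)),
                      residual_a = rnorm(50, sd = 0.1),
                      residual_b = rnorm(50, sd = 0.1))
  pairs$onset_b <- pairs$onset_a + rnorm(50, sd = 0.02)
  rec <- accuracy_table(filter_pairs(pairs), "piece")
  shifted <- pairs
  shifted$onset_a <- shifted$onset_a + 2.5
  shifted$onset_b <- shifted$onset_b + 2.5
  shifted$residual_a <- shifted$residual_a + 0.4
  shifted$residual_b <- shifted$residual_b + 0.4
  rec2 <- accuracy_table(filter_pairs(shifted), "piece")
  expect_equal(rec$MAPE, rec2$MAPE)
  expect_equal(rec$MOE, rec2$MOE)
})

test_that("the full cascade recovers jitter scales from clean synthetic streams", {
  sd_c <- 14.5  # cents
  sd_t <- 0.046 # seconds
  sc <- toy_score(4000, pitch = 60)
  ev <- as_event_table(generate_unison_performance(
    sc, perf_sim_config(onset_jitter_sd = sd_t, pitch_jitter_sd = sd_c,
                        drift_slope = 0.02, gross_pitch_error_rate = 0,
                        gross_onset_error_rate = 0, seed = 17)))
  acc <- compute_accuracy(ev, sc, reference = "score", tempo = 2)
  expect_equal(nrow(acc$piece_table), 1)
  # E[MAPE] = 2 sd_c / sqrt(pi), E[MOE] = 2 sd_t / sqrt(pi)
  n <- acc$piece_table$n_pairs_intonation
  exp_mape <- 2 * sd_c / sqrt(pi)
  exp_moe <- 2 * sd_t / sqrt(pi)
  se_mape <- 100 * stats::sd(abs(acc$pairs$residual_a -
                                   acc$pairs$residual_b)) / sqrt(n)
  expect_lt(abs(acc$piece_table$MAPE - exp_mape), 3 * se_mape)
  se_moe <- stats::sd(abs(acc$pairs$onset_a - acc$pairs$onset_b)) / sqrt(n)
  expect_lt(abs(acc$piece_table$MOE - exp_moe), 3 * se_moe)
})

test_that("unlinked events and missing score lines are reported", {
  sc <- toy_score(5)
  ev <- as_event_table(generate_unison_performance(
    sc, perf_sim_config(gross_pitch_error_rate = 0,
                        gross_onset_error_rate = 0)))
  ev$event_index[1] <- 99
  expect_error(link_score(ev, sc), "without score target")
  expect_error(remove_gross_errors(as_event_table(
    generate_unison_performance(sc, perf_sim_config()))), "linked")
})
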