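test_that("PSTH of a constant-rate train is flat and conserves counts", {
  set.seed(1)
  span <- c(0, 200)
  times <- sort(runif(4000, 0, 200))   # 20 Hz homogeneous
  tr <- spike_train(times, region = "LGN", span_s = span)
  stim <- data.frame(kind = "opto_single", onset_s = seq(5, 195, by = 10))
  sess <- recording_session(list(tr), stimuli = stim, meta = list())
  ps <- compute_psth(sess, "opto_single", bin_ms = 10,
                     window_s = c(-0.5, 0.5))
  expect_lt(abs(mean(ps$rate_hz) - 20), 3 * sqrt(20 / (20 * 1)) )
  # count conservation
  tot <- sum(vapply(stim$onset_s, function(t0)
    sum(times >= t0 - 0.5 & times < t0 + 0.5), 0))
  expect_equal(sum(ps$rate_hz * ps$bin_s * ps$n_trials), tot)
  expect_error(compute_psth(sess, "flash"), "no stimuli")
})

test_that("PSTH mode recovers the generator volley latency", {
  s <- generate_opto_trials(age_profile("P9_11", opto_reliability = 1),
                            stimulus_protocol("opto_single", n_trials = 100),
                            seed = 2)
  ps <- compute_psth(s, "opto_single", region = "LGN",
                     window_s = c(-0.05, 0.1))
  mode_ms <- ps$time_s[which.max(ps$rate_hz)] * 1000
  expect_lt(abs(mode_ms - 21.5), 2.5)
})

test_that("onset latency detects constructed steps exactly", {
  ps <- structure(list(time_s = seq(-0.0995, 0.0995, by = 0.001),
                       rate_hz = rep(2, 200), bin_s = 0.001, n_trials = 100,
                       window_s = c(-0.1, 0.1),
                       baseline_window_s = c(-0.1, 0), region = "LGN"),
                  class = "psth")
  set.seed(3)
  ps$rate_hz <- rpois(200, 2) + 0
  k <- 130  # step at +30 ms
  ps$rate_hz[k:200] <- ps$rate_hz[k:200] + 100
  ol <- onset_latency(ps, smooth_sd_ms = 0)   # raw detector on a clean step
  expect_true(ol$responded)
  expect_equal(ol$latency_ms, (ps$time_s[k]) * 1000)
  # default smoothing shifts a hard step by at most one bin
  expect_lte(abs(onset_latency(ps)$latency_ms - ps$time_s[k] * 1000), 1.001)
  # flat PSTH yields an explicit no-response
  flat <- ps; flat$rate_hz <- rep(2, 200)
  expect_false(onset_latency(flat)$responded)
  # near-zero baseline SD is flagged
  silent <- ps; silent$rate_hz <- c(rep(0, 129), rep(50, 71))
  expect_true(onset_latency(silent)$low_confidence)
})

test_that("reliability equals the hand count of responding trials", {
  s <- generate_opto_trials(age_profile("P9_11", opto_reliability = 0.7),
                            stimulus_protocol("opto_single", n_trials = 80),
                            seed = 4)
  r <- response_reliability(s)
  vc <- get_train(s, "VC")$times_s
  lgn <- get_train(s, "LGN")$times_s
  hand_q <- 0L; hand_r <- 0L
  for (t0 in s$stimuli$onset_s) {
    if (any(vc > t0 & vc <= t0 + 0.03)) {
      hand_q <- hand_q + 1L
      if (any(lgn > t0 + 0.001 & lgn <= t0 + 0.1)) hand_r <- hand_r + 1L
    }
  }
  expect_equal(r$n_qualifying, hand_q)
  expect_equal(r$n_responding, hand_r)
  expect_equal(r$reliability_pct, 100 * hand_r / hand_q)
})

test_that("reliability estimates track the generator's Bernoulli rate", {
  s <- generate_opto_trials(age_profile("P9_11", opto_reliability = 0.9),
                            stimulus_protocol("opto_single", n_trials = 200,
                                              inter_trial_s = 2), seed = 5)
  r <- response_reliability(s)
  ci <- 1.96 * sqrt(0.9 * 0.1 / r$n_qualifying) * 100
  expect_lt(abs(r$reliability_pct - 90), ci + 1)  # +1% chance-spike allowance
  # developmental ordering is recovered
  lo <- response_reliability(generate_opto_trials(
    age_profile("P5_7"), stimulus_protocol("opto_single", n_trials = 100),
    seed = 6))
  hi <- response_reliability(generate_opto_trials(
    age_profile("P13_14"), stimulus_protocol("opto_single", n_trials = 100),
    seed = 6))
  expect_lt(lo$reliability_pct, hi$reliability_pct)
})

test_that("window rate change is zero on the baseline and guards zeros", {
  ps <- structure(list(time_s = seq(-0.0995, 0.2995, by = 0.001),
                       rate_hz = rep(10, 400), bin_s = 0.001, n_trials = 10,
                       window_s = c(-0.1, 0.3),
                       baseline_window_s = c(-0.1, 0), region = "LGN"),
                  class = "psth")
  expect_equal(window_rate_change(ps, c(-0.1, 0)), 0)
  expect_equal(window_rate_change(ps, c(0.1, 0.25)), 0)
  zero <- ps; zero$rate_hz <- rep(0, 400)
  expect_error(window_rate_change(zero, c(0.1, 0.25)), "baseline")
})

test_that("primary/secondary split respects windows and trial spans", {
  s <- generate_evoked_trials(age_profile("P9_11"),
                              stimulus_protocol("flash", n_trials = 12),
                              seed = 7)
  expect_error(split_primary_secondary(s, secondary_s = c(0.2, 40)),
               "span|window")
  sp <- split_primary_secondary(s)
  expect_equal(dim(sp$primary$trial_counts)[2], 300L)
  # empty window on a silent recording gives a zero-rate sub-PSTH
  quiet <- spike_train(c(0.0105, 0.0115), region = "LGN", span_s = c(0, 60))
  sq <- recording_session(list(quiet),
                          stimuli = data.frame(kind = "flash",
                                               onset_s = c(0, 30)),
                          meta = list())
  spq <- split_primary_secondary(sq)
  expect_equal(spq$secondary$rate_hz, 0)
})

test_that("evoked spectra separate gamma and spindle bands", {
  s <- generate_evoked_trials(age_profile("P9_11"),
                              stimulus_protocol("flash", n_trials = 20),
                              seed = 8)
  sp <- split_primary_secondary(s)
  p1 <- peak_frequency(evoked_spectrum(sp$primary$trial_counts), c(5, 55))
  p2 <- peak_frequency(evoked_spectrum(sp$secondary$trial_counts), c(5, 55))
  expect_gte(p1$f_peak_hz, 30); expect_lte(p1$f_peak_hz, 50)
  expect_gte(p2$f_peak_hz, 8);  expect_lte(p2$f_peak_hz, 30)
})

test_that("entrainment requires a train protocol and tracks suppression", {
  single <- generate_opto_trials(age_profile("P9_11"),
                                 stimulus_protocol("opto_single",
                                                   n_trials = 5), seed = 9)
  expect_error(entrainment_index(single), "opto_train")
  tr_proto <- stimulus_protocol("opto_train", n_trials = 30,
                                train_freq_hz = 20, train_n_pulses = 5)
  young <- entrainment_index(generate_opto_trials(age_profile("P9_11"),
                                                  tr_proto, seed = 10))
  old <- entrainment_index(generate_opto_trials(age_profile("P13_14"),
                                                tr_proto, seed = 10))
  expect_true(young$entrained)
  expect_lt(abs(young$psth_peak_hz - 20), young$freq_bin_hz + 1e-9)
  expect_false(old$entrained)
  expect_lt(mean(old$pulse_prob[3:5]), 0.5 * old$pulse_prob[1])
})
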