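mk_train <- function(times, span = NULL) {
  if (is.null(span)) span <- c(0, max(times, 1) + 1)
  spike_train(times, region = "LGN", span_s = span)
}

test_that("event detection follows the inter-spike-interval rule", {
  ev <- detect_events(mk_train(c(0, 0.3, 0.6, 2.0), span = c(0, 3)))
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$events$start_s, 0)
  expect_equal(ev$events$stop_s, 0.6)
  expect_equal(ev$events$n_spikes, 3L)
  # isolated spikes and supra-threshold intervals yield nothing
  ev2 <- detect_events(mk_train(seq(0, 6, by = 0.6), span = c(0, 7)))
  expect_equal(nrow(ev2$events), 0L)
  # ties at exactly the threshold break the run (strict inequality)
  ev3 <- detect_events(mk_train(c(0, 0.5, 1.0), span = c(0, 2)))
  expect_equal(nrow(ev3$events), 0L)
  expect_equal(nrow(detect_events(mk_train(numeric(), span = c(0, 1)))$events),
               0L)
})

test_that("event detection matches the brute-force oracle on random trains", {
  set.seed(42)
  for (i in 1:300) {
    n <- rpois(1, 30)
    times <- random_spike_train(n, span = 8)
    thr <- sample(c(0.1, 0.25, 0.5), 1)
    got <- detect_events(mk_train(times, span = c(0, 8)),
                         iei_threshold_s = thr)$events
    want <- brute_force_events(times, thr = thr)
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$stop_s, want$stop_s)
    expect_equal(got$n_spikes, want$n_spikes)
  }
})

test_that("continuity is event time over span", {
  ev <- detect_events(mk_train(c(0, 15, 30), span = c(0, 60)),
                      iei_threshold_s = 20)
  expect_equal(compute_continuity(ev)$continuity, 0.5)
  empty <- detect_events(mk_train(numeric(), span = c(0, 10)))
  expect_equal(compute_continuity(empty)$continuity, 0)
  bad <- empty
  bad$span_s <- c(1, 1)
  expect_error(compute_continuity(bad), "span")
})

test_that("continuity tracks the generator's active fraction", {
  s <- generate_wave_recording(age_profile("P9_11"),
                               wave_params(duration_s = 600,
                                           wave_rate_hz = 150, seed = 77))
  ap <- s$meta$log$active_periods
  frac <- sum(ap$stop_s - ap$start_s) / 600
  cont <- compute_continuity(detect_events(get_train(s, "LGN")))$continuity
  expect_lt(abs(cont - frac), 0.05)
})

test_that("continuity is invariant to time translation", {
  times <- c(0.5, 0.7, 1.0, 4.0, 4.2)
  a <- compute_continuity(detect_events(mk_train(times, span = c(0, 10))))
  b <- compute_continuity(detect_events(mk_train(times + 100,
                                                 span = c(100, 110))))
  expect_equal(a$continuity, b$continuity)
})

test_that("event time adds across concatenated recordings", {
  t1 <- c(1, 1.2, 1.4)
  t2 <- c(2, 2.3)
  a <- compute_continuity(detect_events(mk_train(t1, span = c(0, 5))))
  b <- compute_continuity(detect_events(mk_train(t2 + 5, span = c(5, 10))))
  ab <- compute_continuity(detect_events(mk_train(c(t1, t2 + 5),
                                                  span = c(0, 10))))
  expect_equal(ab$total_event_time_s,
               a$total_event_time_s + b$total_event_time_s)
})

test_that("duration distributions expose the CDF and long-event bins", {
  ev <- detect_events(mk_train(c(0, 0.2, 1, 2, 2.1, 3, 4, 4.3, 4.4, 7.5),
                               span = c(0, 10)), iei_threshold_s = 0.45)
  d <- event_duration_distribution(ev)
  expect_equal(sort(d$durations_s), sort(ev$events$duration_s))
  expect_equal(d$ecdf(2), mean(ev$events$duration_s <= 2))
  expect_true(any(d$histogram$lo_s == 5))   # >5 s bin present
  expect_true(any(d$histogram$lo_s == 10))  # >10 s bin present
  # oracle CDF from sorting
  set.seed(1)
  durs <- runif(50, 0, 12)
  evs <- list(events = data.frame(duration_s = durs), span_s = c(0, 100))
  dd <- event_duration_distribution(evs)
  for (q in c(0.5, 2, 5, 11))
    expect_equal(dd$ecdf(q), mean(sort(durs) <= q))
  # degenerate and empty cases
  evd <- list(events = data.frame(duration_s = rep(2, 5)), span_s = c(0, 50))
  expect_equal(event_duration_distribution(evd)$ecdf(2), 1)
  e0 <- detect_events(mk_train(numeric(), span = c(0, 1)))
  expect_true(event_duration_distribution(e0)$empty)
})

test_that("percent change is plain signed arithmetic with guarded pre", {
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(10, 2), -80)
  expect_equal(percent_change(10, 0), -100)
  expect_equal(percent_change(10, 15), 50)
  expect_error(percent_change(0, 5), "pre")
})
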