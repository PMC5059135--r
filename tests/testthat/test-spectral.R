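test_that("DPSS tapers are orthonormal and concentration-ordered", {
  tap <- wavegate:::dpss_tapers(256, 3, 5)
  gram <- crossprod(tap)
  expect_lt(max(abs(gram - diag(5))), 1e-8)
  # first taper is bell-shaped: no sign changes
  expect_true(all(tap[, 1] > 0))
})

test_that("homogeneous Poisson spectra are flat under the null", {
  # a Poisson count spectrum is flat, so the null check runs without 1/f
  # compensation (compensation deliberately tilts spectra by f)
  par_nc <- spectral_params(comp_one_over_f = FALSE)
  for (seed in 1:8) {
    tr <- simulate_oscillatory_train(40, 23, 0, 60, seed = seed)
    s <- analyze_spectrum(bin_spike_train(tr), par_nc)
    sel <- s$freq_hz >= 5 & s$freq_hz <= 55
    expect_lt(max(s$power[sel]), 3 * median(s$power[sel]))
    expect_true(peak_frequency(s)$low_confidence)
  }
})

test_that("sinusoidal rate modulation is recovered at the right frequency", {
  s <- analyze_spectrum(bin_spike_train(
    simulate_oscillatory_train(40, 23, 0.8, 100, seed = 12)))
  pk <- peak_frequency(s)
  expect_lt(abs(log(pk$f_peak_hz) - log(23)), log_grid_step() + 1e-12)
  expect_false(pk$low_confidence)
})

test_that("peak location is invariant to splitting the train", {
  tr <- simulate_oscillatory_train(60, 20, 0.8, 80, seed = 13)
  full <- peak_frequency(analyze_spectrum(bin_spike_train(tr)))
  half1 <- tr; half1$times_s <- tr$times_s[c(TRUE, FALSE)]
  half2 <- tr; half2$times_s <- tr$times_s[c(FALSE, TRUE)]
  for (h in list(half1, half2)) {
    pk <- peak_frequency(analyze_spectrum(bin_spike_train(h)))
    expect_lt(abs(log(pk$f_peak_hz) - log(full$f_peak_hz)),
              log_grid_step() + 1e-12)
  }
})

test_that("multitaper spectrum localizes a pure sinusoid", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  set.seed(3)
  x <- sin(2 * pi * 20 * t) + rnorm(length(t), sd = 0.1)
  s <- lfp_multitaper_spectrum(x, fs_hz = fs)
  expect_equal(s$freq_hz[2] - s$freq_hz[1], 0.5)  # 2 s window resolution
  expect_equal(s$freq_hz[which.max(s$power)], 20)
  expect_equal(s$n_windows, 10L)
  expect_error(lfp_multitaper_spectrum(x[1:100], fs_hz = fs), "window")
})

test_that("1/f compensation tilts white noise up and is invertible", {
  set.seed(4)
  s <- lfp_multitaper_spectrum(rnorm(20000), fs_hz = 1000)
  cs <- compensate_one_over_f(s)
  sel <- cs$freq_hz > 1
  fit <- coef(lm(cs$power[sel] ~ cs$freq_hz[sel]))
  expect_gt(fit[2], 0)                      # increasing with frequency
  expect_equal(cs$power[cs$freq_hz == 0], 0)
  rt <- uncompensate_one_over_f(cs)
  expect_equal(rt$power[rt$freq_hz > 0], s$power[s$freq_hz > 0])
  expect_error(compensate_one_over_f(cs), "already")
  # power proportional to 1/f becomes flat
  inv <- wavegate:::new_spectrum(1:100, 1 / (1:100))
  flat <- compensate_one_over_f(inv)
  expect_equal(unique(round(flat$power, 12)), 1)
})

test_that("log resampling preserves flat spectra and peak locations", {
  s <- wavegate:::new_spectrum(seq(0, 500, by = 0.5), rep(2, 1001))
  r <- log_resample_spectrum(s)
  expect_equal(unique(r$power), 2)
  expect_true(r$flags$resampled)
  # grid equal to native bins is the identity
  s2 <- wavegate:::new_spectrum(1:100, runif(100))
  r2 <- log_resample_spectrum(s2, grid = 5:50)
  expect_equal(r2$power, s2$power[5:50])
  expect_error(log_resample_spectrum(s2, grid = c(0.5, 10)), "outside")
  expect_error(log_resample_spectrum(s2, grid = c(10, 5)), "increasing")
  # narrow peak lands on the nearest log-grid bin (dense-interp oracle)
  pk <- wavegate:::new_spectrum(seq(0, 100, by = 0.5),
                                stats::dnorm(seq(0, 100, by = 0.5), 16, 0.4))
  rp <- log_resample_spectrum(pk)
  dense <- exp(seq(log(2), log(100), length.out = 6000))
  oracle <- dense[which.max(approx(log(pk$freq_hz[-1]), pk$power[-1],
                                   xout = log(dense))$y)]
  got <- rp$freq_hz[which.max(rp$power)]
  expect_lt(abs(log(got) - log(oracle)), log_grid_step() + 1e-12)
})

test_that("normalization fixes in-band mean power at one", {
  set.seed(5)
  for (i in 1:10) {
    s <- wavegate:::new_spectrum(seq(0.5, 100, by = 0.5), rexp(200) + 0.01)
    ns <- normalize_spectrum(s)
    sel <- ns$freq_hz >= 2 & ns$freq_hz <= 55
    expect_lt(abs(mean(ns$power[sel]) - 1), 1e-9)
    # scale invariance
    s10 <- s; s10$power <- s$power * 10
    expect_equal(normalize_spectrum(s10)$power, ns$power)
  }
  cs <- wavegate:::new_spectrum(1:60, rep(7, 60))
  expect_equal(unique(normalize_spectrum(cs)$power), 1)
  zs <- wavegate:::new_spectrum(1:60, rep(0, 60))
  expect_error(normalize_spectrum(zs), "zero")
  # idempotent: renormalizing a normalized spectrum changes nothing
  expect_equal(normalize_spectrum(normalize_spectrum(cs))$power,
               normalize_spectrum(cs)$power)
})

test_that("peak extraction breaks ties low and flags flat spectra", {
  s <- wavegate:::new_spectrum(1:60, rep(1, 60))
  s$power[c(15, 25)] <- 5
  pk <- peak_frequency(s)
  expect_equal(pk$f_peak_hz, 15)
  flat <- peak_frequency(wavegate:::new_spectrum(1:60, rep(1, 60)))
  expect_true(flat$low_confidence)
  expect_error(peak_frequency(s, search_band = c(200, 300)), "no frequency")
})

test_that("total spectral power tracks count variance (Parseval)", {
  for (seed in 1:3) {
    tr <- simulate_oscillatory_train(50, 20, 0.6, 60, seed = seed)
    b <- bin_spike_train(tr)
    s <- mua_spectrum_autocorr(b)
    L <- length(s$freq_hz) - 1L
    # mean over the full symmetric grid reconstructs the lag-0 windowed acf
    tot <- (sum(s$power) + sum(s$power[2:L])) / (2 * L)
    expect_lt(abs(tot - var(b$counts) * (length(b$counts) - 1) /
                    length(b$counts)) / tot, 0.05)
  }
})

test_that("all-zero counts yield a flagged empty spectrum", {
  tr <- spike_train(numeric(), region = "LGN", span_s = c(0, 10))
  s <- mua_spectrum_autocorr(bin_spike_train(tr))
  expect_true(s$flags$empty)
  expect_true(all(s$power == 0))
  expect_error(mua_spectrum_autocorr(rep(1, 10), fs_hz = 1000), "shorter")
})

test_that("spectrogram shows a stable ridge and silent columns", {
  tr <- simulate_oscillatory_train(100, 23, 0.8, 30, seed = 14)
  sg <- mua_spectrogram(bin_spike_train(tr))
  sel <- sg$freq_hz >= 10 & sg$freq_hz <= 55
  ridge <- sg$freq_hz[sel][apply(sg$power[sel, ], 2, which.max)]
  expect_gt(mean(abs(ridge - 23) <= 2), 0.9)
  # silent epochs produce near-zero columns
  tr2 <- spike_train(c(1, 1.01, 1.02), region = "LGN", span_s = c(0, 10))
  sg2 <- mua_spectrogram(bin_spike_train(tr2))
  late <- sg2$time_s > 4
  expect_lt(max(sg2$power[, late]), 1e-6 * max(sg2$power))
  # time-averaged spectrogram agrees with the directly computed
  # multitaper spectrum of the smoothed series at the ridge
  avg <- rowMeans(sg$power)
  expect_equal(sg$freq_hz[sel][which.max(avg[sel])], 23, tolerance = 0.1)
})
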