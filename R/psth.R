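#' Trial-aligned peri-stimulus time histogram
#'
#' Aligns spikes on stimulus onsets of the requested kind and returns the
#' trial-averaged rate per bin (counts / (n_trials * bin width), in Hz).
#' For train protocols alignment is on the first pulse of each train. Trials
#' whose window extends beyond the recording span are dropped.
#'
#' @param session a [recording_session()].
#' @param align stimulus kind to align on (`"flash"`, `"opto_single"`,
#'   `"opto_train"`).
#' @param region,channel select the spike train (channel `NULL` = only
#'   train in the region).
#' @param bin_ms bin width (ms).
#' @param window_s length-2 `(pre, post)` around onset (s), pre negative.
#' @param baseline_window_s baseline interval (s) relative to onset; default
#'   the whole pre-stimulus part of the window.
#' @return an object of class `psth`: list with `time_s` (bin centres),
#'   `rate_hz`, `bin_s`, `n_trials`, `window_s`, `baseline_window_s`,
#'   `region`.
#' @export
compute_psth <- function(session, align, region = "LGN", channel = NULL,
                         bin_ms = 1, window_s = c(-0.1, 0.3),
                         baseline_window_s = NULL) {
  stopifnot(window_s[1] < window_s[2])
  tr <- get_train(session, region = region, channel = channel)
  onsets <- session$stimuli$onset_s[session$stimuli$kind == align]
  if ("pulse" %in% names(session$stimuli))
    onsets <- session$stimuli$onset_s[session$stimuli$kind == align &
                                        session$stimuli$pulse == 1L]
  if (!length(onsets)) stop("no stimuli of kind '", align, "' in session")
  onsets <- onsets[onsets + window_s[1] >= tr$span_s[1] &
                     onsets + window_s[2] <= tr$span_s[2]]
  if (!length(onsets)) stop("no complete trials inside the recording span")
  bin_s <- bin_ms / 1000
  edges <- seq(window_s[1], window_s[2], by = bin_s)
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (t0 in onsets) {
    rel <- tr$times_s[tr$times_s >= t0 + window_s[1] &
                        tr$times_s < t0 + window_s[1] + nb * bin_s] - t0
    idx <- floor((rel - window_s[1]) / bin_s) + 1L
    counts <- counts + tabulate(idx, nbins = nb)
  }
  if (is.null(baseline_window_s)) {
    baseline_window_s <- c(window_s[1], min(0, window_s[2]))
  }
  structure(list(time_s = edges[-length(edges)] + bin_s / 2,
                 rate_hz = counts / (length(onsets) * bin_s),
                 bin_s = bin_s, n_trials = length(onsets),
                 window_s = window_s, baseline_window_s = baseline_window_s,
                 region = region),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %s, %d trials, %d bins of %.1f ms over [%g, %g] s\n",
              x$region, x$n_trials, length(x$rate_hz), x$bin_s * 1000,
              x$window_s[1], x$window_s[2]))
  invisible(x)
}

psth_baseline <- function(psth) {
  sel <- psth$time_s >= psth$baseline_window_s[1] &
    psth$time_s < psth$baseline_window_s[2]
  if (!any(sel)) stop("empty baseline window")
  psth$rate_hz[sel]
}

#' Response onset latency from a PSTH
#'
#' The latency is the first post-stimulus bin at which the Gaussian-smoothed
#' PSTH exceeds baseline mean + `k_sd` baseline SDs for at least `min_bins`
#' consecutive bins. A near-zero baseline SD yields a low-confidence flag
#' (the criterion degenerates).
#'
#' @param psth a `psth` from [compute_psth()].
#' @param k_sd criterion in baseline SDs (default 3).
#' @param min_bins persistence requirement (default 3 consecutive bins).
#' @param smooth_sd_ms Gaussian smoothing sd (ms) applied before detection.
#' @return list with `responded`, `latency_ms` (NA when no crossing),
#'   `criterion_hz`, `low_confidence`.
#' @export
onset_latency <- function(psth, k_sd = 3, min_bins = 3, smooth_sd_ms = 0.5) {
  base <- psth_baseline(psth)
  mu <- mean(base)
  sdv <- stats::sd(base)
  low_conf <- !is.finite(sdv) || sdv < 1e-9
  crit <- mu + k_sd * max(sdv, 0) + if (low_conf) 1e-9 else 0
  sm <- as.numeric(gaussian_smooth(psth$rate_hz,
                                   smooth_sd_ms / 1000 / psth$bin_s))
  post <- which(psth$time_s >= 0)
  above <- sm[post] > crit
  run <- 0L
  onset_idx <- NA_integer_
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= min_bins) {
      onset_idx <- post[i - min_bins + 1L]
      break
    }
  }
  if (is.na(onset_idx))
    return(list(responded = FALSE, latency_ms = NA_real_,
                criterion_hz = crit, low_confidence = low_conf))
  list(responded = TRUE,
       latency_ms = psth$time_s[onset_idx] * 1000,
       criterion_hz = crit, low_confidence = low_conf)
}

#' Per-trial response reliability
#'
#' Among trials in which cortex fired (at least one VC spike within 30 ms of
#' the pulse), the fraction in which LGN fired within the excitation window,
#' reported as a percentage.
#'
#' @param session an optogenetic [recording_session()].
#' @param excitation_window_s LGN response window after the pulse (s),
#'   default `(0.001, 0.100)`.
#' @param vc_window_s VC qualification window (s), default `(0, 0.030)`.
#' @return list with `reliability_pct`, `n_qualifying`, `n_responding`.
#' @export
response_reliability <- function(session,
                                 excitation_window_s = c(0.001, 0.100),
                                 vc_window_s = c(0, 0.030)) {
  vc <- get_train(session, region = "VC")
  lgn <- get_train(session, region = "LGN")
  onsets <- session$stimuli$onset_s
  if ("pulse" %in% names(session$stimuli))
    onsets <- session$stimuli$onset_s[session$stimuli$pulse == 1L]
  if (!length(onsets)) stop("session has no stimuli")
  has_spike <- function(times, t0, win)
    any(times > t0 + win[1] & times <= t0 + win[2])
  vc_ok <- vapply(onsets, function(t0) has_spike(vc$times_s, t0, vc_window_s), TRUE)
  if (!any(vc_ok)) stop("no qualifying trials (no VC response in any trial)")
  lgn_ok <- vapply(onsets[vc_ok], function(t0)
    has_spike(lgn$times_s, t0, excitation_window_s), TRUE)
  list(reliability_pct = 100 * mean(lgn_ok),
       n_qualifying = sum(vc_ok), n_responding = sum(lgn_ok))
}

#' Percent rate change in a post-stimulus window
#'
#' `100 * (window mean - baseline mean) / baseline mean` of the PSTH rate.
#' The standard windows are 1-100 ms (excitation) and 100-250 ms
#' (inhibition) after the stimulus.
#'
#' @param psth a `psth`.
#' @param window_s length-2 window (s) relative to stimulus onset.
#' @param baseline_window_s optional override of the PSTH's baseline window.
#' @return percent change (scalar).
#' @export
window_rate_change <- function(psth, window_s,
                               baseline_window_s = NULL) {
  if (!is.null(baseline_window_s)) psth$baseline_window_s <- baseline_window_s
  base <- mean(psth_baseline(psth))
  if (base <= 0) stop("zero baseline rate; percent change undefined")
  sel <- psth$time_s >= window_s[1] & psth$time_s < window_s[2]
  if (!any(sel)) stop("window contains no PSTH bins")
  100 * (mean(psth$rate_hz[sel]) - base) / base
}

#' Split evoked responses into primary and secondary windows
#'
#' Slices each flash trial's spikes into the primary (early-gamma) and
#' secondary (spindle-burst) windows and returns, per window, the mean
#' evoked rate, a sub-PSTH, and the per-trial count series at 1 ms used as
#' input to the 0.3 s evoked spectral window.
#'
#' @param session a flash [recording_session()].
#' @param region spike-train region.
#' @param primary_s,secondary_s windows (s) relative to onset; defaults
#'   0-200 ms and 200-1000 ms.
#' @param spectral_window_s length (s) of the evoked spectral window taken
#'   from the start of each response window (default 0.3).
#' @return list of two lists (`primary`, `secondary`), each with `window_s`,
#'   `rate_hz`, `psth` and `trial_counts` (trials x ms matrix).
#' @export
split_primary_secondary <- function(session, region = "LGN",
                                    primary_s = c(0, 0.2),
                                    secondary_s = c(0.2, 1.0),
                                    spectral_window_s = 0.3) {
  if (primary_s[2] > secondary_s[1] + 1e-12 && primary_s[1] < secondary_s[2])
    if (primary_s[2] > secondary_s[1]) stop("primary and secondary windows overlap")
  tr <- get_train(session, region = region)
  onsets <- session$stimuli$onset_s[session$stimuli$kind == "flash"]
  if (!length(onsets)) stop("no flash stimuli in session")
  if (length(onsets) > 1 &&
      max(primary_s[2], secondary_s[2]) > min(diff(sort(onsets))) + 1e-9)
    stop("response windows exceed the trial span (inter-trial interval)")
  if (any(onsets + secondary_s[2] > tr$span_s[2] + 1e-9))
    onsets <- onsets[onsets + secondary_s[2] <= tr$span_s[2] + 1e-9]
  if (!length(onsets)) stop("response windows exceed the trial span")
  slice <- function(win) {
    full <- compute_psth(session, align = "flash", region = region,
                         bin_ms = 1, window_s = c(min(win[1], 0) - 0.0, win[2]))
    sel <- full$time_s >= win[1] & full$time_s < win[2]
    sub <- full
    sub$time_s <- full$time_s[sel]
    sub$rate_hz <- full$rate_hz[sel]
    sub$window_s <- win
    ns <- round(spectral_window_s * 1000)
    # tile the response window with full spectral windows (zero-padded
    # single window when the response is shorter than one)
    tile_starts <- if (diff(win) >= spectral_window_s)
      seq(win[1], win[2] - spectral_window_s + 1e-9, by = spectral_window_s)
    else win[1]
    grid <- expand.grid(t0 = onsets, w0 = tile_starts)
    tc <- t(mapply(function(t0, w0) {
      hi <- min(win[2], w0 + spectral_window_s)
      rel <- tr$times_s[tr$times_s >= t0 + w0 & tr$times_s < t0 + hi] -
        (t0 + w0)
      tabulate(floor(rel * 1000) + 1L, nbins = ns)
    }, grid$t0, grid$w0))
    attr(tc, "tile") <- match(grid$w0, tile_starts)
    list(window_s = win, rate_hz = mean(sub$rate_hz), psth = sub,
         trial_counts = tc)
  }
  list(primary = slice(primary_s), secondary = slice(secondary_s))
}

#' Evoked spectrum from per-trial count series
#'
#' Multitaper spectrum of the per-trial spike-count series (window = the
#' full series length), averaged across trials, then 1/f-compensated and
#' normalized. Used for the 0.3 s primary/secondary evoked spectral windows.
#' The trial-averaged evoked transient is subtracted (per tile position)
#' before the transform, so the estimate reflects induced oscillatory power
#' rather than the broadband envelope of the response; no rate smoothing is
#' applied (a Gaussian pre-filter attenuates gamma-band power far more than
#' spindle-band power and would bias band comparisons), and 1/f compensation
#' is off by default (a 0.3 s count window has no appreciable 1/f trend, and
#' multiplying the 10 Hz wide multitaper lobe by frequency biases peak
#' locations upward).
#'
#' @param trial_counts trials x ms matrix from [split_primary_secondary()].
#' @param params a [spectral_params()] (`tapers` used).
#' @param normalize apply band normalization?
#' @param compensate apply 1/f compensation?
#' @return a `spectrum_estimate`.
#' @export
evoked_spectrum <- function(trial_counts, params = spectral_params(),
                            normalize = TRUE, compensate = FALSE) {
  stopifnot(is.matrix(trial_counts), nrow(trial_counts) >= 1)
  n <- ncol(trial_counts)
  tile <- attr(trial_counts, "tile") %||% rep(1L, nrow(trial_counts))
  resid <- trial_counts
  for (g in unique(tile)) {
    rows <- tile == g
    if (sum(rows) > 1)
      resid[rows, ] <- sweep(trial_counts[rows, , drop = FALSE], 2,
                             colMeans(trial_counts[rows, , drop = FALSE]))
  }
  tap <- dpss_tapers(n, params$tapers[1], params$tapers[2])
  acc <- 0
  for (i in seq_len(nrow(resid))) {
    x <- as.numeric(resid[i, ])
    acc <- acc + mt_window_spectrum(x - mean(x), tap)
  }
  half <- floor(n / 2) + 1L
  s <- new_spectrum((0:(half - 1L)) * 1000 / n, acc / nrow(trial_counts),
                    n_windows = nrow(trial_counts), source = "MUA")
  if (compensate) s <- compensate_one_over_f(s)
  if (normalize) s <- normalize_spectrum(s, params$norm_band_hz) else s
}

#' Entrainment of LGN by rhythmic cortical stimulation
#'
#' For a pulse-train protocol, computes the probability of an LGN response
#' at each pulse position (response = at least one LGN spike between 1 ms
#' after the pulse and the next pulse time) and the peak frequency of the
#' train-aligned PSTH spectrum. The LGN is called entrained when that peak
#' lies within one frequency bin of the train frequency AND the mean
#' response probability at pulses 3..n is at least half that of pulse 1.
#'
#' @param session an opto-train [recording_session()].
#' @return list with `pulse_prob` (per position), `psth_peak_hz`,
#'   `freq_bin_hz`, `entrained`.
#' @export
entrainment_index <- function(session) {
  proto <- session$meta$protocol
  if (is.null(proto) || !identical(proto$kind, "opto_train"))
    stop("entrainment_index requires an opto_train session")
  f <- proto$train_freq_hz
  np <- proto$train_n_pulses
  lgn <- get_train(session, region = "LGN")
  stim <- session$stimuli
  period <- 1 / f
  prob <- vapply(seq_len(np), function(k) {
    on <- stim$onset_s[stim$pulse == k]
    mean(vapply(on, function(t0)
      any(lgn$times_s > t0 + 0.001 & lgn$times_s <= t0 + period), TRUE))
  }, 0)
  # spectrum of the train-aligned PSTH over the train duration
  ps <- compute_psth(session, align = "opto_train", region = "LGN",
                     bin_ms = 1, window_s = c(-0.05, np * period))
  sel <- ps$time_s >= 0
  x <- ps$rate_hz[sel] - mean(ps$rate_hz[sel])
  n <- length(x)
  pw <- Mod(stats::fft(x)[1:(floor(n / 2) + 1L)])^2
  fr <- (0:floor(n / 2)) / (n * ps$bin_s)
  band <- fr > 2 & fr <= 3 * f
  peak <- fr[band][which.max(pw[band])]
  dfr <- fr[2] - fr[1]
  entr <- abs(peak - f) <= dfr + 1e-9 &&
    mean(prob[3:np]) >= 0.5 * prob[1]
  list(pulse_prob = prob, psth_peak_hz = peak, freq_bin_hz = dfr,
       entrained = entr)
}
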