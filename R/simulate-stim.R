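# Stimulation-session generators: optogenetic cortical pulses and whole-field
# flashes, built as additive rate components on the 1 ms grid then thinned.

add_decay_volley <- function(rate, onset_s, peak_hz, tau_s, dur_s, n) {
  i0 <- floor(onset_s / .sim_dt) + 1L
  i1 <- min(i0 + round(dur_s / .sim_dt) - 1L, n)
  if (i1 < i0 || i0 > n) return(rate)
  tloc <- (seq(i0, i1) - i0) * .sim_dt
  rate[i0:i1] <- rate[i0:i1] + peak_hz * exp(-tloc / tau_s)
  rate
}

# residual LGN rate during the post-stimulus inhibitory window; calibrated so
# the 100-250 ms window change is about -89% at full inhibition
.inhibition_residual <- 0.11
.inhibition_window_s <- c(0.100, 0.250)

#' Simulate LGN/VC responses to optogenetic cortical stimulation
#'
#' Per pulse, a short-latency cortical spike volley (onset about 3.5 ms) is
#' always emitted; an LGN volley of roughly 30 ms duration follows at the
#' profile's corticothalamic latency with Bernoulli probability equal to the
#' profile's reliability. When the profile has feed-forward inhibition
#' (P13-14), LGN firing is suppressed to a small residual during 100-250 ms
#' after each pulse, and a train pulse whose LGN volley would fall inside an
#' earlier pulse's suppression window fails to respond.
#'
#' @param age an [age_profile()].
#' @param protocol a [stimulus_protocol()] of kind `opto_single` or
#'   `opto_train`.
#' @param seed integer seed.
#' @param baseline_hz spontaneous LGN/VC rate (Hz).
#' @param vc_latency_ms cortical volley onset after the light pulse (ms).
#' @param lgn_volley_hz,vc_volley_hz peak volley rates (Hz).
#' @param lgn_volley_dur_s LGN volley duration (s).
#' @return a [recording_session()]; `meta$log$pulses` records, per pulse,
#'   whether the LGN volley occurred and its onset.
#' @export
generate_opto_trials <- function(age, protocol, seed, baseline_hz = 0.5,
                                 vc_latency_ms = 3.5, lgn_volley_hz = 500,
                                 vc_volley_hz = 400, lgn_volley_dur_s = 0.03) {
  stopifnot(inherits(age, "age_profile"), inherits(protocol, "stimulus_protocol"))
  if (!protocol$kind %in% c("opto_single", "opto_train"))
    stop("generate_opto_trials requires an optogenetic protocol")
  set.seed(as.integer(seed))
  lead <- 0.5
  duration <- lead + protocol$n_trials * protocol$inter_trial_s
  n <- round(duration / .sim_dt)
  n_pulses <- if (protocol$kind == "opto_train") protocol$train_n_pulses else 1L
  ipi <- if (protocol$kind == "opto_train") 1 / protocol$train_freq_hz else 0

  stim <- do.call(rbind, lapply(seq_len(protocol$n_trials), function(i) {
    t0 <- lead + (i - 1) * protocol$inter_trial_s
    data.frame(kind = protocol$kind, onset_s = t0 + (seq_len(n_pulses) - 1) * ipi,
               trial = i, pulse = seq_len(n_pulses))
  }))

  lgn <- rep(baseline_hz, n)
  vc <- rep(baseline_hz, n)
  lgn_mult <- rep(1, n)
  pulses <- stim
  pulses$lgn_responded <- FALSE
  pulses$lgn_onset_s <- NA_real_
  suppression <- matrix(numeric(0), ncol = 2)  # active (start, stop) windows

  for (k in seq_len(nrow(pulses))) {
    t0 <- pulses$onset_s[k]
    vc <- add_decay_volley(vc, t0 + vc_latency_ms / 1000, vc_volley_hz,
                           0.005, 0.03, n)
    lgn_onset <- t0 + age$opto_latency_ms / 1000
    suppressed <- nrow(suppression) > 0 &&
      any(lgn_onset >= suppression[, 1] & lgn_onset <= suppression[, 2])
    if (!suppressed && stats::runif(1) < age$opto_reliability) {
      lgn <- add_decay_volley(lgn, lgn_onset, lgn_volley_hz, 0.010,
                              lgn_volley_dur_s, n)
      pulses$lgn_responded[k] <- TRUE
      pulses$lgn_onset_s[k] <- lgn_onset
    }
    if (age$inhibition_enabled) {
      win <- t0 + .inhibition_window_s
      suppression <- rbind(suppression, win)
      i0 <- floor(win[1] / .sim_dt) + 1L
      i1 <- min(ceiling(win[2] / .sim_dt), n)
      if (i1 >= i0) lgn_mult[i0:i1] <- .inhibition_residual
    }
  }
  lgn <- lgn * lgn_mult

  span <- c(0, n * .sim_dt)
  trains <- list(
    spike_train(thin_spikes(lgn), region = "LGN", channel = 1L, span_s = span),
    spike_train(thin_spikes(vc), region = "VC", channel = 1L, span_s = span))
  recording_session(trains, stimuli = stim,
                    meta = list(age = age, generator = "opto",
                                protocol = protocol, seed = as.integer(seed),
                                baseline_hz = baseline_hz,
                                log = list(pulses = pulses)))
}

#' Simulate two-phase visually evoked responses
#'
#' Each flash trial adds to baseline an initial early-gamma component
#' (30-50 Hz modulated burst in the primary window) followed by a secondary
#' spindle-band component. In `P13_14` mode the primary response is brief and
#' non-oscillatory and the secondary component is greatly reduced.
#' Stimulus timestamps start at 0 and repeat every `inter_trial_s` seconds.
#'
#' @param age an [age_profile()].
#' @param protocol a [stimulus_protocol()] of kind `flash`.
#' @param seed integer seed.
#' @param baseline_hz spontaneous rate (Hz).
#' @param gamma_freq_hz early-gamma modulation frequency (Hz).
#' @param primary_hz,secondary_hz peak amplitudes of the two components
#'   (Hz above baseline); `NULL` takes age-appropriate defaults.
#' @return a [recording_session()]; `meta$log` records windows and
#'   amplitudes used.
#' @export
generate_evoked_trials <- function(age, protocol, seed, baseline_hz = 5,
                                   gamma_freq_hz = 40, primary_hz = NULL,
                                   secondary_hz = NULL) {
  stopifnot(inherits(age, "age_profile"), inherits(protocol, "stimulus_protocol"))
  if (protocol$kind != "flash")
    stop("generate_evoked_trials requires a flash protocol")
  if (protocol$n_trials < 1) stop("n_trials must be >= 1")
  set.seed(as.integer(seed))
  mature <- age$name == "P13_14"
  if (is.null(primary_hz)) primary_hz <- 350
  if (is.null(secondary_hz)) secondary_hz <- if (mature) 30 else 450
  primary_win <- if (mature) c(0.025, 0.125) else c(0.030, 0.200)
  secondary_win <- c(0.200, 1.000)

  duration <- protocol$n_trials * protocol$inter_trial_s
  n <- round(duration / .sim_dt)
  onsets <- (seq_len(protocol$n_trials) - 1) * protocol$inter_trial_s
  stim <- data.frame(kind = "flash", onset_s = onsets,
                     trial = seq_len(protocol$n_trials))

  tt <- (seq_len(n) - 1L) * .sim_dt
  lgn <- rep(baseline_hz, n)
  vc <- rep(baseline_hz, n)
  burst <- function(rate, t0, win, amp, f_mod, phase, n) {
    i0 <- floor((t0 + win[1]) / .sim_dt) + 1L
    i1 <- min(ceiling((t0 + win[2]) / .sim_dt), n)
    if (i1 < i0 || i0 > n) return(rate)
    tloc <- tt[i0:i1] - (t0 + win[1])
    env <- sin(pi * pmin(tloc / diff(win), 1))
    mod <- if (is.null(f_mod)) 1 else
      1 + 0.8 * sin(2 * pi * f_mod * tloc + phase)
    rate[i0:i1] <- rate[i0:i1] + amp * env * mod
    rate
  }
  for (i in seq_len(protocol$n_trials)) {
    t0 <- onsets[i]
    ph1 <- stats::runif(1, 0, 2 * pi)
    ph2 <- stats::runif(1, 0, 2 * pi)
    f1 <- if (mature) NULL else gamma_freq_hz
    f2 <- if (mature) NULL else age$spindle_freq_hz
    lgn <- burst(lgn, t0, primary_win, primary_hz, f1, ph1, n)
    lgn <- burst(lgn, t0, secondary_win, secondary_hz, f2, ph2, n)
    vc <- burst(vc, t0 + 0.010, primary_win, primary_hz, f1, ph1, n)
    vc <- burst(vc, t0 + 0.010, secondary_win, secondary_hz, f2, ph2, n)
  }

  span <- c(0, n * .sim_dt)
  trains <- list(
    spike_train(thin_spikes(lgn), region = "LGN", channel = 1L, span_s = span),
    spike_train(thin_spikes(vc), region = "VC", channel = 1L, span_s = span))
  recording_session(trains, stimuli = stim,
                    meta = list(age = age, generator = "evoked",
                                protocol = protocol, seed = as.integer(seed),
                                baseline_hz = baseline_hz,
                                log = list(primary_win_s = primary_win,
                                           secondary_win_s = secondary_win,
                                           primary_hz = primary_hz,
                                           secondary_hz = secondary_hz)))
}
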