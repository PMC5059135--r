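# Spike emission: the continuous rate is evaluated on a 1 ms grid and spikes
# are drawn bin-wise (Poisson count per bin, uniform placement within the
# bin), equivalent to thinning a piecewise-constant intensity.
.sim_dt <- 1e-3

thin_spikes <- function(rate_hz, dt_s = .sim_dt, t0_s = 0) {
  n <- length(rate_hz)
  counts <- stats::rpois(n, pmax(rate_hz, 0) * dt_s)
  idx <- rep.int(seq_len(n), counts)
  if (!length(idx)) return(numeric())
  sort(t0_s + (idx - 1L) * dt_s + stats::runif(length(idx)) * dt_s)
}

# Alternating silent/active timeline; durations uniform within the profile's
# ranges. Returns a data.frame of active periods (start_s, stop_s, phase).
draw_timeline <- function(age, duration_s) {
  starts <- stops <- phases <- numeric()
  t <- stats::runif(1, age$silent_dur_s[1], age$silent_dur_s[2])
  while (t < duration_s) {
    a <- stats::runif(1, age$active_dur_s[1], age$active_dur_s[2])
    starts <- c(starts, t)
    stops <- c(stops, min(t + a, duration_s))
    phases <- c(phases, stats::runif(1, 0, 2 * pi))
    t <- t + a + stats::runif(1, age$silent_dur_s[1], age$silent_dur_s[2])
  }
  data.frame(start_s = starts, stop_s = stops, phase = phases)
}

# Rate profile on the 1 ms grid for one region from a period table with
# per-period frequency, rate, depth and phase columns.
wave_rate_profile <- function(periods, base_rate, n) {
  tt <- (seq_len(n) - 1L) * .sim_dt
  rate <- rep(base_rate, n)
  for (k in seq_len(nrow(periods))) {
    i0 <- floor(periods$start_s[k] / .sim_dt) + 1L
    i1 <- min(ceiling(periods$stop_s[k] / .sim_dt), n)
    if (i1 < i0 || i0 > n) next
    tloc <- tt[i0:i1] - periods$start_s[k]
    rate[i0:i1] <- periods$rate_hz[k] *
      (1 + periods$depth[k] * sin(2 * pi * periods$freq_hz[k] * tloc +
                                  periods$phase[k]))
  }
  rate
}

# Calibration of cortical-silencing effects on LGN by age, emulating the
# reported roles of corticothalamic feedback: amplification-only during
# cholinergic waves (about half the waves fail to drive LGN without
# cortex), amplification + prolongation + acceleration during glutamatergic
# waves (rates and active durations reduced, rhythm reverts to the slower
# intrinsic LGN frequency), and net inhibition after eye opening (silencing
# cortex disinhibits LGN).
.vc_silencing_profile <- function(age, r) {
  if (age$inhibition_enabled)
    return(list(mode = "release", rate_mult = 1 + 0.11 * (1 - r),
                dur_mult = 1 + 0.2 * (1 - r)))
  if (age$name == "P5_7")
    return(list(mode = "survival", survive_p = r + (1 - r) * 0.42))
  list(mode = "reshape", rate_mult = r + (1 - r) * 0.6,
       dur_mult = r + (1 - r) * 0.25, freq_shift = r < 0.5)
}

# Residual burst structure that remains when the main drive is silenced:
# sparse short unmodulated bursts whose time fraction is residual x the
# age's mean active fraction.
residual_burst_timeline <- function(from_s, to_s, age, params, burst_dur_s) {
  f0 <- mean(age$active_dur_s) /
    (mean(age$active_dur_s) + mean(age$silent_dur_s))
  frac <- params$residual * f0
  out <- data.frame(start_s = numeric(), stop_s = numeric(),
                    phase = numeric())
  if (frac <= 0) return(out)
  mean_burst <- mean(burst_dur_s)
  mean_gap <- mean_burst * (1 / frac - 1)
  t <- from_s + stats::runif(1, 0.5 * mean_gap, 1.5 * mean_gap)
  while (t < to_s) {
    b <- stats::runif(1, burst_dur_s[1], burst_dur_s[2])
    out <- rbind(out, data.frame(start_s = t, stop_s = min(t + b, to_s),
                                 phase = stats::runif(1, 0, 2 * pi)))
    t <- t + b + stats::runif(1, 0.5 * mean_gap, 1.5 * mean_gap)
  }
  out
}

#' Simulate spontaneous wave-driven activity in LGN and VC
#'
#' Generates paired LGN and VC spike trains from an inhomogeneous Poisson
#' process: long silent periods at `base_rate_hz` alternate with active
#' periods (durations uniform within the age profile's ranges) in which the
#' rate is sinusoidally modulated at the profile's spindle frequency with a
#' random phase per period.
#'
#' Manipulations act from `onset_s` onward. Silencing the retina (or, for
#' the cortical trace, silencing LGN) removes the wave structure itself:
#' active periods are replaced by sparse, short, unmodulated residual bursts
#' whose time fraction is the residual fraction of the normal active
#' fraction, and baseline firing is scaled by the residual. Silencing VC
#' acts on LGN according to age: during cholinergic waves (P5-7) a fraction
#' of waves simply fail (amplification-only feedback); during glutamatergic
#' waves (P9-11) in-wave rates and active durations shrink and the rhythm
#' reverts to the slower intrinsic LGN frequency (feedback amplifies,
#' prolongs and accelerates); after eye opening (P13-14) LGN is disinhibited
#' and rates increase.
#'
#' @param age an [age_profile()].
#' @param params a [wave_params()] (the seed lives here).
#' @param manip a [manipulation_spec()].
#' @return a [recording_session()] whose `meta$log` holds the per-region
#'   active-period tables.
#' @export
generate_wave_recording <- function(age, params,
                                    manip = manipulation_spec("none")) {
  stopifnot(inherits(age, "age_profile"), inherits(params, "wave_params"),
            inherits(manip, "manipulation_spec"))
  if (params$duration_s <= 0) stop("duration_s must be positive")
  if (!manip$target %in% c("none", "retina", "lgn", "vc"))
    stop("unknown manipulation target: ", manip$target)
  set.seed(params$seed)
  dur <- params$duration_s
  n <- round(dur / .sim_dt)
  r <- manip$residual_fraction
  sham <- manip$target == "none" || r >= 1   # full residual: no-op
  onset <- if (sham) dur else min(manip$onset_s, dur)

  depth <- params$modulation_depth %||%
    (if (age$inhibition_enabled) 0.2 else 0.8)
  base <- draw_timeline(age, dur)
  base$freq_hz <- rep(age$spindle_freq_hz, nrow(base))
  base$rate_hz <- rep(params$wave_rate_hz, nrow(base))
  base$depth <- rep(depth, nrow(base))
  pre <- base[base$start_s < onset, , drop = FALSE]
  pre$stop_s <- pmin(pre$stop_s, onset)
  post <- base[base$start_s >= onset, , drop = FALSE]

  burstify <- function(burst_dur_s) {
    bt <- residual_burst_timeline(onset, dur, age,
                                  list(residual = r), burst_dur_s)
    if (!nrow(bt)) return(pre)
    bt$freq_hz <- age$spindle_freq_hz
    bt$rate_hz <- params$wave_rate_hz
    bt$depth <- 0                      # residual bursts are unmodulated
    rbind(pre, bt)
  }

  lgn_periods <- rbind(pre, post)
  vc_periods <- rbind(pre, post)
  lgn_base_mult <- vc_base_mult <- 1
  if (sham) {
    # no manipulation applied
  } else if (manip$target == "retina") {
    lgn_periods <- burstify(c(0.5, 2))
    vc_periods <- burstify(c(0.5, 2))
    lgn_base_mult <- vc_base_mult <- r
  } else if (manip$target == "lgn") {
    scaled <- post
    scaled$rate_hz <- scaled$rate_hz * r
    lgn_periods <- rbind(pre, scaled)
    lgn_base_mult <- r
    vc_periods <- burstify(c(0.3, 1))  # cortex alone: very short bursts
    vc_base_mult <- r
  } else if (manip$target == "vc") {
    vp <- .vc_silencing_profile(age, r)
    scaled_vc <- post
    scaled_vc$rate_hz <- scaled_vc$rate_hz * r
    vc_periods <- rbind(pre, scaled_vc)
    vc_base_mult <- r
    if (vp$mode == "survival") {
      keep <- stats::runif(nrow(post)) < vp$survive_p
      lgn_periods <- rbind(pre, post[keep, , drop = FALSE])
      lgn_base_mult <- vp$survive_p  # inter-wave firing loses the same share
    } else if (vp$mode == "reshape") {
      rs <- post
      rs$stop_s <- rs$start_s + (rs$stop_s - rs$start_s) * vp$dur_mult
      rs$rate_hz <- rs$rate_hz * vp$rate_mult
      if (vp$freq_shift) rs$freq_hz <- age$intrinsic_freq_hz
      lgn_periods <- rbind(pre, rs)
      lgn_base_mult <- vp$rate_mult
    } else {                            # release (P13-14): disinhibition
      rs <- post
      rs$stop_s <- rs$start_s + (rs$stop_s - rs$start_s) * vp$dur_mult
      rs$rate_hz <- rs$rate_hz * vp$rate_mult
      lgn_periods <- rbind(pre, rs)
      lgn_base_mult <- vp$rate_mult
    }
  }

  base_vec <- function(mult) {
    b <- rep(params$base_rate_hz, n)
    i0 <- floor(onset / .sim_dt) + 1L
    if (mult != 1 && i0 <= n) b[i0:n] <- b[i0:n] * mult
    b
  }
  lgn_rate <- wave_rate_profile(lgn_periods, 0, n) ; lgn_bg <- base_vec(lgn_base_mult)
  lgn_rate <- pmax(lgn_rate, lgn_bg)
  vc_rate <- wave_rate_profile(vc_periods, 0, n)
  vc_rate <- pmax(vc_rate, base_vec(vc_base_mult)) * params$vc_rate_scale

  span <- c(0, n * .sim_dt)
  trains <- list(
    spike_train(thin_spikes(lgn_rate), region = "LGN", channel = 1L, span_s = span),
    spike_train(thin_spikes(vc_rate), region = "VC", channel = 1L, span_s = span))
  lfp <- NULL
  if (isTRUE(params$make_lfp))
    lfp <- list(synth_wave_lfp(vc_periods, params, age, n))
  recording_session(trains, lfp = lfp,
                    meta = list(age = age, generator = "wave",
                                params = params, manipulation = manip,
                                seed = params$seed,
                                log = list(active_periods = base,
                                           lgn_periods = lgn_periods,
                                           vc_periods = vc_periods)))
}

# Cortical LFP stand-in: band-limited background noise plus a spindle-band
# oscillation during active periods (amplitude tracking the period's rate,
# frequency and modulation depth). Synthesized only as needed; thalamic LFP
# is not modelled.
synth_wave_lfp <- function(periods, params, age, n_ms) {
  fs <- params$lfp_fs_hz
  n <- round(n_ms * .sim_dt * fs)
  noise <- stats::rnorm(n)
  bf <- signal::butter(2, min(100, 0.45 * fs) / (fs / 2), type = "low")
  x <- 20 * as.numeric(signal::filter(bf, noise))
  tt <- (seq_len(n) - 1L) / fs
  for (k in seq_len(nrow(periods))) {
    i0 <- floor(periods$start_s[k] * fs) + 1L
    i1 <- min(ceiling(periods$stop_s[k] * fs), n)
    if (i1 < i0) next
    tloc <- tt[i0:i1] - periods$start_s[k]
    env <- sin(pi * pmin(tloc / (periods$stop_s[k] - periods$start_s[k]), 1))
    amp <- 100 * periods$rate_hz[k] / max(params$wave_rate_hz, 1e-9) *
      ifelse(periods$depth[k] > 0, 1, 0.2)
    x[i0:i1] <- x[i0:i1] + amp * env *
      sin(2 * pi * periods$freq_hz[k] * tloc + periods$phase[k])
  }
  lfp_trace(x, fs_hz = fs, region = "VC", channel = 1L)
}

#' Simulate a sinusoidally rate-modulated Poisson spike train
#'
#' Convenience generator for spectral calibration: a stationary train with
#' rate `rate_hz * (1 + depth * sin(2*pi*f_hz*t + phase))` over the full
#' duration.
#'
#' @param rate_hz mean rate (Hz).
#' @param f_hz modulation frequency (Hz).
#' @param depth modulation depth in \[0, 1\].
#' @param duration_s duration (s).
#' @param seed integer seed.
#' @param phase modulation phase (radians); random if `NULL`.
#' @param region,channel passed to [spike_train()].
#' @return a [spike_train()].
#' @export
simulate_oscillatory_train <- function(rate_hz, f_hz, depth, duration_s, seed,
                                       phase = NULL, region = "LGN",
                                       channel = 1L) {
  stopifnot(rate_hz >= 0, f_hz > 0, depth >= 0, depth <= 1, duration_s > 0)
  set.seed(seed)
  if (is.null(phase)) phase <- stats::runif(1, 0, 2 * pi)
  n <- round(duration_s / .sim_dt)
  tt <- (seq_len(n) - 1L) * .sim_dt
  rate <- rate_hz * (1 + depth * sin(2 * pi * f_hz * tt + phase))
  spike_train(thin_spikes(rate), region = region, channel = channel,
              span_s = c(0, n * .sim_dt))
}

#' Render a spike train as a wideband extracellular voltage trace
#'
#' Places a biphasic spike waveform at each spike time on top of Gaussian
#' noise, for exercising threshold-crossing spike extraction on synthetic
#' data.
#'
#' @param train a [spike_train()].
#' @param fs_hz sampling rate of the rendered trace (Hz).
#' @param amp_uv peak (negative) spike amplitude in microvolts.
#' @param noise_sd_uv standard deviation of the additive noise.
#' @param seed integer seed for the noise.
#' @return an [lfp_trace()] (wideband, in microvolts).
#' @export
render_mua_trace <- function(train, fs_hz = 20000, amp_uv = -80,
                             noise_sd_uv = 5, seed = 1) {
  set.seed(seed)
  n <- ceiling(diff(train$span_s) * fs_hz)
  x <- stats::rnorm(n, sd = noise_sd_uv)
  # biphasic template: 0.3 ms negative phase, 0.5 ms positive rebound
  t_neg <- seq(0, 3e-4, by = 1 / fs_hz)
  t_pos <- seq(1 / fs_hz, 5e-4, by = 1 / fs_hz)
  w <- c(amp_uv * sin(pi * t_neg / 3e-4), -0.3 * amp_uv * sin(pi * t_pos / 5e-4))
  for (ts in train$times_s) {
    i0 <- round((ts - train$span_s[1]) * fs_hz) + 1L
    ii <- i0:(i0 + length(w) - 1L)
    ok <- ii >= 1L & ii <= n
    x[ii[ok]] <- x[ii[ok]] + w[ok]
  }
  lfp_trace(x, fs_hz = fs_hz, region = train$region, channel = train$channel,
            t0_s = train$span_s[1])
}
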