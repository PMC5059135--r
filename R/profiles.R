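#' Age-specific activity profile
#'
#' Parameters of spontaneous and stimulus-driven thalamocortical activity at
#' the three developmental stages covered by the simulator. `P5_7` corresponds
#' to the period of cholinergic (stage II) retinal waves, `P9_11` to peak
#' glutamatergic (stage III) waves, and `P13_14` to the days around eye
#' opening when cortical feedback has become net inhibitory.
#'
#' Defaults encode the field's reported values: spindle-burst rate modulation
#' near 16 Hz at P5-7 and 23 Hz at P9-11; corticothalamic loop latencies of
#' about 34, 21.5 and 20 ms with per-pulse response reliabilities of about
#' 0.40, 0.85 and 0.92 across the three stages; and post-stimulus inhibition
#' present only at P13-14. `intrinsic_freq_hz` is the frequency at which LGN
#' oscillates without cortical feedback (about 16 Hz at all pre-eye-opening
#' ages); at P9-11 the intact feedback loop accelerates the rhythm above this
#' intrinsic value.
#'
#' @param name one of `"P5_7"`, `"P9_11"`, `"P13_14"`.
#' @param spindle_freq_hz centre frequency (Hz) of the oscillatory rate
#'   modulation during active periods.
#' @param intrinsic_freq_hz LGN oscillation frequency (Hz) when cortical
#'   feedback is removed.
#' @param active_dur_s length-2 numeric, range of active-period durations (s).
#' @param silent_dur_s length-2 numeric, range of silent-period durations (s).
#' @param opto_latency_ms latency (ms) from a cortical pulse to the LGN
#'   spike volley.
#' @param opto_reliability probability in \[0, 1\] that a cortical volley
#'   elicits an LGN volley.
#' @param inhibition_enabled logical; does stimulation recruit feed-forward
#'   inhibition (suppression of LGN firing 100-250 ms after a pulse)?
#' @return an object of class `age_profile`.
#' @export
age_profile <- function(name = c("P9_11", "P5_7", "P13_14"),
                        spindle_freq_hz = NULL,
                        intrinsic_freq_hz = NULL,
                        active_dur_s = NULL,
                        silent_dur_s = NULL,
                        opto_latency_ms = NULL,
                        opto_reliability = NULL,
                        inhibition_enabled = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    P5_7 = list(spindle_freq_hz = 16, intrinsic_freq_hz = 16,
                active_dur_s = c(1, 5), silent_dur_s = c(10, 60),
                opto_latency_ms = 34.2, opto_reliability = 0.40,
                inhibition_enabled = FALSE),
    P9_11 = list(spindle_freq_hz = 23, intrinsic_freq_hz = 16,
                 active_dur_s = c(3, 10), silent_dur_s = c(10, 60),
                 opto_latency_ms = 21.5, opto_reliability = 0.85,
                 inhibition_enabled = FALSE),
    P13_14 = list(spindle_freq_hz = 12, intrinsic_freq_hz = 12,
                  active_dur_s = c(5, 20), silent_dur_s = c(1, 5),
                  opto_latency_ms = 20.0, opto_reliability = 0.92,
                  inhibition_enabled = TRUE))
  p <- defaults
  p$name <- name
  override <- list(spindle_freq_hz = spindle_freq_hz,
                   intrinsic_freq_hz = intrinsic_freq_hz,
                   active_dur_s = active_dur_s, silent_dur_s = silent_dur_s,
                   opto_latency_ms = opto_latency_ms,
                   opto_reliability = opto_reliability,
                   inhibition_enabled = inhibition_enabled)
  for (nm in names(override)) if (!is.null(override[[nm]])) p[[nm]] <- override[[nm]]
  stopifnot(p$spindle_freq_hz > 0, p$intrinsic_freq_hz > 0,
            length(p$active_dur_s) == 2L, p$active_dur_s[1] <= p$active_dur_s[2],
            length(p$silent_dur_s) == 2L, p$silent_dur_s[1] <= p$silent_dur_s[2],
            p$opto_latency_ms > 0,
            p$opto_reliability >= 0, p$opto_reliability <= 1,
            is.logical(p$inhibition_enabled))
  structure(p, class = "age_profile")
}

#' Wave-generator parameters
#'
#' Controls the inhomogeneous Poisson model of spontaneous activity: long
#' silences at `base_rate_hz` alternate with active periods in which the
#' rate is `wave_rate_hz * (1 + modulation_depth * sin(2*pi*f*t + phi))`,
#' with `f` taken from the age profile and a random phase per active period.
#'
#' @param base_rate_hz firing rate (Hz) between waves.
#' @param wave_rate_hz mean multi-unit firing rate (Hz) within active
#'   periods (pooled across units on the analysis channel).
#' @param modulation_depth oscillatory modulation depth in \[0, 1\];
#'   `NULL` uses an age-appropriate default (0.8 during the wave period,
#'   0.2 after eye opening, when prominent spindle oscillations are lost).
#' @param duration_s total simulated time (s).
#' @param vc_rate_scale cortical rate as a fraction of the LGN rate profile.
#' @param make_lfp logical, synthesize a cortical LFP trace (band-limited
#'   noise plus a spindle-band oscillation during active periods)?
#' @param lfp_fs_hz LFP sampling rate (Hz).
#' @param seed integer random seed (mandatory; one stream per session).
#' @return an object of class `wave_params`.
#' @export
wave_params <- function(base_rate_hz = 0.1, wave_rate_hz = 100,
                        modulation_depth = NULL, duration_s = 600,
                        vc_rate_scale = 1, make_lfp = FALSE,
                        lfp_fs_hz = 1000, seed) {
  stopifnot(base_rate_hz >= 0, wave_rate_hz >= 0,
            is.null(modulation_depth) ||
              (modulation_depth >= 0 && modulation_depth <= 1),
            duration_s > 0, vc_rate_scale >= 0,
            is.numeric(seed), length(seed) == 1L)
  structure(list(base_rate_hz = base_rate_hz, wave_rate_hz = wave_rate_hz,
                 modulation_depth = modulation_depth, duration_s = duration_s,
                 vc_rate_scale = vc_rate_scale, make_lfp = make_lfp,
                 lfp_fs_hz = lfp_fs_hz, seed = as.integer(seed)),
            class = "wave_params")
}

#' Silencing-manipulation specification
#'
#' Describes pharmacological silencing of one node of the retino-thalamo-
#' cortical chain. The targeted drive is scaled by `residual_fraction` from
#' `onset_s` onward. Silencing the retina scales both LGN and VC (the retina
#' is the source of the drive); silencing LGN scales both LGN output and its
#' cortical consequence; silencing VC scales cortical firing directly and
#' removes the corticothalamic amplification share of LGN drive (see
#' [generate_wave_recording()]).
#'
#' @param target `"none"`, `"retina"`, `"lgn"` or `"vc"`.
#' @param residual_fraction fraction of drive remaining in \[0, 1\].
#' @param onset_s time (s) at which the manipulation takes effect.
#' @return an object of class `manipulation_spec`.
#' @export
manipulation_spec <- function(target = c("none", "retina", "lgn", "vc"),
                              residual_fraction = 1, onset_s = 0) {
  target <- match.arg(target)
  stopifnot(residual_fraction >= 0, residual_fraction <= 1, onset_s >= 0)
  structure(list(target = target, residual_fraction = residual_fraction,
                 onset_s = onset_s),
            class = "manipulation_spec")
}

#' Stimulus protocol
#'
#' Flash protocol follows the classic design of a 100 ms whole-field flash
#' every 30 s; optogenetic protocols use 10 ms light pulses, either single
#' pulses or trains (e.g. five pulses at 20 Hz).
#'
#' @param kind `"flash"`, `"opto_single"` or `"opto_train"`.
#' @param pulse_dur_ms stimulus duration (ms).
#' @param inter_trial_s seconds between trial onsets.
#' @param n_trials number of trials (>= 1).
#' @param train_freq_hz pulse rate within a train (required for
#'   `opto_train`).
#' @param train_n_pulses pulses per train (required for `opto_train`).
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(kind = c("flash", "opto_single", "opto_train"),
                              pulse_dur_ms = NULL, inter_trial_s = NULL,
                              n_trials = 20, train_freq_hz = NULL,
                              train_n_pulses = NULL) {
  kind <- match.arg(kind)
  if (is.null(pulse_dur_ms)) pulse_dur_ms <- if (kind == "flash") 100 else 10
  if (is.null(inter_trial_s)) inter_trial_s <- if (kind == "flash") 30 else 10
  stopifnot(n_trials >= 1, pulse_dur_ms > 0, inter_trial_s > 0)
  if (kind == "opto_train") {
    if (is.null(train_freq_hz) || is.null(train_n_pulses))
      stop("opto_train requires train_freq_hz and train_n_pulses")
    stopifnot(train_freq_hz > 0, train_n_pulses >= 2)
    if (1000 / train_freq_hz <= pulse_dur_ms)
      stop("train_freq_hz incompatible with pulse_dur_ms: pulses overlap")
  } else if (!is.null(train_freq_hz) || !is.null(train_n_pulses)) {
    stop("train parameters are only valid for kind = 'opto_train'")
  }
  structure(list(kind = kind, pulse_dur_ms = pulse_dur_ms,
                 inter_trial_s = inter_trial_s, n_trials = as.integer(n_trials),
                 train_freq_hz = train_freq_hz,
                 train_n_pulses = if (is.null(train_n_pulses)) NULL else as.integer(train_n_pulses)),
            class = "stimulus_protocol")
}

#' Delayed feedback-loop model parameters
#'
#' Parameters of the discrete-time corticothalamic rate model integrated by
#' [simulate_feedback_loop()]. The LGN rate is the retinal drive multiplied
#' by `1 + feedback_gain * C(t - delay_vc_to_lgn)`, minus a delayed
#' subtractive inhibition term; the cortical rate follows the LGN rate after
#' `delay_lgn_to_vc`. With round-trip delay `D` the closed loop echoes drive
#' fluctuations every `D` ms and so concentrates power near `1000/D` Hz.
#'
#' The default `feedback_gain` is calibrated so that with the default 10 Hz
#' mean retinal drive the closed-loop LGN rate is about five times the
#' open-loop rate, i.e. roughly 80% of LGN firing is contributed by the
#' cortical feedback loop.
#'
#' @param dt_ms integration step (ms); must not exceed a quarter of the
#'   smallest delay.
#' @param delay_lgn_to_vc_ms,delay_vc_to_lgn_ms loop conduction delays (ms).
#' @param feedback_gain multiplicative feedback gain (per Hz of cortical
#'   rate); loop gain equals `mean drive * feedback_gain * cortical_gain`.
#' @param cortical_gain cortical rate per unit LGN rate.
#' @param inhibition_gain subtractive feed-forward inhibition gain
#'   (dimensionless); 0 disables inhibition.
#' @param inhibition_delay_ms extra delay (ms) of the inhibitory pathway
#'   relative to the excitatory feedback.
#' @param retinal_drive `NULL` for the built-in stochastic drive (mean
#'   `drive_rate_hz`, exponentially smoothed noise), a numeric rate vector on
#'   the `dt_ms` grid, or a function `f(t_s)` returning rates (Hz).
#' @param drive_rate_hz mean of the built-in retinal drive (Hz).
#' @param drive_cv coefficient of variation of the built-in drive.
#' @param drive_tau_ms correlation time (ms) of the built-in drive.
#' @param rate_floor_hz lower clip for the LGN rate.
#' @param rate_ceiling_hz instability guard; integration aborts if the LGN
#'   rate exceeds this value.
#' @return an object of class `loop_params`.
#' @export
loop_params <- function(dt_ms = 1, delay_lgn_to_vc_ms = 20,
                        delay_vc_to_lgn_ms = 20, feedback_gain = 0.08,
                        cortical_gain = 1, inhibition_gain = 0,
                        inhibition_delay_ms = 40, retinal_drive = NULL,
                        drive_rate_hz = 10, drive_cv = 0.5, drive_tau_ms = 10,
                        rate_floor_hz = 0, rate_ceiling_hz = 1e4) {
  stopifnot(dt_ms > 0, delay_lgn_to_vc_ms >= dt_ms, delay_vc_to_lgn_ms >= dt_ms,
            feedback_gain >= 0, cortical_gain >= 0, inhibition_gain >= 0,
            inhibition_delay_ms >= dt_ms || inhibition_gain == 0,
            drive_rate_hz >= 0, rate_floor_hz >= 0,
            rate_ceiling_hz > rate_floor_hz)
  if (dt_ms > min(delay_lgn_to_vc_ms, delay_vc_to_lgn_ms) / 4)
    stop("dt_ms must be at most a quarter of the smallest loop delay")
  structure(list(dt_ms = dt_ms, delay_lgn_to_vc_ms = delay_lgn_to_vc_ms,
                 delay_vc_to_lgn_ms = delay_vc_to_lgn_ms,
                 feedback_gain = feedback_gain, cortical_gain = cortical_gain,
                 inhibition_gain = inhibition_gain,
                 inhibition_delay_ms = inhibition_delay_ms,
                 retinal_drive = retinal_drive, drive_rate_hz = drive_rate_hz,
                 drive_cv = drive_cv, drive_tau_ms = drive_tau_ms,
                 rate_floor_hz = rate_floor_hz,
                 rate_ceiling_hz = rate_ceiling_hz),
            class = "loop_params")
}
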