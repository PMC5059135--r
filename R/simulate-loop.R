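#' Integrate the delayed corticothalamic feedback-loop rate model
#'
#' Discrete-time rate model of the retino-thalamo-cortical loop. With
#' `R(t)` the retinal drive, `L(t)` the LGN rate and `C(t)` the cortical
#' rate, the update is
#' \deqn{L(t) = \max(\mathrm{floor},\; R(t)\,[1 + g_{fb} C(t - d_{VC\to LGN})]
#'   - g_{inh} C(t - d_{VC\to LGN} - d_{inh}))}
#' \deqn{C(t) = \max(0,\; a\, L(t - d_{LGN\to VC}))}
#' so cortical feedback multiplies the retinal drive rather than adding to
#' it. The closed loop echoes drive fluctuations at the round-trip delay
#' `d_LGN->VC + d_VC->LGN`, concentrating rate power near the reciprocal of
#' that delay (25 Hz for 20 ms + 20 ms); subtractive inhibition arriving one
#' further round-trip later cancels the echo and suppresses the rhythm.
#' Poisson spike trains are emitted from both rate traces.
#'
#' @param params a [loop_params()].
#' @param duration_s simulated time (s).
#' @param seed integer seed (drive noise and spike emission).
#' @return a [recording_session()] with LGN and VC trains; `meta$log$rates`
#'   holds the noiseless rate traces (`lgn`, `vc`, `drive`, in Hz on the
#'   `dt_ms` grid).
#' @export
simulate_feedback_loop <- function(params, duration_s, seed) {
  stopifnot(inherits(params, "loop_params"), duration_s > 0)
  set.seed(as.integer(seed))
  dt <- params$dt_ms / 1000
  n <- round(duration_s / dt)
  d1 <- round(params$delay_vc_to_lgn_ms / params$dt_ms)
  d2 <- round(params$delay_lgn_to_vc_ms / params$dt_ms)
  di <- round(params$inhibition_delay_ms / params$dt_ms)

  drv <- params$retinal_drive
  R <- if (is.null(drv)) {
    # exponentially correlated positive drive
    a <- exp(-params$dt_ms / params$drive_tau_ms)
    x <- as.numeric(stats::filter(stats::rnorm(n, sd = sqrt(1 - a^2)), a,
                                  method = "recursive"))
    pmax(params$drive_rate_hz * (1 + params$drive_cv * x), 0)
  } else if (is.function(drv)) {
    pmax(drv((seq_len(n) - 1L) * dt), 0)
  } else {
    if (length(drv) < n) stop("retinal_drive vector shorter than simulation")
    pmax(as.numeric(drv[seq_len(n)]), 0)
  }

  L <- C <- numeric(n)
  g_fb <- params$feedback_gain; g_inh <- params$inhibition_gain
  a_c <- params$cortical_gain
  for (t in seq_len(n)) {
    c_fb <- if (t > d1) C[t - d1] else 0
    c_in <- if (t > d1 + di) C[t - d1 - di] else 0
    L[t] <- max(params$rate_floor_hz, R[t] * (1 + g_fb * c_fb) - g_inh * c_in)
    if (L[t] > params$rate_ceiling_hz)
      stop(sprintf(
        "feedback loop unstable: LGN rate %.1f Hz exceeded ceiling %.1f Hz at t = %.3f s (loop gain too high)",
        L[t], params$rate_ceiling_hz, t * dt))
    C[t] <- max(0, a_c * (if (t > d2) L[t - d2] else 0))
  }

  span <- c(0, n * dt)
  trains <- list(
    spike_train(thin_spikes(L, dt_s = dt), region = "LGN", channel = 1L,
                span_s = span),
    spike_train(thin_spikes(C, dt_s = dt), region = "VC", channel = 1L,
                span_s = span))
  recording_session(trains,
                    meta = list(generator = "feedback_loop", params = params,
                                seed = as.integer(seed),
                                log = list(rates = list(lgn = L, vc = C,
                                                        drive = R),
                                           dt_s = dt)))
}
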