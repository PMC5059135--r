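#' Extract multi-unit activity from a wideband trace
#'
#' Band-pass filters the trace (zero-phase 4th-order Butterworth), detects
#' negative-going crossings of the voltage threshold and applies a short
#' refractory lockout so multiphasic waveforms are not double counted. Spike
#' times are reported at the crossing sample.
#'
#' @param trace an [lfp_trace()] (wideband, microvolts).
#' @param threshold_uv negative voltage threshold (default -50).
#' @param band_hz length-2 band edges (Hz); the upper edge is capped just
#'   below Nyquist.
#' @param refractory_ms lockout after each accepted crossing (ms).
#' @return a [spike_train()].
#' @export
extract_mua <- function(trace, threshold_uv = -50, band_hz = c(300, 9000),
                        refractory_ms = 1) {
  stopifnot(inherits(trace, "lfp_trace"), threshold_uv < 0,
            length(band_hz) == 2L, band_hz[1] < band_hz[2])
  nyq <- trace$fs_hz / 2
  if (band_hz[1] >= nyq)
    stop(sprintf("band low edge %.0f Hz is at or above Nyquist (%.0f Hz)",
                 band_hz[1], nyq))
  hi <- min(band_hz[2], 0.99 * nyq)
  bf <- signal::butter(4, c(band_hz[1], hi) / nyq, type = "pass")
  y <- signal::filtfilt(bf, trace$samples_uv)
  cross <- which(y[-1] < threshold_uv & y[-length(y)] >= threshold_uv) + 1L
  if (length(cross)) {
    lock <- refractory_ms / 1000 * trace$fs_hz
    keep <- logical(length(cross))
    last <- -Inf
    for (i in seq_along(cross)) {
      if (cross[i] - last > lock) {
        keep[i] <- TRUE
        last <- cross[i]
      }
    }
    cross <- cross[keep]
  }
  n <- length(trace$samples_uv)
  spike_train(trace$t0_s + (cross - 1L) / trace$fs_hz,
              region = trace$region, channel = trace$channel,
              span_s = c(trace$t0_s, trace$t0_s + n / trace$fs_hz))
}

#' Bin a spike train into fixed-width counts
#'
#' Bins are half-open `[t, t + bin)` from the start of the recording span;
#' the sum of counts equals the number of spikes.
#'
#' @param train a [spike_train()].
#' @param bin_ms bin width (ms), default 1 (1 kHz count series).
#' @return an object of class `binned_counts`: list with `counts`, `bin_s`,
#'   `t0_s` and `fs_hz`.
#' @export
bin_spike_train <- function(train, bin_ms = 1) {
  stopifnot(bin_ms > 0)
  bin_s <- bin_ms / 1000
  n <- ceiling((train$span_s[2] - train$span_s[1]) / bin_s - 1e-9)
  idx <- floor((train$times_s - train$span_s[1]) / bin_s) + 1L
  idx[idx > n] <- n  # spike exactly at span end
  counts <- tabulate(idx, nbins = n)
  structure(list(counts = counts, bin_s = bin_s, t0_s = train$span_s[1],
                 fs_hz = 1 / bin_s),
            class = "binned_counts")
}

#' Select the analysis channel per region
#'
#' `evoked_earliest` picks, per region, the channel whose trial-averaged
#' flash PSTH first exceeds its response criterion (baseline mean + 3 SD,
#' sustained); `spindle_strongest` picks the channel with the highest spike
#' rate inside detected events. Channels with no response / no events yield
#' an explicit no-selection result rather than a silent default.
#'
#' @param session a [recording_session()].
#' @param mode `"evoked_earliest"` or `"spindle_strongest"`.
#' @return named list (one element per region) with `channel` (NA if no
#'   selection), `value` (latency in ms, or in-event rate in Hz) and
#'   `reason` when no channel qualifies.
#' @export
select_analysis_channel <- function(session,
                                    mode = c("evoked_earliest",
                                             "spindle_strongest")) {
  mode <- match.arg(mode)
  regions <- unique(vapply(session$spike_trains, `[[`, "", "region"))
  if (mode == "evoked_earliest" &&
      !any(session$stimuli$kind == "flash"))
    stop("evoked_earliest selection requires flash stimuli in the session")
  out <- list()
  for (reg in regions) {
    trs <- get_trains(session, region = reg)
    best_ch <- NA_integer_
    best_val <- if (mode == "evoked_earliest") Inf else -Inf
    for (tr in trs) {
      if (mode == "evoked_earliest") {
        ps <- compute_psth(session, align = "flash", region = reg,
                           channel = tr$channel, bin_ms = 1,
                           window_s = c(-0.1, 0.3))
        ol <- onset_latency(ps)
        if (ol$responded && ol$latency_ms < best_val) {
          best_val <- ol$latency_ms
          best_ch <- tr$channel
        }
      } else {
        ev <- detect_events(tr)
        if (nrow(ev$events)) {
          tot <- sum(ev$events$duration_s)
          val <- if (tot > 0) sum(ev$events$n_spikes) / tot else 0
          if (val > best_val) {
            best_val <- val
            best_ch <- tr$channel
          }
        }
      }
    }
    out[[reg]] <- if (is.na(best_ch))
      list(channel = NA_integer_, value = NA_real_,
           reason = if (mode == "evoked_earliest") "no responsive channel"
                    else "no events on any channel")
    else list(channel = best_ch, value = best_val)
  }
  out
}
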